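# Internal helpers shared across the package: timestamp handling, text
# normalization for drug labels and French problem keywords, display rounding
# and threshold comparators.

#' @importFrom stats rnorm runif rlnorm rbinom rnbinom sd setNames
#' @importFrom utils write.csv head
NULL

# Timestamps are timezone-naive ISO-8601 at minute resolution; internally
# carried as POSIXct pinned to UTC so arithmetic is unambiguous.
pc_parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (all(is.na(x))) {
    return(as.POSIXct(rep(NA_character_, length(x)), tz = "UTC"))
  }
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M")
  retry <- is.na(out) & !is.na(x)
  if (any(retry)) {
    out[retry] <- as.POSIXct(x[retry], tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  }
  retry <- is.na(out) & !is.na(x)
  if (any(retry)) {
    out[retry] <- as.POSIXct(x[retry], tz = "UTC", format = "%Y-%m-%d")
  }
  if (any(is.na(out) & !is.na(x))) {
    pc_stop(sprintf("unparseable timestamp: %s",
                    paste(x[is.na(out) & !is.na(x)], collapse = ", ")),
            "pharmacheck_parse_error")
  }
  out
}

pc_format_ts <- function(x) {
  ifelse(is.na(x), NA_character_, format(x, "%Y-%m-%dT%H:%M", tz = "UTC"))
}

pc_days <- function(n) as.difftime(n, units = "days")

# Classed error so callers can distinguish package failures from base ones.
pc_stop <- function(message, class = "pharmacheck_error") {
  stop(structure(
    class = c(class, "pharmacheck_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# Lowercase + strip the French diacritics that occur in problem notes and
# drug labels. chartr is locale-independent, unlike iconv //TRANSLIT.
pc_fold <- function(x) {
  x <- tolower(x)
  chartr("àâäéèêëîïôöùûüç",
         "aaaeeeeiioouuuc", x)
}

# Canonical form of a drug label: folded, squished, and with a trailing "e"
# stemmed so French substance spellings (metformine, warfarine) compare equal
# to their international nonproprietary names. Applied to both sides.
pc_normalize_label <- function(x) {
  x <- pc_fold(trimws(x))
  x <- gsub("[[:space:]]+", " ", x)
  sub("e$", "", x)
}

# Half-up rounding at display precision (0.1 percent); R's round() is
# half-to-even, which disagrees with clinical-report conventions.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Threshold comparators, keyed by the glyphs used in the rulebook. "outside"
# is a two-sided band: value <= low OR value >= high, both inclusive.
pc_compare <- function(value, comparator, threshold, threshold_high = NA_real_) {
  switch(comparator,
    "<=" = value <= threshold,
    ">=" = value >= threshold,
    "<"  = value < threshold,
    ">"  = value > threshold,
    "outside" = value <= threshold | value >= threshold_high,
    pc_stop(sprintf("unknown comparator '%s'", comparator))
  )
}

pc_empty_df <- function(template) template[0, , drop = FALSE]

`%||%` <- function(a, b) if (is.null(a)) b else a
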