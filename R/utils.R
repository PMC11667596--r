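# Internal helpers shared across modules.

#' Default study window
#'
#' The default surveillance window runs from January 2011 through the end of
#' February 2020 (110 calendar months), stopping before the COVID-19 pandemic
#' could distort reporting behaviour.
#'
#' @return A length-2 `Date` vector `c(start, end)`.
#' @export
default_window <- function() {
  as.Date(c("2011-01-01", "2020-02-29"))
}

# 0-based calendar-month index of `dates` relative to the month of `start`.
month_index <- function(dates, start) {
  12L * (as.integer(format(dates, "%Y")) - as.integer(format(start, "%Y"))) +
    (as.integer(format(dates, "%m")) - as.integer(format(start, "%m")))
}

# Number of calendar months spanned by a window (both ends inclusive).
n_window_months <- function(window) {
  month_index(window[2], window[1]) + 1L
}

# First days of every calendar month in the window.
window_month_starts <- function(window) {
  first <- as.Date(format(window[1], "%Y-%m-01"))
  seq(first, by = "month", length.out = n_window_months(window))
}

check_window <- function(window) {
  window <- as.Date(window)
  if (length(window) != 2L || anyNA(window)) {
    stop("`window` must be two valid dates c(start, end)", call. = FALSE)
  }
  if (window[1] > window[2]) {
    stop("window start is after window end", call. = FALSE)
  }
  window
}

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed uses (and advances) the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Half-away-from-zero rounding (base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Normalize narrative text for phrase matching
#'
#' Uppercases, collapses every run of whitespace to a single space and trims.
#' All phrase matching in the package happens on text normalized this way, so
#' matching is deterministic regardless of the casing and spacing of the raw
#' narrative.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_text("the  patient\n expired ")
normalize_text <- function(x) {
  x[is.na(x)] <- ""
  trimws(gsub("[[:space:]]+", " ", toupper(x)))
}
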