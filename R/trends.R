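# Monthly time series, linear trend fits, cross-series comparison statistics
# and the class-by-outcome share table.

#' Bin cohort events into a zero-filled monthly count series
#'
#' Counts events per calendar month of the study window, binning by the
#' event date (when the adverse event occurred), not the date the report was
#' received — reporting lag varies by manufacturer. Months with no events are
#' present with count 0: omitting them would bias trend slopes. `x` is the
#' 0-based month index, with 0 the window's first calendar month.
#'
#' @param events Cohort events from [build_cohort()].
#' @param window Study window; defaults to the events' `window` attribute.
#' @param stent_class,outcome Optional filters (`NULL` = all).
#' @return A `monthly_series`: list with `stent_class`, `outcome`, `window`,
#'   `x` (0...M-1) and `y` (integer counts).
#' @export
bin_monthly <- function(events, window = NULL, stent_class = NULL,
                        outcome = NULL) {
  if (is.null(window)) window <- attr(events, "window")
  if (is.null(window)) stop("no window given and events carry none", call. = FALSE)
  window <- check_window(window)

  sel <- rep(TRUE, nrow(events))
  if (!is.null(stent_class)) sel <- sel & events$stent_class %in% stent_class
  if (!is.null(outcome)) sel <- sel & events$outcome %in% outcome
  m <- n_window_months(window)
  idx <- month_index(events$event_date[sel], window[1])
  if (length(idx) && (min(idx) < 0L || max(idx) >= m)) {
    stop("event date outside the binning window", call. = FALSE)
  }
  structure(
    list(
      stent_class = if (is.null(stent_class)) "all" else paste(stent_class, collapse = "+"),
      outcome = if (is.null(outcome)) "all" else paste(outcome, collapse = "+"),
      window = window,
      x = seq_len(m) - 1L,
      y = tabulate(idx + 1L, nbins = m)
    ),
    class = "monthly_series"
  )
}

#' @export
print.monthly_series <- function(x, ...) {
  cat("Monthly series: ", x$stent_class, " / ", x$outcome, ", ",
      length(x$y), " months, ", sum(x$y), " events\n", sep = "")
  invisible(x)
}

#' Element-wise sum of two monthly series
#'
#' Combines two outcome series from the same window (e.g. injuries plus
#' malfunctions for one stent class) into one series labeled with the
#' combined outcome.
#'
#' @param a,b `monthly_series` objects over the same window.
#' @return A `monthly_series` with `y = a$y + b$y`.
#' @export
combined_series <- function(a, b) {
  stopifnot(inherits(a, "monthly_series"), inherits(b, "monthly_series"))
  if (!identical(a$window, b$window)) {
    stop("series windows differ; cannot combine", call. = FALSE)
  }
  structure(
    list(
      stent_class = if (identical(a$stent_class, b$stent_class)) a$stent_class
                    else paste(a$stent_class, b$stent_class, sep = "+"),
      outcome = paste(a$outcome, b$outcome, sep = "+"),
      window = a$window, x = a$x, y = a$y + b$y
    ),
    class = "monthly_series"
  )
}

#' Fit a linear trend to a monthly count series
#'
#' Ordinary least squares of monthly counts on the month index, with the
#' Pearson correlation of (x, y) as the goodness-of-trend measure the
#' surveillance literature reports. A constant series has slope 0 and its
#' intercept equal to the constant, but its correlation is undefined and
#' reported as `NA` — not 0 — so no trend is fabricated.
#'
#' @param series A `monthly_series`, or a numeric vector of counts.
#' @param x Month indices when `series` is a bare numeric vector; defaults
#'   to `0, 1, ...`.
#' @return A `trend_fit`: coefficients (intercept in cases, slope in
#'   cases/month), Pearson `r`, `n` points, the data, fitted values and
#'   residuals. Supports `coef`, `predict`, `fitted`, `residuals`,
#'   `simulate`, `plot` and `print`.
#' @export
#' @examples
#' fit_linear_trend(c(1, 3, 5, 7, 9))
fit_linear_trend <- function(series, x = NULL) {
  if (inherits(series, "monthly_series")) {
    y <- as.numeric(series$y)
    x <- as.numeric(series$x)
    meta <- series[c("stent_class", "outcome")]
  } else {
    y <- as.numeric(series)
    if (is.null(x)) x <- seq_along(y) - 1
    x <- as.numeric(x)
    meta <- list(stent_class = NA_character_, outcome = NA_character_)
  }
  n <- length(y)
  if (n < 3L) stop("need at least 3 points to fit a trend", call. = FALSE)
  if (length(x) != n) stop("x and y lengths differ", call. = FALSE)

  if (stats::sd(y) == 0) {
    # constant series: slope exactly 0, correlation undefined (not 0)
    b <- c(y[1], 0)
    r <- NA_real_
  } else {
    b <- unname(stats::coef(stats::lm(y ~ x)))
    r <- stats::cor(x, y)
  }

  structure(
    list(
      coefficients = c(intercept = b[1], slope = b[2]),
      r = r, n = n, x = x, y = y,
      fitted.values = b[1] + b[2] * x,
      residuals = y - (b[1] + b[2] * x),
      stent_class = meta$stent_class, outcome = meta$outcome
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, digits = 2, ...) {
  b <- x$coefficients
  lab <- if (is.na(x$stent_class)) "" else paste0(" [", x$stent_class, " / ", x$outcome, "]")
  cat(sprintf("Linear trend%s: y = %s x + %s  (R = %s, n = %d)\n", lab,
              format(round_half_up(b["slope"], digits)),
              format(round_half_up(b["intercept"], digits)),
              if (is.na(x$r)) "undefined" else format(round_half_up(x$r, digits)),
              x$n))
  invisible(x)
}

#' @export
coef.trend_fit <- function(object, ...) object$coefficients

#' @rdname fit_linear_trend
#' @param object A `trend_fit`.
#' @param newx Month indices at which to evaluate the fitted line.
#' @param ... Unused.
#' @export
predict.trend_fit <- function(object, newx = object$x, ...) {
  unname(object$coefficients["intercept"] + object$coefficients["slope"] * newx)
}

#' @export
residuals.trend_fit <- function(object, ...) object$residuals

#' @export
fitted.trend_fit <- function(object, ...) object$fitted.values

#' @export
simulate.trend_fit <- function(object, nsim = 1, seed = NULL, ...) {
  # Poisson counts around the fitted mean, floored at 0 where the fitted
  # line goes negative.
  mu <- pmax(0, object$fitted.values)
  with_seed(seed, {
    as.data.frame(replicate(nsim, stats::rpois(length(mu), mu)))
  })
}

#' @export
plot.trend_fit <- function(x, main = NULL, ...) {
  if (is.null(main)) {
    main <- if (is.na(x$stent_class)) "Monthly trend"
            else paste(x$stent_class, x$outcome)
  }
  graphics::plot(x$x, x$y, pch = 16, cex = 0.6, xlab = "month",
                 ylab = "reports", main = main, ...)
  graphics::abline(x$coefficients["intercept"], x$coefficients["slope"],
                   col = "red3", lwd = 2)
  lab <- sprintf("y = %.2fx + %.1f  R = %s", x$coefficients["slope"],
                 x$coefficients["intercept"],
                 if (is.na(x$r)) "undef." else sprintf("%.2f", x$r))
  graphics::mtext(lab, side = 3, line = 0.1, cex = 0.8)
  invisible(x)
}

#' Slope-to-intercept ratio of a fitted trend
#'
#' A scale-free summary of a trend: the monthly change relative to the
#' series' starting level, used to compare declining and growing device
#' classes whose absolute volumes differ by an order of magnitude.
#'
#' @param fit A `trend_fit`.
#' @return `slope / intercept` (dimensionless, per month).
#' @export
slope_to_intercept_ratio <- function(fit) {
  b <- stats::coef(fit)
  if (b[["intercept"]] == 0) {
    stop("intercept is zero; slope-to-intercept ratio undefined", call. = FALSE)
  }
  unname(b[["slope"]] / b[["intercept"]])
}

#' Magnitude ratio of two trend slopes
#'
#' `|slope(a)| / |slope(b)|` — e.g. how many times faster one class's
#' malfunction reports grow than another's decline.
#'
#' @param fit_a,fit_b `trend_fit` objects (or numbers taken as slopes).
#' @return Non-negative dimensionless ratio.
#' @export
magnitude_ratio <- function(fit_a, fit_b) {
  slope_of <- function(f) {
    if (inherits(f, "trend_fit")) f$coefficients[["slope"]] else as.numeric(f)
  }
  sa <- slope_of(fit_a)
  sb <- slope_of(fit_b)
  if (sb == 0) stop("denominator slope is zero; ratio undefined", call. = FALSE)
  abs(sa) / abs(sb)
}

#' Class-by-outcome share table
#'
#' Cross-tabulates counts by stent class and outcome with marginals and the
#' grand total, and carries every percentage at full precision (display
#' rounding happens only in `print`). Percentages are undefined (`NA`) for an
#' empty table rather than 0.
#'
#' @param counts Integer matrix, classes in rows, outcomes in columns.
#' @return A `share_table`: counts, marginal totals, grand total,
#'   `class_percent`, `outcome_percent`, `cell_percent`.
#' @export
#' @examples
#' share_table(matrix(c(5, 3, 2, 0), 2, 2,
#'                    dimnames = list(c("BMS", "DES"), c("MALFUNCTION", "INJURY"))))
share_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  total <- sum(counts)
  pct <- function(x) if (total == 0) x * NA_real_ else 100 * x / total
  structure(
    list(
      counts = counts,
      class_total = rowSums(counts),
      outcome_total = colSums(counts),
      total = total,
      class_percent = pct(rowSums(counts)),
      outcome_percent = pct(colSums(counts)),
      cell_percent = pct(counts)
    ),
    class = "share_table"
  )
}

#' Share table of a cohort
#'
#' @param events Cohort events from [build_cohort()].
#' @param classes,outcomes Row and column orders of the table.
#' @return A [share_table()].
#' @export
outcome_share_table <- function(events, classes = c("BMS", "DES", "BVS"),
                                outcomes = cohort_outcomes()) {
  counts <- table(factor(events$stent_class, levels = classes),
                  factor(events$outcome, levels = outcomes))
  share_table(unclass(counts))
}

# Shares are printed to 3 significant digits (e.g. 88.5, 10.2, 1.25), the
# convention of the surveillance tables this mirrors.
fmt_share <- function(p) ifelse(is.na(p), "-", format(signif(p, 3)))

#' @export
print.share_table <- function(x, ...) {
  m <- cbind(x$counts, Total = x$class_total)
  m <- rbind(m, Total = c(x$outcome_total, x$total))
  cat("Adverse event counts by stent class and outcome\n\n")
  print(m)
  cat("\nClass shares (%):  ",
      paste(rownames(x$counts), fmt_share(x$class_percent), collapse = "  "), "\n")
  cat("Outcome shares (%):",
      paste(colnames(x$counts), fmt_share(x$outcome_percent), collapse = "  "), "\n")
  invisible(x)
}
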