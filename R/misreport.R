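# Death-misreporting analysis: phrase matching against event narratives and
# the year-by-class misreporting table.
#
# A report is a candidate death when its narrative contains one of a fixed
# list of death phrases; it is *misreported* when such a narrative sits under
# an injury or malfunction classification instead of death. The misreporting
# rate is the percentage of misreported narratives among all death-phrase
# narratives classified as death, injury or malfunction.

#' The default death-phrase list
#'
#' Seven phrases that flag a narrative as describing a patient death. Phrases
#' are matched as contiguous substrings after [normalize_text()]
#' normalization, so e.g. `"PATIENT EXPIRED"` matches inside
#' `"THE PATIENT EXPIRED TWO DAYS LATER"` but not `"THE PATIENT EXPERIENCED
#' CHEST PAIN"`.
#'
#' @return Character vector of normalized phrases.
#' @export
death_terms <- function() {
  normalize_text(c(
    "Patient expired",
    "Patient died",
    "Subsequently expired",
    "Decedent",
    "Time of death",
    "Patients died",
    "Patient later expired"
  ))
}

check_terms <- function(terms) {
  terms <- normalize_text(terms)
  if (!length(terms) || any(!nzchar(terms))) {
    stop("term list must contain at least one non-empty phrase", call. = FALSE)
  }
  terms
}

#' Does a narrative contain a death phrase?
#'
#' Fixed-string substring search of every phrase against each (normalized)
#' narrative. Vectorized over narratives; empty text never matches.
#'
#' @param text Character vector of narratives, normalized as by
#'   [normalize_text()] (the cohort builder already does this).
#' @param terms Phrase list; default [death_terms()].
#' @return Logical vector: `TRUE` where at least one phrase occurs.
#' @seealso [matched_death_terms()] for which phrases matched.
#' @export
#' @examples
#' contains_death_term(c("THE PATIENT EXPIRED AT HOME",
#'                       "THE PATIENT EXPERIENCED CHEST PAIN"))
contains_death_term <- function(text, terms = death_terms()) {
  terms <- check_terms(terms)
  hit <- rep(FALSE, length(text))
  for (tm in terms) hit <- hit | grepl(tm, text, fixed = TRUE)
  hit
}

#' Which death phrases occur in one narrative?
#'
#' @param text A single narrative (normalized).
#' @inheritParams contains_death_term
#' @return Character vector of the phrases found (possibly empty).
#' @export
matched_death_terms <- function(text, terms = death_terms()) {
  stopifnot(length(text) == 1L)
  terms <- check_terms(terms)
  terms[vapply(terms, grepl, logical(1), x = text, fixed = TRUE)]
}

#' Misreporting rate as a percentage
#'
#' `100 * misreport / total`, carried at full precision; an empty
#' denominator yields `NA` (undefined), never 0. Vectorized.
#'
#' @param misreport Count of death-phrase narratives classified as injury or
#'   malfunction.
#' @param total Count of death-phrase narratives classified as death, injury
#'   or malfunction.
#' @return Numeric percentage(s) in `[0, 100]`, `NA` where `total` is 0.
#' @export
#' @examples
#' misreport_rate(293, 4180)
misreport_rate <- function(misreport, total) {
  if (any(misreport < 0 | total < 0)) stop("negative counts", call. = FALSE)
  if (any(misreport > total)) {
    stop("misreport count exceeds total count", call. = FALSE)
  }
  ifelse(total == 0, NA_real_, 100 * misreport / total)
}

#' Tabulate misreported deaths by year and stent class
#'
#' Restricts the cohort to the requested stent classes, flags events whose
#' narrative contains a death phrase, and tabulates — per event-date calendar
#' year and per scope (each class plus their combination) — the misreported
#' count (phrase-matching events classified injury/malfunction), the total
#' count (phrase-matching events of any cohort outcome) and the rate. A
#' totals row per scope sums the yearly cells. An event matching several
#' phrases counts once. Years only partially covered by the window are
#' emitted but flagged `partial`.
#'
#' BVS is excluded from the default scopes: its case counts are negligible
#' and its rates unstable, but passing `scopes = c("BMS", "DES", "BVS")`
#' computes it.
#'
#' @param events Cohort events from [build_cohort()].
#' @param terms Phrase list; default [death_terms()]. Must be non-empty.
#' @param scopes Stent classes to tabulate; default `c("BMS", "DES")`.
#' @param window Study window (drives the year range and the partial-year
#'   flag); defaults to the events' `window` attribute.
#' @return A `misreport_table`: data frame with columns `year` (`NA` on the
#'   totals row), `scope` (`"combined"` or a class), `misreport`, `total`,
#'   `rate_percent`, `partial`; attribute `scopes`.
#' @export
tabulate_misreports <- function(events, terms = death_terms(),
                                scopes = c("BMS", "DES"), window = NULL) {
  terms <- check_terms(terms)
  if (is.null(window)) window <- attr(events, "window")
  if (is.null(window)) window <- default_window()
  window <- check_window(window)

  ev <- events[events$stent_class %in% scopes, , drop = FALSE]
  hit <- contains_death_term(ev$narrative, terms)
  mv <- ev[hit, , drop = FALSE]

  years <- seq(as.integer(format(window[1], "%Y")),
               as.integer(format(window[2], "%Y")))
  partial <- years == years[1] & format(window[1], "%m-%d") != "01-01" |
             years == years[length(years)] & format(window[2], "%m-%d") != "12-31"

  cell <- function(rows) {
    total <- nrow(rows)
    mis <- sum(rows$outcome != "DEATH")
    c(misreport = mis, total = total)
  }

  out <- list()
  for (scope in c("combined", scopes)) {
    sv <- if (scope == "combined") mv else mv[mv$stent_class == scope, , drop = FALSE]
    for (i in seq_along(years)) {
      cc <- cell(sv[sv$year == years[i], , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        year = years[i], scope = scope, misreport = cc[["misreport"]],
        total = cc[["total"]], partial = partial[i], stringsAsFactors = FALSE
      )
    }
    cc <- cell(sv)
    out[[length(out) + 1L]] <- data.frame(
      year = NA_integer_, scope = scope, misreport = cc[["misreport"]],
      total = cc[["total"]], partial = NA, stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, out)
  tab$rate_percent <- misreport_rate(tab$misreport, tab$total)
  tab <- tab[, c("year", "scope", "misreport", "total", "rate_percent", "partial")]
  structure(tab, scopes = scopes, class = c("misreport_table", "data.frame"))
}

#' Each class's share of combined misreports
#'
#' The percentage of all misreported (death-phrase, non-death-classified)
#' narratives contributed by each stent class. Accepts either a
#' [tabulate_misreports()] table or a named vector of per-class misreport
#' counts with an explicit combined total.
#'
#' @param x A `misreport_table`, or a named numeric vector of per-class
#'   misreport counts.
#' @param combined Combined misreport total when `x` is a bare vector;
#'   defaults to `sum(x)`.
#' @return Named numeric percentages; `NA` when the combined total is 0.
#' @export
#' @examples
#' misreport_share_by_class(c(BMS = 86, DES = 206), combined = 293)
misreport_share_by_class <- function(x, combined = NULL) {
  if (inherits(x, "misreport_table")) {
    tot <- x[is.na(x$year), , drop = FALSE]
    combined <- tot$misreport[tot$scope == "combined"]
    x <- stats::setNames(tot$misreport[tot$scope != "combined"],
                         tot$scope[tot$scope != "combined"])
  }
  if (is.null(combined)) combined <- sum(x)
  if (combined == 0) return(stats::setNames(rep(NA_real_, length(x)), names(x)))
  100 * x / combined
}

#' @export
print.misreport_table <- function(x, digits = 2, ...) {
  cat("Misreported deaths by year and stent class\n")
  cat("(misreport = death-phrase narrative classified injury/malfunction)\n\n")
  d <- x
  class(d) <- "data.frame"
  d$rate_percent <- ifelse(is.na(d$rate_percent), NA,
                           round_half_up(d$rate_percent, digits))
  d$year <- ifelse(is.na(d$year), "Total", as.character(d$year))
  d$partial <- ifelse(is.na(d$partial), "", ifelse(d$partial, "partial", ""))
  print(d, row.names = FALSE)
  sh <- misreport_share_by_class(x)
  if (!all(is.na(sh))) {
    cat("\nClass share of combined misreports (%): ",
        paste(names(sh), round_half_up(sh, 1), collapse = "  "), "\n")
  }
  invisible(x)
}
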