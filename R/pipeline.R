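# End-to-end surveillance analysis: read -> assemble -> cohort -> trends ->
# shares -> misreporting, as one classed result object plus a CSV bundle.

#' Run the full stent surveillance analysis
#'
#' Reads a MAUDE-style dataset (master, device and narrative flat files),
#' assembles and deduplicates the reports, builds the death / injury /
#' malfunction cohort for the three stent classes over the study window,
#' bins zero-filled monthly count series and fits a linear trend for every
#' class-by-outcome pair, tabulates class and outcome shares, and computes
#' the death-misreporting table.
#'
#' @param master,device,narrative Paths to the three flat files.
#' @param window Study window; default [default_window()].
#' @param code_map Product-code to stent-class map; default
#'   [default_code_map()].
#' @param injury_tokens Event-type tokens mapped to `INJURY`.
#' @param terms Death-phrase list; default [death_terms()].
#' @param scopes Classes tabulated in the misreporting table.
#' @param strict Abort on malformed input rows instead of skipping them?
#' @return A `stent_surveillance` object: `events`, `exclusions`, `shares`
#'   (a [share_table()]), `series` and `fits` (named `"CLASS.OUTCOME"`
#'   lists), `misreport` (a [tabulate_misreports()] table), `window` and
#'   `meta` (skip and orphan tallies). Methods: `print`, `summary`, `plot`,
#'   `coef`.
#' @seealso [run_pipeline()] to also write the CSV output bundle.
#' @export
stent_surveillance <- function(master, device, narrative,
                               window = default_window(),
                               code_map = default_code_map(),
                               injury_tokens = c("I", "IN", "IL"),
                               terms = death_terms(),
                               scopes = c("BMS", "DES"),
                               strict = FALSE) {
  window <- check_window(window)
  m <- read_maude_file(master, "master", strict = strict)
  d <- read_maude_file(device, "device", strict = strict)
  n <- read_maude_file(narrative, "narrative", strict = strict)

  reports <- assemble_reports(m, d, n)
  dd <- deduplicate(reports)
  cohort <- build_cohort(
    dd$reports, window = window, code_map = code_map,
    injury_tokens = injury_tokens,
    duplicates = dd$removed + attr(reports, "duplicate_master_rows")
  )

  classes <- stent_classes(code_map)
  series <- list()
  fits <- list()
  for (cls in classes) {
    for (oc in cohort_outcomes()) {
      key <- paste(cls, oc, sep = ".")
      s <- bin_monthly(cohort$events, window, stent_class = cls, outcome = oc)
      s$stent_class <- cls
      s$outcome <- oc
      series[[key]] <- s
      fits[[key]] <- fit_linear_trend(s)
    }
  }

  structure(
    list(
      events = cohort$events,
      exclusions = cohort$exclusions,
      shares = outcome_share_table(cohort$events, classes = classes),
      series = series,
      fits = fits,
      misreport = tabulate_misreports(cohort$events, terms = terms,
                                      scopes = scopes, window = window),
      window = window,
      meta = list(
        files = c(master = master, device = device, narrative = narrative),
        skipped = c(master = attr(m, "skipped"), device = attr(d, "skipped"),
                    narrative = attr(n, "skipped")),
        orphans = attr(reports, "orphans")
      )
    ),
    class = "stent_surveillance"
  )
}

#' @export
print.stent_surveillance <- function(x, ...) {
  cat("Stent adverse-event surveillance analysis\n")
  cat("  window: ", format(x$window[1]), " to ", format(x$window[2]),
      " (", n_window_months(x$window), " months)\n", sep = "")
  cat("  cohort: ", nrow(x$events), " events from ",
      x$exclusions$input_reports, " reports\n", sep = "")
  cat("  use summary() for the full report\n")
  invisible(x)
}

#' @export
coef.stent_surveillance <- function(object, ...) {
  t(vapply(object$fits, function(f) {
    c(f$coefficients, r = f$r)
  }, numeric(3)))
}

#' One-page text summary of a surveillance analysis
#'
#' Renders cohort size, class and outcome shares, the fitted trend line and
#' Pearson R for every class-by-outcome series, and the misreporting totals
#' with each class's share of combined misreports. Every number shown also
#' appears in the CSV bundle written by [run_pipeline()].
#'
#' @param x A `stent_surveillance` object.
#' @return Character vector of report lines.
#' @export
render_summary <- function(x) {
  stopifnot(inherits(x, "stent_surveillance"))
  sh <- x$shares
  lines <- c(
    "Stent adverse-event surveillance summary",
    sprintf("Window: %s to %s (%d months)", format(x$window[1]),
            format(x$window[2]), n_window_months(x$window)),
    sprintf("Cohort events: %d (from %d assembled reports)", nrow(x$events),
            x$exclusions$input_reports),
    ""
  )
  if (nrow(x$events) == 0) {
    return(c(lines, "Zero events in cohort; no shares, trends or misreport",
             "rates were computed."))
  }
  lines <- c(lines, "Class shares (%):")
  for (cls in rownames(sh$counts)) {
    lines <- c(lines, sprintf("  %-4s %6d  %s", cls, sh$class_total[[cls]],
                              fmt_share(sh$class_percent[[cls]])))
  }
  lines <- c(lines, "Outcome shares (%):")
  for (oc in colnames(sh$counts)) {
    lines <- c(lines, sprintf("  %-12s %6d  %s", oc, sh$outcome_total[[oc]],
                              fmt_share(sh$outcome_percent[[oc]])))
  }
  lines <- c(lines, "", "Monthly linear trends (cases/month):")
  for (key in names(x$fits)) {
    f <- x$fits[[key]]
    lines <- c(lines, sprintf(
      "  %-16s y = %sx + %s  (R = %s)", key,
      format(round_half_up(f$coefficients[["slope"]], 2)),
      format(round_half_up(f$coefficients[["intercept"]], 1)),
      if (is.na(f$r)) "undefined" else format(round_half_up(f$r, 2))
    ))
  }
  tot <- x$misreport[is.na(x$misreport$year), , drop = FALSE]
  lines <- c(lines, "", "Misreported deaths (death-phrase narratives):")
  for (i in seq_len(nrow(tot))) {
    lines <- c(lines, sprintf(
      "  %-9s %d of %d  (%s%%)", tot$scope[i], tot$misreport[i], tot$total[i],
      if (is.na(tot$rate_percent[i])) "undefined"
      else format(round_half_up(tot$rate_percent[i], 2))
    ))
  }
  shares <- misreport_share_by_class(x$misreport)
  if (!all(is.na(shares))) {
    lines <- c(lines, sprintf(
      "  class share of combined misreports: %s",
      paste(names(shares), paste0(round_half_up(shares, 1), "%"), collapse = ", ")
    ))
  }
  lines
}

#' @export
summary.stent_surveillance <- function(object, ...) {
  structure(render_summary(object), class = "summary.stent_surveillance")
}

#' @export
print.summary.stent_surveillance <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}

#' @export
plot.stent_surveillance <- function(x, ...) {
  fits <- x$fits
  old <- graphics::par(mfrow = c(length(fits) %/% 3, 3), mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(old))
  for (f in fits) plot(f, ...)
  invisible(x)
}

#' Run the analysis and write the CSV output bundle
#'
#' Calls [stent_surveillance()] and writes `shares.csv`,
#' `monthly_counts.csv`, `trend_fits.csv`, `misreport.csv`,
#' `exclusions.csv` and `run.log` into `out_dir`. Outputs are plain CSV and
#' deterministic: the same inputs and configuration produce byte-identical
#' files. The log carries row counts and skip/orphan/exclusion tallies,
#' never narrative text (real narratives can contain sensitive content).
#'
#' @inheritParams stent_surveillance
#' @param out_dir Output directory (created if needed).
#' @return The `stent_surveillance` object, invisibly, with `$paths` set.
#' @export
run_pipeline <- function(master, device, narrative, out_dir, ...) {
  s <- stent_surveillance(master, device, narrative, ...)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }

  sh <- s$shares
  cells <- as.data.frame(as.table(sh$counts), stringsAsFactors = FALSE)
  names(cells) <- c("stent_class", "outcome", "count")
  cells$percent <- as.vector(sh$cell_percent)
  marg <- rbind(
    data.frame(stent_class = rownames(sh$counts), outcome = "Total",
               count = unname(sh$class_total),
               percent = unname(sh$class_percent), stringsAsFactors = FALSE),
    data.frame(stent_class = "Total", outcome = colnames(sh$counts),
               count = unname(sh$outcome_total),
               percent = unname(sh$outcome_percent), stringsAsFactors = FALSE),
    data.frame(stent_class = "Total", outcome = "Total", count = sh$total,
               percent = if (sh$total > 0) 100 else NA_real_,
               stringsAsFactors = FALSE)
  )
  shares_df <- rbind(cells, marg)

  starts <- window_month_starts(s$window)
  monthly <- do.call(rbind, lapply(s$series, function(sr) {
    data.frame(stent_class = sr$stent_class, outcome = sr$outcome,
               month = sr$x, month_start = starts, count = sr$y,
               stringsAsFactors = FALSE)
  }))

  fits_df <- do.call(rbind, lapply(s$fits, function(f) {
    data.frame(stent_class = f$stent_class, outcome = f$outcome,
               intercept = f$coefficients[["intercept"]],
               slope = f$coefficients[["slope"]],
               pearson_r = f$r, n_months = f$n, stringsAsFactors = FALSE)
  }))

  mis <- s$misreport
  class(mis) <- "data.frame"
  mis$year <- ifelse(is.na(mis$year), "Total", as.character(mis$year))

  paths <- c(
    shares = file.path(out_dir, "shares.csv"),
    monthly_counts = file.path(out_dir, "monthly_counts.csv"),
    trend_fits = file.path(out_dir, "trend_fits.csv"),
    misreport = file.path(out_dir, "misreport.csv"),
    exclusions = file.path(out_dir, "exclusions.csv"),
    log = file.path(out_dir, "run.log")
  )
  utils::write.csv(shares_df, paths["shares"], row.names = FALSE, na = "")
  utils::write.csv(monthly, paths["monthly_counts"], row.names = FALSE, na = "")
  utils::write.csv(fits_df, paths["trend_fits"], row.names = FALSE, na = "")
  utils::write.csv(mis, paths["misreport"], row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(s$exclusions), paths["exclusions"],
                   row.names = FALSE, na = "")

  log <- c(
    paste0("window.start=", s$window[1]),
    paste0("window.end=", s$window[2]),
    paste0("input.", names(s$meta$files), "=", basename(s$meta$files)),
    paste0("skipped.", names(s$meta$skipped), "=", s$meta$skipped),
    paste0("orphans.", names(s$meta$orphans), "=", s$meta$orphans),
    paste0("exclusion.", names(s$exclusions$counters),
           "=", unlist(s$exclusions$counters)),
    paste0("reports.assembled=", s$exclusions$input_reports),
    paste0("events.cohort=", nrow(s$events))
  )
  writeLines(log, paths["log"])

  s$paths <- paths
  invisible(s)
}
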