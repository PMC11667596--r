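# Cohort construction: stent-class assignment, outcome mapping, exclusions,
# deduplication, and the exclusion audit log.

#' Product-code map for the three coronary stent classes
#'
#' FDA product codes identify the stent classes: `MAF` bare-metal (BMS),
#' `NIQ` drug-eluting (DES), `PNY` bioresorbable (BVS). The map is total on
#' these three codes and undefined elsewhere.
#'
#' @return Named character vector (names = product codes, values = classes).
#' @export
default_code_map <- function() {
  c(MAF = "BMS", NIQ = "DES", PNY = "BVS")
}

stent_classes <- function(code_map = default_code_map()) {
  unique(unname(code_map))
}

cohort_outcomes <- function() c("MALFUNCTION", "INJURY", "DEATH")

#' Map a raw event-type token to a device outcome
#'
#' MAUDE codes the reporter's outcome classification as a short token:
#' `D` death, `I`/`IN`/`IL` injury, `M` malfunction, `O` other, and `*` (or
#' blank) unknown/missing. Anything unrecognized is `UNKNOWN`. The function
#' is total and vectorized; matching ignores case and surrounding whitespace.
#'
#' @param code Character vector of raw `EVENT_TYPE` tokens.
#' @param injury_tokens Tokens mapped to `INJURY`.
#' @return Character vector over `DEATH`, `INJURY`, `MALFUNCTION`, `OTHER`,
#'   `UNKNOWN`.
#' @export
#' @examples
#' map_outcome(c("D", "IN", "m", "*", ""))
map_outcome <- function(code, injury_tokens = c("I", "IN", "IL")) {
  u <- toupper(trimws(ifelse(is.na(code), "", code)))
  out <- rep("UNKNOWN", length(u))
  out[u == "D"] <- "DEATH"
  out[u %in% toupper(injury_tokens)] <- "INJURY"
  out[u == "M"] <- "MALFUNCTION"
  out[u == "O"] <- "OTHER"
  out
}

#' Stent classes named by a report's product codes
#'
#' Image of the report's product-code set under the class map; codes outside
#' the map contribute nothing. A report naming devices of two classes yields
#' both.
#'
#' @param product_codes Character vector of 3-letter product codes.
#' @param code_map Product-code to class map, see [default_code_map()].
#' @return Sorted character vector of distinct classes (possibly empty).
#' @export
#' @examples
#' assign_classes(c("MAF", "NIQ", "XYZ"))
assign_classes <- function(product_codes, code_map = default_code_map()) {
  sort(unique(unname(code_map[intersect(product_codes, names(code_map))])))
}

report_signature <- function(reports) {
  # All fields except the report key, so manufacturer resubmissions of the
  # same content under a fresh key collapse to one report.
  paste(
    reports$event_type_code,
    ifelse(is.na(reports$event_date), "", format(reports$event_date)),
    ifelse(is.na(reports$received_date), "", format(reports$received_date)),
    vapply(reports$product_codes, paste, character(1), collapse = ","),
    vapply(reports$narratives, paste, character(1), collapse = "\x1f"),
    sep = "\x1e"
  )
}

#' Deduplicate assembled reports
#'
#' Two rules, applied in order: (1) among reports sharing a report key, keep
#' the one with the latest received date (ties or all-missing: first
#' encountered); (2) reports identical in every field except the key are
#' collapsed to the first — late same-key reports are typically amendments,
#' and identical content under distinct keys arises from manufacturer
#' resubmission.
#'
#' @param reports Assembled reports from [assemble_reports()].
#' @return List with `reports` (deduplicated data frame) and `removed`
#'   (number of rows dropped).
#' @export
deduplicate <- function(reports) {
  n0 <- nrow(reports)
  if (n0 == 0L) return(list(reports = reports, removed = 0L))

  keys <- reports$report_key
  if (anyDuplicated(keys)) {
    ukeys <- unique(keys)
    recv <- as.numeric(reports$received_date)
    recv[is.na(recv)] <- -Inf
    pick <- vapply(split(seq_along(keys), factor(keys, levels = ukeys)),
                   function(i) i[which.max(recv[i])], integer(1))
    reports <- reports[sort(pick), , drop = FALSE]
  }
  keep <- !duplicated(report_signature(reports))
  reports <- reports[keep, , drop = FALSE]
  rownames(reports) <- NULL
  list(reports = reports, removed = n0 - nrow(reports))
}

new_exclusion_log <- function(counters, input_reports, n_units, events) {
  structure(
    list(input_reports = input_reports, counters = counters,
         n_units = n_units, events = events),
    class = "exclusion_log"
  )
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("Exclusion log (", x$input_reports, " reports in, ",
      x$events, " events out)\n", sep = "")
  for (nm in names(x$counters)) {
    cat(sprintf("  %-20s %d\n", nm, x$counters[[nm]]))
  }
  invisible(x)
}

#' @export
as.data.frame.exclusion_log <- function(x, ...) {
  data.frame(counter = c(names(x$counters), "events"),
             value = c(unname(unlist(x$counters)), x$events),
             stringsAsFactors = FALSE)
}

#' Build the analysis cohort from assembled reports
#'
#' Expands each deduplicated report into one clean event per assigned stent
#' class, keeping only events classified as death, injury or malfunction
#' whose event date is present and inside the study window. Every exclusion
#' is tallied: reports with no target product code (`non_target_product`),
#' and per (report, class) pair, `unknown_outcome`, `other_outcome`,
#' `missing_event_date` and `out_of_window`. The counters satisfy an
#' accounting identity — counting one unit per (report, matched class) pair
#' and one unit for each classless report, every unit is either an emitted
#' event or lands in exactly one counter.
#'
#' Narratives are normalized here, once: blocks are concatenated with a
#' single space (so no phrase can match across two blocks), uppercased and
#' whitespace-collapsed, making all downstream matching deterministic.
#'
#' @param reports Deduplicated assembled reports (see [deduplicate()]).
#' @param window Study window `c(start, end)`; default [default_window()].
#' @param code_map,injury_tokens Passed to [assign_classes()]/[map_outcome()].
#' @param duplicates Count of reports removed upstream by deduplication,
#'   carried into the log for a complete audit trail.
#' @return List with `events` (data frame: `report_key`, `stent_class`,
#'   `outcome`, `event_date`, `year`, `narrative`; attribute `window`) and
#'   `exclusions` (an `exclusion_log`).
#' @export
build_cohort <- function(reports, window = default_window(),
                         code_map = default_code_map(),
                         injury_tokens = c("I", "IN", "IL"),
                         duplicates = 0L) {
  window <- check_window(window)

  classes <- lapply(reports$product_codes, assign_classes, code_map = code_map)
  k <- lengths(classes)
  outcome <- map_outcome(reports$event_type_code, injury_tokens)
  dt <- reports$event_date

  reason <- rep("keep", nrow(reports))
  reason[outcome == "UNKNOWN"] <- "unknown_outcome"
  reason[outcome == "OTHER"] <- "other_outcome"
  sel <- reason == "keep"
  reason[sel & is.na(dt)] <- "missing_event_date"
  sel <- reason == "keep"
  reason[sel & (dt < window[1] | dt > window[2])] <- "out_of_window"
  reason[k == 0L] <- "non_target_product"

  counters <- list(
    duplicate          = as.integer(duplicates),
    non_target_product = sum(k == 0L),
    unknown_outcome    = sum(k[reason == "unknown_outcome"]),
    other_outcome      = sum(k[reason == "other_outcome"]),
    missing_event_date = sum(k[reason == "missing_event_date"]),
    out_of_window      = sum(k[reason == "out_of_window"])
  )

  keep <- which(reason == "keep")
  idx <- rep(keep, k[keep])
  events <- data.frame(
    report_key  = reports$report_key[idx],
    stent_class = unlist(classes[keep], use.names = FALSE),
    outcome     = outcome[idx],
    event_date  = dt[idx],
    stringsAsFactors = FALSE
  )
  events$year <- as.integer(format(events$event_date, "%Y"))
  blob <- vapply(reports$narratives[keep], function(b) {
    normalize_text(paste(b, collapse = " "))
  }, character(1))
  events$narrative <- blob[match(idx, keep)]
  attr(events, "window") <- window

  log <- new_exclusion_log(
    counters,
    input_reports = nrow(reports),
    n_units = sum(pmax(k, 1L)),
    events = nrow(events)
  )
  list(events = events, exclusions = log)
}
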