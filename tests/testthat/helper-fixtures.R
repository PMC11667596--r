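# Shared fixtures: all inputs are built in code at test time.

# A small, fast study configuration: 24 months, modest intensities.
small_trends <- function() {
  list(
    BMS = list(MALFUNCTION = trend_spec(20, -0.1),
               INJURY      = trend_spec(15, 0),
               DEATH       = trend_spec(8, 0)),
    DES = list(MALFUNCTION = trend_spec(40, 0.5),
               INJURY      = trend_spec(30, -0.2),
               DEATH       = trend_spec(12, 0))
  )
}

small_config <- function(seed = 1, ...) {
  generator_config(
    window = as.Date(c("2013-01-01", "2014-12-31")),
    trends = small_trends(),
    misreport_rate = c(BMS = 0.2, DES = 0.1),
    death_term_frequency = 0.8,
    seed = seed,
    ...
  )
}

# Cohort pipeline on in-memory generator tables (no disk round trip).
cohort_from_events <- function(ev, window, ...) {
  reports <- assemble_reports(ev$master, ev$device, ev$narrative)
  dd <- deduplicate(reports)
  build_cohort(dd$reports, window = window, duplicates = dd$removed, ...)
}

# Hand-built cohort event rows for direct unit tests.
make_events <- function(outcome, narrative, stent_class = "BMS",
                        event_date = as.Date("2013-06-15"),
                        window = as.Date(c("2013-01-01", "2014-12-31"))) {
  n <- max(length(outcome), length(narrative), length(event_date))
  if (length(outcome) == 0) n <- 0L
  ev <- data.frame(
    report_key = sprintf("K%03d", seq_len(n)),
    stent_class = rep_len(stent_class, n),
    outcome = rep_len(outcome, n),
    event_date = rep_len(event_date, n),
    stringsAsFactors = FALSE
  )
  ev$year <- as.integer(format(ev$event_date, "%Y"))
  ev$narrative <- normalize_text(rep_len(narrative, n))
  attr(ev, "window") <- window
  ev
}

# Exclusion-log accounting identity: every (report, matched-class) unit —
# with classless reports counting one unit — is an event or sits in exactly
# one non-duplicate counter.
exclusion_identity_holds <- function(log) {
  cts <- log$counters
  log$n_units == cts$non_target_product + cts$unknown_outcome +
    cts$other_outcome + cts$missing_event_date + cts$out_of_window +
    log$events
}

# Brute-force OLS via the normal equations, independent of lm().
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- n * sum(x^2) - sum(x)^2
  b1 <- (n * sum(x * y) - sum(x) * sum(y)) / sxx
  b0 <- (sum(y) - b1 * sum(x)) / n
  c(intercept = b0, slope = b1)
}

# Brute-force nested-loop join of the three layouts, one result per
# distinct master key.
join_oracle <- function(masters, devices, narratives) {
  lapply(unique(masters$report_key), function(k) {
    rows <- which(masters$report_key == k)
    recv <- as.numeric(masters$received_date[rows])
    recv[is.na(recv)] <- -Inf
    r <- rows[which.max(recv)]
    nn <- narratives[narratives$report_key == k, , drop = FALSE]
    nn <- nn[order(nn$text_key), , drop = FALSE]
    list(
      report_key = k,
      event_type_code = masters$event_type_code[r],
      product_codes = sort(unique(
        devices$product_code[devices$report_key == k])),
      narratives = nn$text
    )
  })
}
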