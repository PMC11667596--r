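# Seeded generator of MAUDE-shaped synthetic datasets with known ground
# truth. The generator is the package's study-condition model: per
# class-by-outcome linear monthly intensities, a report-level death
# misclassification mechanism, death-phrase narrative placement, and
# optional contamination (duplicates, missing dates, unknown outcomes,
# foreign product codes) so the exclusion audit can be exercised.

#' Linear monthly intensity specification
#'
#' Mean monthly report count `mu(x) = max(0, beta0 + beta1 * x)` over month
#' index `x`, with counts drawn Poisson (`dispersion = 1`) or negative
#' binomial with variance `dispersion * mu` (`dispersion > 1`). The
#' overdispersed option exists because real MAUDE series are noisier than
#' Poisson: pure Poisson noise at these means yields month-to-month
#' correlations with the trend line stronger than real extracts show.
#'
#' @param beta0 Mean monthly count at `x = 0` (cases).
#' @param beta1 Mean change per month (cases/month).
#' @param dispersion Variance multiplier, `>= 1`.
#' @return A `trend_spec`.
#' @export
trend_spec <- function(beta0, beta1 = 0, dispersion = 1) {
  stopifnot(beta0 >= 0, dispersion >= 1)
  structure(list(beta0 = beta0, beta1 = beta1, dispersion = dispersion),
            class = "trend_spec")
}

#' Default per-class, per-outcome trend specifications
#'
#' The published malfunction trends for the two major classes (BMS
#' `y = -0.38x + 51.7`, DES `y = 1.5x + 190.1`) are used verbatim. The
#' remaining series have no published equations; their intercepts are set so
#' the mean total over the 110-month window matches the published
#' class-by-outcome totals, and their slopes encode the described behaviour:
#' DES injuries fall at the same magnitude as DES malfunctions rise
#' (slope -1.5), BMS injuries fall steadily, deaths in both classes decline
#' slightly, and the small BVS series are flat.
#'
#' @return Nested list `trends[[class]][[outcome]]` of [trend_spec()]s.
#' @export
default_trends <- function() {
  list(
    BMS = list(
      MALFUNCTION = trend_spec(51.7, -0.38),
      INJURY      = trend_spec(35.1, -0.12),
      DEATH       = trend_spec(7.0, -0.015)
    ),
    DES = list(
      MALFUNCTION = trend_spec(190.1, 1.5),
      INJURY      = trend_spec(321.9, -1.5),
      DEATH       = trend_spec(51.9, -0.09)
    ),
    BVS = list(
      MALFUNCTION = trend_spec(0.28, 0),
      INJURY      = trend_spec(6.65, 0),
      DEATH       = trend_spec(0.87, 0)
    )
  )
}

#' Generator configuration
#'
#' Bundles everything that defines a synthetic dataset. `misreport_rate` is
#' the per-class probability that a death-mechanism report (one whose
#' underlying event is a death) is classified as injury or malfunction
#' instead of death — the misclassification mechanism the misreporting
#' statistic estimates. `death_term_frequency` is the probability that a
#' death-mechanism report's narrative contains a death phrase; narratives of
#' non-death-mechanism reports never do. Defaults reproduce the published
#' study conditions: class rates 16.76% (BMS), 5.68% (DES) and the 7.01%
#' combined rate for BVS, and a 0.66 phrase frequency (the published ratio
#' of death-phrase death narratives to death classifications).
#'
#' Contamination rates are per clean report and inject *additional* rows:
#' full-content duplicates under fresh keys, reports with a blank event
#' date, with an unknown/other outcome token, or with a non-stent product
#' code. Clean ground-truth counts are therefore preserved under
#' contamination, and every injected row is removed by deduplication or
#' lands in one exclusion counter.
#'
#' @param window Study window; default [default_window()].
#' @param trends Nested `trends[[class]][[outcome]]` list; default
#'   [default_trends()].
#' @param misreport_rate Named per-class misclassification probabilities.
#' @param death_term_frequency Probability a death-mechanism narrative
#'   contains a death phrase.
#' @param duplicate_rate,missing_date_rate,unknown_outcome_rate,foreign_product_rate
#'   Contamination probabilities in `[0, 1]`.
#' @param narrative_split_prob Probability a narrative is emitted as two
#'   text blocks instead of one.
#' @param seed Integer seed fixing the dataset bit-for-bit.
#' @return A `generator_config`.
#' @export
generator_config <- function(window = default_window(),
                             trends = default_trends(),
                             misreport_rate = c(BMS = 0.1676, DES = 0.0568,
                                                BVS = 0.0701),
                             death_term_frequency = 0.66,
                             duplicate_rate = 0,
                             missing_date_rate = 0,
                             unknown_outcome_rate = 0,
                             foreign_product_rate = 0,
                             narrative_split_prob = 0.2,
                             seed = 1L) {
  rates <- c(misreport_rate, death_term_frequency, duplicate_rate,
             missing_date_rate, unknown_outcome_rate, foreign_product_rate,
             narrative_split_prob)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]", call. = FALSE)
  if (!all(names(trends) %in% names(misreport_rate))) {
    stop("misreport_rate must name every class in `trends`", call. = FALSE)
  }
  structure(
    list(window = check_window(window), trends = trends,
         misreport_rate = misreport_rate,
         death_term_frequency = death_term_frequency,
         duplicate_rate = duplicate_rate,
         missing_date_rate = missing_date_rate,
         unknown_outcome_rate = unknown_outcome_rate,
         foreign_product_rate = foreign_product_rate,
         narrative_split_prob = narrative_split_prob,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Sample a monthly count series from a trend specification
#'
#' Draws `count[x] ~ Poisson(mu(x))` (or negative binomial with variance
#' `dispersion * mu(x)`) for `x = 0 ... n_months - 1`, where
#' `mu(x) = max(0, beta0 + beta1 * x)`.
#'
#' @param spec A [trend_spec()].
#' @param n_months Number of months.
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @return Integer vector of counts.
#' @export
sample_monthly_counts <- function(spec, n_months, seed = NULL) {
  stopifnot(inherits(spec, "trend_spec"), n_months >= 1)
  x <- seq_len(n_months) - 1
  mu <- pmax(0, spec$beta0 + spec$beta1 * x)
  with_seed(seed, {
    y <- integer(n_months)
    pos <- mu > 0
    if (spec$dispersion == 1) {
      y[pos] <- stats::rpois(sum(pos), mu[pos])
    } else {
      size <- mu[pos] / (spec$dispersion - 1)
      y[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = size)
    }
    y
  })
}

# Benign filler sentences. Deliberately includes near-miss strings
# ("PATIENT EXPERIENCED", "DECENT", "HAD EXPIRED") that must never trip the
# phrase matcher.
narrative_fillers <- function() {
  c(
    "THE DEVICE WAS DEPLOYED WITHOUT COMPLICATION.",
    "THE PATIENT EXPERIENCED CHEST PAIN DURING THE PROCEDURE.",
    "A DECENT ANGIOGRAPHIC RESULT WAS OBSERVED.",
    "THE STENT FAILED TO EXPAND TO NOMINAL DIAMETER.",
    "THE LESION WAS TREATED WITH A SECOND DEVICE.",
    "THE BALLOON RUPTURED DURING DEPLOYMENT.",
    "THE PATIENT WAS DISCHARGED IN STABLE CONDITION.",
    "THE CATHETER LOT HAD EXPIRED PRIOR TO USE.",
    "NO FURTHER PATIENT HARM WAS REPORTED BY THE FACILITY.",
    "THE PHYSICIAN REPORTED DIFFICULTY CROSSING THE LESION."
  )
}

narrative_prefixes <- function() {
  c("IT WAS REPORTED THAT THE ", "PER THE MANUFACTURER THE ",
    "ACCORDING TO THE FACILITY THE ")
}

narrative_suffixes <- function() {
  c(" FOLLOWING THE PROCEDURE.", " AFTER HOSPITAL TRANSFER.",
    " PER THE AVAILABLE RECORDS.")
}

#' Compose a synthetic event narrative
#'
#' Draws filler prose from a template pool; when `force_death_term` is set,
#' embeds exactly one uniformly chosen death phrase in a carrier sentence,
#' otherwise guarantees (checked against the matcher at generation time)
#' that none of the phrases occurs. The filler pool contains deliberate
#' near-miss strings to stress the matcher.
#'
#' @param outcome Outcome label (flavour only; not encoded in the text).
#' @param force_death_term Embed a death phrase?
#' @param terms Phrase list; default [death_terms()].
#' @param seed Optional seed.
#' @return A single narrative string.
#' @export
compose_narrative <- function(outcome = "MALFUNCTION", force_death_term = FALSE,
                              terms = death_terms(), seed = NULL) {
  with_seed(seed, {
    parts <- sample(narrative_fillers(), 2)
    if (force_death_term) {
      phrase <- sample(terms, 1)
      carrier <- paste0(sample(narrative_prefixes(), 1), phrase,
                        sample(narrative_suffixes(), 1))
      parts[2] <- carrier
    }
    text <- paste(parts, collapse = " ")
    ok <- contains_death_term(normalize_text(text), terms) == force_death_term
    stopifnot(ok)
    text
  })
}

# Vectorized narrative construction: returns a data.frame of two text blocks
# per report (block2 possibly empty) plus the single-string form.
compose_narratives <- function(n, has_term, ref_keys, terms, split_prob) {
  fillers <- narrative_fillers()
  block1 <- paste(sample(fillers, n, replace = TRUE),
                  paste0("MFR REFERENCE ", ref_keys, "."))
  block2 <- sample(fillers, n, replace = TRUE)
  if (any(has_term)) {
    k <- sum(has_term)
    block2[has_term] <- paste0(
      sample(narrative_prefixes(), k, replace = TRUE),
      sample(terms, k, replace = TRUE),
      sample(narrative_suffixes(), k, replace = TRUE)
    )
  }
  split <- stats::runif(n) < split_prob
  data.frame(
    block1 = ifelse(split, block1, paste(block1, block2)),
    block2 = ifelse(split, block2, ""),
    stringsAsFactors = FALSE
  )
}

random_dates_in <- function(n, window) {
  window[1] + floor(stats::runif(n) * (as.numeric(window[2] - window[1]) + 1))
}

#' Generate a synthetic report set in memory
#'
#' The core of [generate_dataset()]: realizes monthly counts for every
#' class-by-outcome trend, applies the death-misclassification mechanism,
#' composes narratives, injects contamination and returns the three
#' MAUDE-layout tables together with the ground truth. Fully deterministic
#' under `config$seed`.
#'
#' @param config A [generator_config()].
#' @return List with `master`, `device`, `narrative` (data frames in the
#'   [read_maude_file()] internal layouts) and `truth` (see
#'   [generate_dataset()]).
#' @export
generate_events <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  window <- config$window
  m <- n_window_months(window)
  starts <- window_month_starts(window)
  # day range of each calendar month, clipped to the window
  month_last <- c(starts[-1] - 1, window[2])
  month_first <- starts
  month_first[1] <- window[1]
  terms <- death_terms()
  code_of <- stats::setNames(names(default_code_map()), default_code_map())
  brands <- c("CORONARY STENT SYSTEM A", "CORONARY STENT SYSTEM B",
              "CORONARY STENT SYSTEM C")
  makers <- c("ACME VASCULAR", "NORTHSTAR MEDICAL", "PACIFIC INTERVENTIONAL")

  with_seed(config$seed, {
    rows <- list()
    for (cls in names(config$trends)) {
      rho <- config$misreport_rate[[cls]]
      for (oc in names(config$trends[[cls]])) {
        counts <- sample_monthly_counts(config$trends[[cls]][[oc]], m)
        n <- sum(counts)
        if (n == 0) next
        mon <- rep(seq_len(m), counts)
        death_mech <- oc == "DEATH"
        if (death_mech) {
          flip <- stats::runif(n) < rho
          final <- ifelse(flip, sample(c("INJURY", "MALFUNCTION"), n, replace = TRUE),
                          "DEATH")
          has_term <- stats::runif(n) < config$death_term_frequency
        } else {
          flip <- rep(FALSE, n)
          final <- rep(oc, n)
          has_term <- rep(FALSE, n)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          stent_class = cls, mechanism = oc, outcome = final, month = mon,
          misreported = flip, has_term = has_term, stringsAsFactors = FALSE
        )
      }
    }
    clean <- do.call(rbind, rows)
    n <- nrow(clean)
    span <- as.numeric(month_last[clean$month] - month_first[clean$month])
    clean$event_date <- month_first[clean$month] +
      floor(stats::runif(n) * (span + 1))
    clean$received_date <- clean$event_date + sample(0:60, n, replace = TRUE)
    clean$report_key <- sprintf("MDR%07d", seq_len(n))
    clean$product_code <- unname(code_of[clean$stent_class])
    nar <- compose_narratives(n, clean$has_term, clean$report_key, terms,
                              config$narrative_split_prob)
    clean$block1 <- nar$block1
    clean$block2 <- nar$block2
    injury_token <- function(k) sample(c("I", "IN", "IL"), k, replace = TRUE,
                                       prob = c(0.85, 0.10, 0.05))
    clean$event_type_code <- clean$outcome
    clean$event_type_code[clean$outcome == "DEATH"] <- "D"
    clean$event_type_code[clean$outcome == "MALFUNCTION"] <- "M"
    inj <- clean$outcome == "INJURY"
    clean$event_type_code[inj] <- injury_token(sum(inj))

    # ---- contamination: extra rows on top of the clean set ----
    next_key <- n
    new_keys <- function(k) {
      out <- sprintf("CON%07d", next_key + seq_len(k))
      next_key <<- next_key + k
      out
    }
    extra <- list()
    contamination <- list(duplicate = 0L, missing_date = 0L,
                          unknown_outcome = 0L, other_outcome = 0L,
                          foreign_product = 0L)

    n_dup <- stats::rbinom(1, n, config$duplicate_rate)
    if (n_dup > 0) {
      src <- clean[sample(n, n_dup, replace = TRUE), , drop = FALSE]
      src$report_key <- new_keys(n_dup)  # content identical, fresh key
      extra$dup <- src
      contamination$duplicate <- n_dup
    }

    junk_row <- function(k, product, token, date_missing = FALSE) {
      d <- random_dates_in(k, window)
      keys <- new_keys(k)
      nar <- compose_narratives(k, rep(FALSE, k), keys, terms,
                                config$narrative_split_prob)
      data.frame(
        stent_class = NA_character_, mechanism = "CONTAMINATION",
        outcome = "CONTAMINATION", month = NA_integer_, misreported = FALSE,
        has_term = FALSE,
        event_date = if (date_missing) as.Date(rep(NA, k)) else d,
        received_date = d + sample(0:60, k, replace = TRUE),
        report_key = keys,
        product_code = sample(product, k, replace = TRUE),
        block1 = nar$block1, block2 = nar$block2,
        event_type_code = sample(token, k, replace = TRUE),
        stringsAsFactors = FALSE
      )
    }

    n_miss <- stats::rbinom(1, n, config$missing_date_rate)
    if (n_miss > 0) {
      extra$miss <- junk_row(n_miss, names(default_code_map()),
                             c("D", "I", "M"), date_missing = TRUE)
      contamination$missing_date <- n_miss
    }
    n_unk <- stats::rbinom(1, n, config$unknown_outcome_rate)
    if (n_unk > 0) {
      r <- junk_row(n_unk, names(default_code_map()), c("*", "", "O"))
      extra$unk <- r
      contamination$unknown_outcome <- sum(r$event_type_code != "O")
      contamination$other_outcome <- sum(r$event_type_code == "O")
    }
    n_for <- stats::rbinom(1, n, config$foreign_product_rate)
    if (n_for > 0) {
      extra$foreign <- junk_row(n_for, c("DYB", "OTW", "MND"), c("D", "I", "M"))
      contamination$foreign_product <- n_for
    }

    all_rows <- rbind(clean, do.call(rbind, unname(extra)))

    # ---- flat-file tables ----
    master <- data.frame(
      report_key = all_rows$report_key,
      event_type_code = all_rows$event_type_code,
      event_date = all_rows$event_date,
      received_date = all_rows$received_date,
      stringsAsFactors = FALSE
    )
    device <- data.frame(
      report_key = all_rows$report_key,
      product_code = all_rows$product_code,
      brand_name = sample(brands, nrow(all_rows), replace = TRUE),
      manufacturer = sample(makers, nrow(all_rows), replace = TRUE),
      stringsAsFactors = FALSE
    )
    two <- nzchar(all_rows$block2)
    narrative <- data.frame(
      report_key = c(all_rows$report_key, all_rows$report_key[two]),
      text_key = c(rep("T0001", nrow(all_rows)), rep("T0002", sum(two))),
      text_type_code = "D",
      text = c(all_rows$block1, all_rows$block2[two]),
      stringsAsFactors = FALSE
    )

    # ---- ground truth ----
    cls_lv <- names(config$trends)
    oc_lv <- cohort_outcomes()
    counts <- as.data.frame(table(
      stent_class = factor(clean$stent_class, cls_lv),
      outcome = factor(clean$outcome, oc_lv),
      month = factor(clean$month, seq_len(m))
    ), stringsAsFactors = FALSE)
    names(counts)[4] <- "count"
    counts$month <- as.integer(counts$month) - 1L  # 0-based, matches bin_monthly

    cm <- clean[clean$has_term & clean$mechanism == "DEATH", , drop = FALSE]
    cm$year <- as.integer(format(cm$event_date, "%Y"))
    yrs <- sort(unique(cm$year))
    mis <- do.call(rbind, lapply(yrs, function(yy) {
      do.call(rbind, lapply(cls_lv, function(cc) {
        s <- cm[cm$year == yy & cm$stent_class == cc, , drop = FALSE]
        data.frame(year = yy, stent_class = cc,
                   misreport = sum(s$misreported), total = nrow(s),
                   stringsAsFactors = FALSE)
      }))
    }))

    truth <- structure(
      list(
        monthly_counts = counts,
        totals = with(counts, tapply(count, list(stent_class, outcome), sum)),
        misreport = mis,
        n_clean_reports = n,
        contamination = contamination,
        config = config
      ),
      class = "maude_ground_truth"
    )
    list(master = master, device = device, narrative = narrative, truth = truth)
  })
}

#' @export
print.maude_ground_truth <- function(x, ...) {
  cat("Synthetic MAUDE ground truth: ", x$n_clean_reports, " clean reports, ",
      sum(unlist(x$contamination)), " contaminated rows\n", sep = "")
  print(x$totals)
  invisible(x)
}

#' Generate a synthetic MAUDE-shaped dataset on disk
#'
#' Realizes a dataset from a [generator_config()], writes the three
#' pipe-delimited flat files plus ground-truth CSVs and a config echo into
#' `dir`, and returns the ground truth. With contamination off, the files
#' parse in strict mode and the pipeline reproduces the ground truth
#' exactly.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `files` (named paths: master, device,
#'   narrative) and `truth`: `monthly_counts` (class, outcome, 0-based
#'   month, count), `totals`, `misreport` (year, class, misreport numerator,
#'   death-phrase denominator), `n_clean_reports`, `contamination`, and the
#'   config echo.
#' @export
generate_dataset <- function(config, dir) {
  ev <- generate_events(config)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir, call. = FALSE)
  }
  files <- c(master = file.path(dir, "master.txt"),
             device = file.path(dir, "device.txt"),
             narrative = file.path(dir, "foitext.txt"))
  write_maude_file(ev$master, files["master"], "master")
  write_maude_file(ev$device, files["device"], "device")
  write_maude_file(ev$narrative, files["narrative"], "narrative")
  utils::write.csv(ev$truth$monthly_counts,
                   file.path(dir, "ground_truth_counts.csv"), row.names = FALSE)
  utils::write.csv(ev$truth$misreport,
                   file.path(dir, "ground_truth_misreport.csv"), row.names = FALSE)
  cfg <- ev$truth$config
  echo <- c(
    paste0("window.start=", cfg$window[1]),
    paste0("window.end=", cfg$window[2]),
    paste0("seed=", cfg$seed),
    paste0("death_term_frequency=", cfg$death_term_frequency),
    paste0("misreport_rate.", names(cfg$misreport_rate), "=", cfg$misreport_rate),
    paste0("duplicate_rate=", cfg$duplicate_rate),
    paste0("missing_date_rate=", cfg$missing_date_rate),
    paste0("unknown_outcome_rate=", cfg$unknown_outcome_rate),
    paste0("foreign_product_rate=", cfg$foreign_product_rate)
  )
  writeLines(echo, file.path(dir, "config_echo.txt"))
  invisible(list(files = files, truth = ev$truth))
}
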