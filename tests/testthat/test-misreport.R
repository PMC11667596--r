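# Death-phrase matching and the misreporting table.

test_that("phrase matching hits embedded phrases and rejects near-misses", {
  expect_true(contains_death_term("THE PATIENT EXPIRED TWO DAYS LATER"))
  expect_equal(matched_death_terms("THE PATIENT EXPIRED TWO DAYS LATER"),
               "PATIENT EXPIRED")
  expect_false(contains_death_term(""))
  expect_equal(matched_death_terms(""), character(0))
  expect_true(contains_death_term("BOTH PATIENTS DIED AT THE SITE"))
  expect_equal(matched_death_terms("BOTH PATIENTS DIED AT THE SITE"),
               "PATIENTS DIED")

  # zero false negatives: every phrase embedded in filler must match
  for (tm in death_terms()) {
    blob <- normalize_text(paste("THE DEVICE WAS DEPLOYED.", tm,
                                 "WAS DOCUMENTED."))
    expect_true(contains_death_term(blob))
    expect_true(tm %in% matched_death_terms(blob))
  }

  # zero false positives on the near-miss suite
  near_misses <- c(
    "THE PATIENT EXPERIENCED CHEST PAIN",
    "A DECENT ANGIOGRAPHIC RESULT WAS OBSERVED",
    "THE CATHETER LOT HAD EXPIRED PRIOR TO USE",
    "THE PATIENT DIETED BEFORE THE PROCEDURE",
    "PATIENTS DENIED ANY SYMPTOMS",
    "THE TIME OF DEPLOYMENT WAS NOT RECORDED",
    "THE PATIENT LATER RECOVERED FULLY",
    "SUBSEQUENTLY THE DEVICE WAS EXPLANTED"
  )
  expect_false(any(contains_death_term(near_misses)))

  expect_error(contains_death_term("X", terms = character(0)), "non-empty")
})

test_that("misreporting rates follow the count ratio with safe edge cases", {
  expect_equal(round(misreport_rate(293, 4180), 2), 7.01)
  expect_equal(round(misreport_rate(86, 513), 2), 16.76)
  expect_equal(round(misreport_rate(206, 3627), 2), 5.68)
  expect_equal(misreport_rate(0, 50), 0)
  expect_true(is.na(misreport_rate(0, 0)))
  expect_error(misreport_rate(5, 3), "exceeds")
  expect_error(misreport_rate(-1, 3), "negative")
})

test_that("a hand-enumerated cohort tabulates cell by cell", {
  ev <- make_events(
    outcome = c("DEATH", "DEATH", "DEATH", "INJURY", "INJURY", "MALFUNCTION"),
    narrative = c("THE PATIENT EXPIRED.", "TIME OF DEATH WAS 0400.",
                  "THE DECEDENT WAS TRANSFERRED.", "THE PATIENT DIED LATER.",
                  "SUBSEQUENTLY EXPIRED AT HOME.", "NO HARM OCCURRED."),
    stent_class = c("BMS", "BMS", "DES", "DES", "BMS", "BMS")
  )
  tab <- tabulate_misreports(ev)
  combined <- tab[tab$scope == "combined" & !is.na(tab$year) & tab$year == 2013, ]
  expect_equal(combined$misreport, 2L)
  expect_equal(combined$total, 5L)
  expect_equal(combined$rate_percent, 40)
  tot_bms <- tab[tab$scope == "BMS" & is.na(tab$year), ]
  expect_equal(tot_bms$misreport, 1L)  # the SUBSEQUENTLY EXPIRED injury
  expect_equal(tot_bms$total, 3L)
  # totals rows equal column sums of the yearly cells
  for (sc in c("combined", "BMS", "DES")) {
    yearly <- tab[tab$scope == sc & !is.na(tab$year), ]
    total <- tab[tab$scope == sc & is.na(tab$year), ]
    expect_equal(sum(yearly$misreport), total$misreport)
    expect_equal(sum(yearly$total), total$total)
  }
})

test_that("a cohort without death phrases yields empty, undefined cells", {
  ev <- make_events(c("INJURY", "MALFUNCTION"), "ROUTINE DEPLOYMENT.")
  tab <- tabulate_misreports(ev)
  expect_true(all(tab$misreport == 0))
  expect_true(all(tab$total == 0))
  expect_true(all(is.na(tab$rate_percent)))
  expect_true(all(is.na(misreport_share_by_class(tab))))
})

test_that("BVS is excluded from the default scopes but computable", {
  ev <- make_events(c("INJURY", "DEATH"), "THE PATIENT EXPIRED.",
                    stent_class = c("BVS", "BVS"))
  tab <- tabulate_misreports(ev)
  expect_false("BVS" %in% tab$scope)
  expect_equal(tab$total[tab$scope == "combined" & is.na(tab$year)], 0L)
  tab3 <- tabulate_misreports(ev, scopes = c("BMS", "DES", "BVS"))
  expect_equal(tab3$total[tab3$scope == "BVS" & is.na(tab3$year)], 2L)
  expect_equal(tab3$misreport[tab3$scope == "BVS" & is.na(tab3$year)], 1L)
})

test_that("adding a phrase never decreases any cell and results are deterministic", {
  cfg <- small_config(seed = 55)
  cc <- cohort_from_events(generate_events(cfg), cfg$window)
  terms <- death_terms()
  sub <- terms[1:3]
  t_sub <- tabulate_misreports(cc$events, terms = sub)
  t_all <- tabulate_misreports(cc$events, terms = terms)
  expect_true(all(t_all$misreport >= t_sub$misreport))
  expect_true(all(t_all$total >= t_sub$total))
  expect_true(all(t_all$misreport <= t_all$total))
  # identical cohort + terms -> identical table, byte for byte
  expect_identical(serialize(t_all, NULL),
                   serialize(tabulate_misreports(cc$events, terms = terms), NULL))
  expect_error(tabulate_misreports(cc$events, terms = character(0)), "non-empty")
})

test_that("the tabulated combined rate recovers the generator's rate", {
  # one replicate at rho = 0.10 with a large death series; the acceptance
  # suite runs the full 100-replicate coverage study
  cfg <- generator_config(
    window = as.Date(c("2013-01-01", "2013-12-31")),
    trends = list(BMS = list(DEATH = trend_spec(60, 0)),
                  DES = list(DEATH = trend_spec(60, 0))),
    misreport_rate = c(BMS = 0.10, DES = 0.10),
    death_term_frequency = 0.9, seed = 77
  )
  ev <- generate_events(cfg)
  cc <- cohort_from_events(ev, cfg$window)
  tab <- tabulate_misreports(cc$events)
  tot <- tab[tab$scope == "combined" & is.na(tab$year), ]
  expect_gt(tot$total, 500)
  lo <- qbinom(0.025, tot$total, 0.10)
  hi <- qbinom(0.975, tot$total, 0.10)
  expect_gte(tot$misreport, lo)
  expect_lte(tot$misreport, hi)
  # tabulated cells equal generator bookkeeping exactly
  truth <- ev$truth$misreport
  expect_equal(tot$misreport, sum(truth$misreport))
  expect_equal(tot$total, sum(truth$total))
})

test_that("class shares of combined misreports follow the printed convention", {
  sh <- misreport_share_by_class(c(BMS = 86, DES = 206), combined = 293)
  expect_equal(round(unname(sh), 1), c(29.4, 70.3))
  sh <- misreport_share_by_class(c(BMS = 0, DES = 10))
  expect_equal(unname(sh), c(0, 100))
  set.seed(3)
  for (i in 1:10) {
    x <- c(BMS = rpois(1, 40), DES = rpois(1, 160))
    if (sum(x) == 0) next
    expect_equal(sum(misreport_share_by_class(x)), 100)
  }
})
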