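# stentwatch

Post-market surveillance of coronary stent adverse-event reports, as
distributed in the pipe-delimited flat-file dialect of the FDA MAUDE
(Manufacturer and User Facility Device Experience) database.

Coronary stents come in three classes — bare-metal (BMS, FDA product code
`MAF`), drug-eluting (DES, `NIQ`) and bioresorbable (BVS, `PNY`) — and every
adverse-event report carries a device outcome: death (`D`), injury
(`I`/`IN`/`IL`), malfunction (`M`), other (`O`) or unknown (`*`). stentwatch
turns a raw three-file MAUDE extract (master events, devices, narratives,
joined on `MDR_REPORT_KEY`) into:

- an audited **analysis cohort**: outcome mapping, stent-class assignment,
  deduplication, and per-rule exclusion counters that satisfy an exact
  accounting identity;
- **monthly trend analysis**: zero-filled monthly count series per
  class × outcome (binned by *event* date, not report date), ordinary least
  squares fits `y = β₁x + β₀` with Pearson *R*, slope-to-intercept ratios
  and cross-class slope magnitude ratios;
- a **share table** of counts and percentages by class and outcome;
- a **death-misreporting table**: narratives containing one of seven fixed
  death phrases ("PATIENT EXPIRED", "PATIENT DIED", "SUBSEQUENTLY EXPIRED",
  "DECEDENT", "TIME OF DEATH", "PATIENTS DIED", "PATIENT LATER EXPIRED")
  that are nonetheless classified as injury or malfunction, per year and
  class, with the misreporting rate
  `100 · misreported / all death-phrase narratives`;
- a seeded **synthetic-data generator** that emits MAUDE-shaped flat files
  with known ground truth (linear monthly intensities, a report-level death
  misclassification mechanism with rate ρ, and optional contamination), so
  the entire pipeline is testable without downloading anything.

## Worked example

Generate a synthetic decade of reports under the default study conditions
and analyze it end to end:

```r
library(stentwatch)

cfg <- generator_config(seed = 2011)        # Jan 2011 - Feb 2020, 110 months
g   <- generate_dataset(cfg, "demo")
s   <- run_pipeline("demo/master.txt", "demo/device.txt", "demo/foitext.txt",
                    "demo/out")
summary(s)
```

```
Stent adverse-event surveillance summary
Window: 2011-01-01 to 2020-02-29 (110 months)
Cohort events: 69594 (from 69594 assembled reports)

Class shares (%):
  BMS    7201  10.3
  DES   61537  88.4
  BVS     856  1.23
Outcome shares (%):
  MALFUNCTION   33598  48.3
  INJURY        30624  44
  DEATH          5372  7.72

Monthly linear trends (cases/month):
  BMS.MALFUNCTION  y = -0.35x + 50.3  (R = -0.91)
  ...
  DES.MALFUNCTION  y = 1.53x + 190.5  (R = 0.94)
  ...

Misreported deaths (death-phrase narratives):
  combined  270 of 3707  (7.28%)
  BMS       86 of 437  (19.68%)
  DES       184 of 3270  (5.63%)
  class share of combined misreports: BMS 31.9%, DES 68.1%
```

DES dominates the report volume (88.4%), BMS malfunctions decline while DES
malfunctions grow, and about 7% of death-phrase narratives are filed under
a less severe outcome. The fitted trend objects support the comparison
statistics directly:

```r
bms <- s$fits[["BMS.MALFUNCTION"]]
des <- s$fits[["DES.MALFUNCTION"]]
slope_to_intercept_ratio(bms)   # -0.0069  (relative monthly decline)
slope_to_intercept_ratio(des)   #  0.0080  (same magnitude, opposite sign)
magnitude_ratio(des, bms)       #  4.40    (DES growth ~4x the BMS decline)
```

`run_pipeline()` also writes `shares.csv`, `monthly_counts.csv`,
`trend_fits.csv`, `misreport.csv`, `exclusions.csv` and `run.log`. A thin
command-line wrapper with `generate` / `analyze` / `summary` verbs lives in
`inst/scripts/stentwatch.R`.

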