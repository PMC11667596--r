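Package: stentwatch
Title: Post-Market Surveillance Trends for Coronary Stent Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for post-market surveillance of coronary stent adverse event
    reports distributed in the pipe-delimited flat-file dialect of the FDA
    MAUDE (Manufacturer and User Facility Device Experience) database. Reads
    and joins master, device and narrative report files; builds an analysis
    cohort of bare-metal (BMS), drug-eluting (DES) and bioresorbable (BVS)
    stent events classified as death, injury or malfunction, with an audited
    exclusion log; bins events into zero-filled monthly count series and fits
    linear trends with Pearson correlations; tabulates device and outcome
    shares; and estimates death-misreporting rates by matching a fixed list of
    death phrases against event narratives. Includes a seeded generator of
    MAUDE-shaped synthetic datasets with known ground truth so the whole
    pipeline is testable without access to the live database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
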