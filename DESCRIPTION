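Package: changescape
Title: Change Budgets, Systematic Transition Signals and Zonal Dynamics
    for Categorical Land-Cover Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analyse change between pairs of co-registered categorical
    land-cover maps. Builds time-1 to time-2 cross-tabulation (transition)
    matrices and per-class change budgets (persistence, gross gain, gross
    loss, net change, swap and total change); detects systematic versus
    random inter-category transitions by comparing observed transition
    shares with their expectations under a random process of gain or loss
    (deviations D and prevalence-corrected ratios R); and computes a
    zone-level land-cover change dynamic index (LUCDI) with
    kernel-smoothed intensity surfaces. A seeded synthetic-landscape
    generator (Markov per-pixel transitions, spatial clustering, Voronoi
    zones) provides known ground truth for validation, and two published
    six-class transition matrices for the periods 1992-2000 and 2000-2013
    ship as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
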