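Package: pbapr
Title: Single-Particle Fluorescent Bioaerosol Analysis for Ship-Based
    Marine Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for ultraviolet light-induced fluorescence
    (UV-LIF) single-particle bioaerosol measurements collected from a ship,
    of the kind produced by a wideband integrated bioaerosol sensor (WIBS).
    Derives fluorescence detection thresholds from forced-trigger background
    records, classifies particles into fluorescent and hyper-fluorescent
    tiers and the seven-way ABC channel-combination classes, computes the
    channel B-to-A fluorescence ratio (an approximate humification index),
    segregates ship-track data into pristine-marine and terrestrially
    influenced subsets by distance to land, and provides the paired-sample
    correlation machinery (subsampling bootstrap, permutation p-values)
    used to relate fluorescent particle fractions to sea spray proxies and
    seawater biota. A synthetic campaign generator with known ground truth
    makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    geosphere,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
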