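Package: meiorec
Title: Meiotic Recombination Activity and 3D Chromatin Organization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of meiotic three-dimensional chromatin
    organization and recombination activity. Derives per-bin Hi-C metrics
    (cis/total contact ratio, A/B compartment scores via fine-grain
    eigendecomposition of 10-Mb chunks, insulation scores, FIRE-style
    near-cis interaction scores, contact-probability P(s) curves with
    compartment masking and derivative-maximum loop-length estimates),
    builds a crossover-score genetic map from crossover resolution
    intervals, partitions PRDM9 and DSB hotspots into activity quartiles
    with enrichment and significance summaries, computes symmetric-averaged
    track profiles and observed/expected contact pileups with bootstrap
    confidence intervals, and fits forward-selection linear models of DSB
    and crossover likelihood on principal components of chromatin features.
    Includes a seeded synthetic-genome generator emulating meiotic
    checkerboard compartment structure, compartment-specific loop-size
    shoulders in the distance decay, and recombination peak/crossover sets
    with known ground truth, plus an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
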