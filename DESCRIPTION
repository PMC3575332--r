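Package: maskovr
Title: Genome-Independent Genotype Imputation and Linkage Map Statistics
    for Pseudo-Testcross Progenies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Imputation and error correction of marker-by-individual
    genotype matrices from genotyping-by-sequencing of two-parent
    outcrossing (CP) progenies, without a reference genome.  Implements the
    Maskov three-pass algorithm (missing-value compression, recombination
    edge detection by convolution with an antisymmetric first-derivative
    mask, winner-take-all block filling), together with supporting
    map-building statistics: segregation-class filtering, genotype binning,
    recombination counting, two-point recombination fractions and LOD
    scores, single-linkage grouping, Kosambi map distances, and a
    chi-squared segregation-distortion scan.  A synthetic-progeny simulator
    with known crossovers, GBS-like missingness and genotyping error
    provides truth sets for recovery testing, and a command-line front end
    exposes the full simulate/impute/stats pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
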