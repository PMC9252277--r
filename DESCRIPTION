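Package: lshaped
Title: L-Shaped Max-Min Selection for Multitrait Genomic Selection
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Exact solvers and simulation tools for multitrait genomic
    selection. Implements classical weighted-sum index selection and the
    L-shaped (max-min, Chebyshev-type) selection of breeding parents on
    normalized genetic values, together with Pareto-frontier utilities
    (dominance filtering, supported/convex efficient frontier, weight-region
    decomposition for two traits), two population-level performance measures
    (Pareto optimality gap and diversity), a recurrent biparental breeding
    simulator with meiosis under a recombination map, and generators for
    synthetic maize-like genotype, effect and recombination data. File
    formats (TSV dialects, phased VCF input) and a command-line interface
    are included.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    quadprog,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
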