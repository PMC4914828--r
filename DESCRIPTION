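Package: dyadkin
Title: Population-Epigenetic Kinetics of CpG Dyad Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete-generation population-epigenetic model of global DNA
    demethylation at CpG dyad resolution. Tracks the six unordered dyad
    states over unmethylated, 5-methylcytosine and 5-hydroxymethylcytosine
    strands across cell divisions, driven by de novo methylation (p1),
    maintenance methylation (p2) and oxidative conversion to 5hmC (p3).
    Provides closed-form steady states, minimum-mean-square-error grid-search
    parameter estimation with error-surface export and local-minima
    (identifiability) analysis, knockout and vitamin-C scenario predictions,
    and synthetic-data generators emulating LC-MS global 5mC/5hmC time
    courses and hairpin-bisulfite dyad count tables, including a stochastic
    per-dyad simulator used as a brute-force oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
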