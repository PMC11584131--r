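Package: remede
Title: Stochastic Models of Self-Excising X-Linked Homing Gene Drives
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and analysis of CRISPR homing gene drives
    that remove themselves by single-strand annealing (SSA) between
    engineered direct repeats. Implements a per-allele germline
    repair-outcome model (homing, NHEJ resistant-allele formation, SSA
    excision with marker retention, second-site disruption), discrete
    generation Wright-Fisher style population dynamics at an X-linked
    locus with phenotype-dependent mating costs, emulation of
    population-cage trial protocols with score/seed pool splitting,
    tabulation and maximum-likelihood calibration of pair-mated cross
    outcome tables, and generators for synthetic cross, cage, and
    courtship-assay datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
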