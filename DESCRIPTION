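Package: neurocascade
Title: Newborn Neuron and Astrocyte Dynamics in the Adult Hippocampal Niche
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of adult hippocampal
    neurogenesis and astrogenesis from BrdU pulse-and-chase cell counts.
    Implements a seedable Marsaglia polar normal sampler, constrained
    Monte-Carlo simulation of nested BrdU+ cohorts (GFAP-locked or
    NeuN-locked marker allocation), longitudinal exponential-plateau and
    transversal exponential decay fitting with AICc model comparison,
    lineage yield statistics (neurogenic and astrogenic yield,
    neuron-to-astrocyte ratio), and a bisection search over extra-survival
    allocation scenarios. A synthetic-data generator with known ground
    truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
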