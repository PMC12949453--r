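Package: dcepref
Title: Discrete Choice Experiment Design, Simulation and Preference Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stated-preference studies of treatment attributes:
    construction of D-efficient, blocked discrete choice experiment (DCE)
    designs with attention-check tasks; a random-utility simulator for
    synthetic respondent cohorts, choices and drug rankings; mixed logit
    estimation by simulated maximum likelihood with Halton draws (with a
    multinomial logit special case); Borda-style weighted rank-preference
    scoring; coefficient-range relative importance of attributes; subgroup
    comparison by z tests on separately fitted models; and subsample
    stability checking. Includes an end-to-end pipeline from design through
    report with reproducible, seeded text outputs.
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
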