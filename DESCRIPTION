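Package: mgsalloc
Title: Mating-Group Size and Sex Allocation in Sessile Hermaphrodites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for sex allocation in aggregating barnacles
    and other sessile simultaneous hermaphrodites that mate unilaterally by
    penis. From individual positions and penis lengths it builds the directed
    penis-reach graph on each substrate shell, derives mating group size in
    the male role (MGSm, potential sperm recipients plus one) and in the
    female role (MGSf, potential sperm donors plus one), assembles variable
    and fixed reproductive-cost aggregates and a sex-allocation index, and
    fits shell random-intercept linear mixed models with collinearity
    diagnostics and likelihood-ratio model comparison. A seeded synthetic
    population generator with known ground truth makes every stage testable
    without field data and supports parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
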