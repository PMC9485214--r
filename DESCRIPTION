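Package: lifevar
Title: Abridged Life Tables, Lifespan Variation, and Mortality Inequalities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing abridged period life tables from stratified
    vital-registration counts and for quantifying mortality inequalities between
    population subgroups. Computes life expectancy and lifespan variation (the
    standard deviation and coefficient of variation of age at death) at any
    grid age, attaches Monte-Carlo (parametric Poisson bootstrap) standard
    errors and confidence intervals, and summarises absolute and relative
    inequalities by race/ethnicity, gender, urbanicity, and period. Includes a
    Siler-model synthetic vital-registration generator with exact ground truth
    so the whole pipeline can be validated end to end without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
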