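Package: busulpk
Title: Semi-Mechanistic Population Pharmacokinetics of Intravenous
    Busulfan in Children
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-mechanistic population pharmacokinetic modelling of
    intravenous busulfan in paediatric haematopoietic cell transplant
    recipients. Implements a two-compartment infusion model whose
    clearance is modulated by a depletable, resynthesised glutathione
    pool, with normal-fat-mass allometry, postmenstrual-age maturation
    and glutathione S-transferase activity as covariates; first-order
    conditional estimation with interaction (FOCE-I) for nonlinear
    mixed-effects fitting; model qualification via prediction-corrected
    visual predictive checks, nonparametric bootstrap and prediction
    metrics; and Monte-Carlo virtual trials with probability-of-target
    attainment dose optimisation. A synthetic-data generator emulating
    the paediatric study design makes the whole pipeline testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
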