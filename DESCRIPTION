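Package: allelometa
Title: Phylogenetic Bayesian Meta-Analysis of Grass Allelopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of plant allelopathy experiments, built
    around study-level control/treatment comparisons of germination and growth.
    Computes small-sample-corrected delta log response ratios with sampling
    variances and a Geary normality screen, imputes missing dose by
    predictive-mean-matching chained equations, and fits a non-linear
    two-component ("study" + "species") Bayesian hierarchical model with a
    Student-t measurement-error likelihood, phylogenetically structured species
    random effects, and a low-rank penalized smooth of log-scaled phylogenetic
    distance. Includes directional posterior hypothesis tests for the Novel
    Weapons, Biotic Resistance and Phylogenetic Distance hypotheses, variance
    decomposition, PSIS-LOO/WAIC model comparison, Egger regression and
    year-of-publication publication-bias diagnostics, an a-priori
    random-effects power calculator, and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    mgcv,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
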