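Package: surromix
Title: Mixture-of-Regressions Risk Scores for Partial Surrogate Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Risk-score modelling when the outcome used for model training is
    a partial surrogate: a readily measured stand-in that tracks the clinical
    target only in a latent subpopulation and is noise in the rest. Provides
    an EM-fitted mixture of linear regressions with unconstrained component
    variances ('mixlm'), post hoc identification of the informative component
    and its risk score, discrimination evaluation against the target outcome
    (AUC with paired placement-value tests, Spearman's rho with permutation
    comparison, concordance probability, inverse-probability-of-observation
    weighted AUC sweeps over outcome cutoffs), a synthetic cohort generator
    emulating a perioperative acute kidney injury cohort, and end-to-end
    simulation studies comparing pooled linear and mixture risk scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, survival
Suggests: testthat (>= 3.0.0), jsonlite, optparse, pROC, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
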