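Package: tapb
Title: Target Prior Bias Diagnosis and Interventional Debiasing for
    Drug-Target Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing and alleviating target prior bias in
    sequence-based drug-target interaction (DTI) prediction. Provides
    per-sequence prior-tendency statistics with a label permutation test,
    counter-prior training-set constructions (drug-biased and balanced
    re-splits), amino-acid randomization of residue feature matrices,
    masked-language-model corruption of SMILES tokens, and the TAPB model:
    a dual-tower transformer with a confounder alignment module and
    backdoor-adjusted prediction P(Y|D,do(T)) over a K-Means confounder
    dictionary. Includes a synthetic biased-DTI generator, a training and
    evaluation harness with Youden-index thresholding, and a random-feature
    bias probe.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
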