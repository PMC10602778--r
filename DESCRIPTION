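Package: remitcf
Title: Counterfactual Explanation of Remission Prognosis Models in First-Episode Psychosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multicenter first-episode-psychosis cohorts with the
    attrition funnel, mixed-type baseline measures, 48 binary psychiatric
    comorbidity interview items and repeated symptom-scale visits of an
    antipsychotic switching trial; trains a recurrent multi-modal neural
    classifier of symptomatic remission; and explains it with single-flip
    counterfactuals. Per-patient feature-importance maps (the change in
    predicted remission probability when one comorbidity item is flipped) are
    summarised at the group level with Wilcoxon rank-sum tests against a
    bootstrapped null distribution, Bonferroni correction and rank-sum r
    effect sizes, and clustered with Ward agglomerative linkage to find
    patient subgroups with distinct comorbidity-effect profiles. Includes
    repeated stratified k-fold and leave-one-site-out cross-validation with
    AUC, balanced accuracy, sensitivity and specificity, and an ablation
    contrast of models with and without the comorbidity items.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
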