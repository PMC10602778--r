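# remitcf

Counterfactual explanation of remission prognosis models in first-episode
psychosis.

## What problem this solves, and for whom

Prognostic classifiers for schizophrenia-spectrum disorders increasingly
ingest psychiatric comorbidity indicators — the 48 binary yes/no items of
the MINI-PLUS structured interview (schizophrenia-spectrum modules removed)
— alongside demographics, clinical scales and repeated symptom measurements.
For clinical use the question is not only *whether* the classifier predicts
symptomatic remission, but *how each comorbidity moves an individual
patient's prediction*. `remitcf` is aimed at methods researchers in
precision psychiatry and biostatistics: it implements, end to end and under
test, a pipeline that

1. **simulates** multicenter first-episode-psychosis cohorts with the
   structure of a two-phase antipsychotic switching trial (attrition funnel
   446 → 371 → 72 → 66, mixed-type baseline features with missingness,
   correlated comorbidity items, PANSS/PSP/CGI visit trajectories consistent
   with the remission outcome, and *configurable planted comorbidity
   effects* so every downstream claim is testable as parameter recovery);
2. **trains** a recurrent multi-modal classifier — one LSTM per dynamic
   modality (30 PANSS items, 5 PSP domains, 2 CGI scales over six visits), a
   fusion layer joining the hidden states with the encoded static features,
   per-outcome interaction layers and softmax heads — with a weighted
   MSE + cross-entropy multi-objective loss, Adam with exponential
   learning-rate decay, pretraining on a synthesized bank, data
   augmentation and Platt calibration;
3. **explains** it by single-flip counterfactuals. For patient `p` and item
   `C_i`, the feature importance is the effect size

   `Δ_i(p) = P(remission | C_i = yes) − P(remission | C_i = no)`,

   computed from 49 model evaluations (the actual record plus 48 records
   each flipping exactly one item), always by the cross-validation fold
   model that held the patient out;
4. **summarises and clusters**: per-item medians/quartiles across patients,
   rank-sum effect sizes `r = |Z|/√(n₁+n₂)` against a bootstrapped null
   pooled across items, ensemble-calibrated Bonferroni significance flags,
   and Ward (minimum variance) hierarchical clustering of the per-patient
   importance maps into subgroups, with identification of the
   "limited-effect" cluster whose mean map is nearest zero.

Model-comparison machinery (repeated stratified 10-fold and
leave-one-site-out cross-validation; AUC, balanced accuracy, sensitivity,
specificity; Mann–Whitney contrasts of the with- versus
without-comorbidity model) is included.

## Worked example

```r
library(remitcf)

# a cohort with a planted negative depression effect on remission
beta <- rep(0, 48); beta[1] <- -2          # item 1: major depressive episode, current
cfg <- cohort_config(n_enrolled = 600, funnel_targets = c(600, 600, 600, 600),
                     beta = beta, gamma = 0, seed = 301)
cohort <- generate_cohort(cfg)

arch <- arch_config(hidden = 8, fusion = 16, interaction = 8,
                    epochs = 16, batch = 16, lr = 6e-3,
                    pretrain_epochs = 0, augment_multiplier = 1, seed = 301)
cv <- repeated_stratified_kfold(cohort, feature_schema(), arch,
                                k = 5, repetitions = 1, seed = 301,
                                collect_importance = TRUE)
effects <- summarize_group_effects(cv$maps, B = 200, seed = 301)
head(effects[, c("item", "item_label", "median", "p_value", "r_value", "significant")], 3)
```

```
  item                              item_label      median      p_value   r_value significant
1    1       major depressive episode: current -0.13488342 7.199482e-06 0.8271478        TRUE
2   19 post-traumatic stress disorder: current -0.03865877 1.345111e-02 0.5852009       FALSE
3   24     obsessive-compulsive disorder: past -0.03513558 2.078423e-02 0.5649688       FALSE
```

The planted item ranks first with a strongly negative median effect
(flipping it to "yes" lowers the predicted remission probability by ~0.13
for the median patient) and is the only Bonferroni-significant item; the
rank-sum r of 0.83 indicates near-complete separation from the pooled null,
while the runner-up items sit inside the item ensemble's noise. Clustering
the maps then separates patients by how strongly comorbidities move their
prediction:

```r
m <- maps_matrix(cv$maps)
cl <- ward_cluster(m, k = 2)
near_zero_cluster_report(cl)
#> $limited_cluster
#> [1] 1
#> $l1_norms
#>  cluster1  cluster2
#> 0.6965436 1.7666267
#> $cluster_sizes
#> [1] 502  98
#> $limited_fraction
#> [1] 0.8366667
```

Here 98 of the 600 patients — essentially the comorbidity carriers — form
the cluster whose predictions the items move strongly, and the mean
importance map of the remaining 502 stays close to zero.

The whole pipeline can also be driven by one YAML config through
`run_pipeline()` (stage outputs as CSV plus a JSON run manifest) or the thin
command-line wrapper in `inst/cli/remitcf`.

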