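# thinpatch

Patch-wise normative modeling of cortical thickness, and everything needed
to turn it into a domain-specific disease-burden and progression pipeline.

## The problem

In disorders like early Parkinson's disease, cortical atrophy is subtle and
spatially heterogeneous, and the *location* of thinning matters: burden in
cortex serving a particular function (say, extremity movement) should track
— and help predict — disability in that function specifically. That calls
for a single-patient statistic that (a) scores every small piece of cortex
against what is normal for that person's age and sex, and (b) can be
restricted to any functionally defined region.

## The statistic

The cortex is divided into `P` roughly equal-area patches (default 1000,
500 per hemisphere), each carrying mean cortical thickness in mm. For a
patient with thickness vector `x`:

1. **Matched reference**: all normative subjects of the same sex within
   ±2 years of age form the reference (size `n`).
2. **Patch z-scores**: `z_j = (x_j − mean_j) / sd_j` (sample SD).
3. **Exact permutation p-values**: pooling the patient with the reference,
   all `n + 1` orderings are equally likely under exchangeability, so the
   exact left-tail p-value is `p_j = (1 + #{ref ≤ x_j}) / (n + 1)` —
   one-sided toward thinness, ties counted conservatively.
4. **Thin calls**: patch `j` is "significantly thin" iff `p_j < 0.05`
   (strict, uncorrected).
5. **Thin-patch fraction (TPF)**: the fraction of thin patches within any
   patch set — whole brain, or a domain-specific restriction such as the
   79 patches overlapping hand/leg functional networks.

Around this core the package provides: projection of binary surface masks
onto the parcellation (`mask_to_patches`, `best_matching_network`,
`union_patchsets`); covariate-adjusted linear models of clinical scores on
TPF with adjusted-R² model comparison (`fit_tpf_model`,
`compare_by_adjusted_r2`); progressor dichotomization and an exact
tie-aware Wilcoxon signed-rank test (`label_progressors`,
`wilcoxon_signed_rank`); an RBF-SVM progression classifier with leak-free
feature selection and five-fold CV tuning (`run_progression_experiment`);
a seeded synthetic-cohort generator (`simulate_study`) standing in for the
restricted normative/patient repositories; and an end-to-end orchestrator
(`run_pipeline`) with full provenance manifests.

## Worked example

```r
library(thinpatch)

cfg <- cohort_config(n_normative = 400, n_patients = 60, n_patches = 300,
                     age_range = c(55, 75), patient_age_mean = 65,
                     patient_age_sd = 4,
                     roi_patches = round(seq(2, 299, length.out = 79)),
                     seed = 7)
study <- simulate_study(cfg)

m <- map_cohort(study$patients$thickness, study$patients$demographics,
                study$normative)
m
#> MAP result: 60 patients x 300 patches (alpha = 0.05)
#>   matched reference sizes: 31-58 (median 40)
#>   mean whole-brain TPF: 0.1261

roi <- patch_set(cfg$roi_patches, name = "extremity")
head(tpf(m, roi), 3)
#>   patient_id patch_set n_patches_considered n_thin       tpf
#> 1   pat_0001 extremity                   79     48 0.6075949
#> 2   pat_0002 extremity                   79     65 0.8227848
#> 3   pat_0003 extremity                   79     79 1.0000000
```

Each row is one patient: of the 79 extremity patches, patient 1 has 48
called thin (TPF 0.61), i.e. deep focal atrophy — this synthetic world
plants 0.3 mm of thinning per unit latent severity on exactly those
patches. The whole-brain TPF of a healthy subject would sit near the
discrete null rate `null_tpf_expectation(n_ref)` (~0.02–0.03 here), so
0.126 on average reflects the planted ROI burden diluted over 300 patches.

Does the restricted TPF explain the extremity motor score better than the
whole-brain TPF, adjusting for age, sex, handedness and symptom duration?

```r
bl <- subset(study$patients$clinical, visit == "BL" & measure == "extremity")
ids <- rownames(study$patients$thickness)
covar <- study$patients$demographics[match(ids, study$patients$demographics$subject_id), ]
y <- bl$value[match(ids, bl$subject_id)]
compare_by_adjusted_r2(
  fit_tpf_model(y, tpf(m, roi)$tpf, covar, outcome_name = "extremity"),
  fit_tpf_model(y, tpf(m)$tpf,     covar, outcome_name = "extremity"))
#> Adjusted-R2 comparison for 'extremity': winner = restricted
#>         model r2_adjusted  tpf_p_value significant
#>    restricted   0.7554953 4.031745e-18        TRUE
#>  unrestricted   0.5489402 5.203759e-11        TRUE
```

The domain-restricted model wins, as it should when atrophy is confined to
the domain's patches. Finally, predicting 1-year extremity progression from
baseline z-scores:

```r
run_progression_experiment(m, study$patients$clinical, roi,
                           classifier_config(n_features = 79, seed = 7),
                           measures = "extremity", horizons = "Y1")
#> Progression classification experiment (2 cells)
#>    outcome horizon        feature_mode n_train n_test   C gamma cv_accuracy test_accuracy
#>  extremity      Y1      restricted_roi      48     12  10 0.001        0.73         0.750
#>  extremity      Y1 wholebrain_selected      48     12 100 0.001        0.72         0.667
```

75% held-out accuracy for the restricted model: in this generator, annual
motor worsening accelerates with the same latent severity that drives the
planted atrophy, so baseline cortical state is genuinely prognostic.

See `vignettes/thin-patch-fraction.Rmd` for the full model, the generator's
assumptions, and every numerical policy (tie handling, degenerate
references, discreteness of the null).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end analysis from scratch at the given
seed — synthetic study, normative mapping, restricted/unrestricted TPF,
clinical association models, progression labels and the 12-cell SVM
experiment — and writes the acceptance JSON to `--out`.
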