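---
title: "Normative thin-patch modeling of cortical thickness: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative thin-patch modeling of cortical thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thinpatch)
```

## The statistic

Cortical thinning in neurodegenerative disease is spatially heterogeneous:
two patients with the same total atrophy burden can have it in very
different places, and the places matter for which clinical functions
deteriorate. `thinpatch` implements a patch-wise normative framework for
quantifying that burden at the single-patient level.

The cortex is represented as a parcellation of $P$ roughly equal-area
patches ($P = 1000$, 500 per hemisphere, in the standard configuration),
each carrying the patient's mean cortical thickness in millimetres. For a
patient with thickness vector $x$ and a normative cohort, the pipeline:

1. **Matches a reference.** All normative subjects of the same sex whose
   age is within $\pm 2$ years (inclusive) of the patient form the
   reference subgroup of size $n$. This is an exact-matching alternative to
   regression-based normative curves: it makes no functional-form
   assumption about aging, at the price of needing a reference cohort dense
   enough in age.
2. **Scores each patch.** $z_j = (x_j - \bar r_j)/s_j$ with the reference
   sample mean and SD (denominator $n-1$).
3. **Converts to exact permutation p-values.** Pooling the patient with the
   $n$ reference values, exchangeability under the null makes each of the
   $n+1$ ranks equally likely. Enumerating all orderings — every possible
   permutation without replacement — gives the exact left-tail p-value
   $$p_j = \frac{1 + \#\{\,r_{ij} \le x_j\,\}}{n + 1},$$
   i.e. the patient's rank from below. This is the only exhaustive,
   replacement-free test available for a one-versus-reference design, and
   it is what "exhaustive permutation testing" means here. The test is
   one-sided toward *thinness*: cortex thicker than the norm is never
   flagged, because the quantity of interest is atrophy.
4. **Calls thin patches.** $\text{thin}_j = (p_j < \alpha)$ with
   $\alpha = 0.05$, strict inequality, and deliberately **no**
   multiple-comparison correction across the $P$ patches: the patch calls
   are an exploratory burden map, not confirmatory tests, and the
   downstream statistic aggregates them. (A `correct` argument to
   `call_thin()` offers BH adjustment for users who want it; it is off by
   default.)
5. **Aggregates to the thin-patch fraction.** For any patch set $S$,
   $$\mathrm{TPF}(S) = \frac{\#\{j \in S : \text{thin}_j\}}{|S|}.$$
   Whole-brain TPF uses $S = \{1..P\}$; a *restricted* TPF uses a
   domain-specific set, e.g. the 79 patches overlapping hand/leg functional
   networks, so that the scalar tracks disease burden in the cortex serving
   a particular clinical function.

Two discreteness facts shape everything downstream. The smallest attainable
p-value is $1/(n+1)$, so **no patch can ever be called thin when
$n < 20$** at $\alpha = 0.05$; `match_reference()` warns in that case. And
under the null each patch is thin with probability
$\#\{k : k/(n+1) < \alpha\}/(n+1)$ (`null_tpf_expectation()`), which is the
expected TPF of a healthy patient — about $1/31 \approx 0.032$ at $n = 30$,
not $\alpha$ itself. Note the strict inequality: when $\alpha(n+1)$ is an
integer the often-quoted $\lfloor\alpha(n+1)\rfloor/(n+1)$ over-counts by
one grid point (at $n = 19$, $p = 1/20 = 0.05$ is *not* below 0.05).

### Tie handling

Ties between the patient and reference values count toward the $\le$ set,
which inflates $p$ and therefore produces *fewer* thin calls — the
conservative direction for an atrophy claim. With continuous thickness
values ties are measure-zero, but file round-trips and rounded inputs make
them real.

## Clinical association and model comparison

Baseline clinical scores (an extremity-specific motor subscore, the total
motor score, a cognitive screen) are regressed on TPF with ordinary least
squares, adjusting for age, sex (one dummy), handedness (L and A dummies
against the right-handed reference, the majority category) and symptom
duration in months — symptom rather than diagnosis duration, since symptom
onset anchors disease biology while diagnosis lag is administrative.
Restricted and unrestricted models of the same outcome are compared by
adjusted $R^2 = 1 - (1-R^2)(n-1)/(n-p-1)$; the TPF term's two-sided t-test
p-value is reported with the conventional 0.05 threshold, uncorrected
across the six baseline models. Outcomes are ordinal but modeled as
continuous, which is standard for these scales at cohort sizes in the
hundreds; an ordinal alternative is out of scope.

The extremity subscore sums the 14 lateralized extremity items of the motor
exam (rigidity of the four extremities — neck excluded — plus finger
tapping, hand movements, pronation–supination, toe tapping and leg agility,
each side separately), giving a 0–56 range. Missing sub-items are an error,
never imputed: a silent zero would masquerade as health.

## Progression

A patient *progresses* on a motor measure if the score shows **any**
increase between baseline and the 1- or 3-year visit, and on the cognitive
measure if it shows any decrease; zero change is a non-progressor either
way. A zero-threshold dichotomization is deliberate: typical annual motor
progression in early disease (~2–3 points) is small enough that a 5- or
10-point cutoff would empty the progressor class.

Visit distributions are compared with the Wilcoxon signed-rank test.
Because clinical scores are small integers, ties and zero differences are
the norm, and the usual exact algorithms decline to handle them. The
package computes the **exact** null distribution of $V$ (the positive-rank
sum) over all $2^n$ sign assignments with midranks, via an integer
convolution that is mathematically identical to full enumeration, whenever
the number of nonzero differences is at most 25; beyond that it switches to
the normal approximation with tie and continuity corrections. Zero
differences are dropped (the classic rule, not Pratt's; the choice is
flagged in the output because it affects $V$). The two-sided p-value is
$\min(1,\, 2\min(P(V \le v), P(V \ge v)))$.

## Progression classification

For each of the 12 cells {restricted ROI, whole-brain} × {extremity motor,
total motor, cognitive} × {1 year, 3 years}, an RBF-kernel support vector
machine is trained on the per-patch normative z-scores:

* deterministic, stratified 0.8/0.2 train/test split (test size
  $\mathrm{round}(0.2\,n)$, class proportions preserved to ±1 subject; the
  same split serves both feature modes of a cell so their accuracies are
  directly comparable);
* feature selection **on the training set only**: the restricted mode uses
  the pre-selected domain patch set unchanged; the whole-brain mode keeps
  the $k = 79$ patches with the largest absolute pooled-variance two-sample
  t-statistic (ties toward the lower patch index), matching the restricted
  dimensionality. The t-filter is a transparent, oracle-testable choice
  among the many unspecified alternatives;
* grid search over $C \in \{0.01, 0.1, 1, 10, 100\}$ and
  $\gamma \in \{10^{-4}, \dots, 10\}$ by mean stratified five-fold
  cross-validated accuracy on the training set, ties resolving to the
  smallest $C$ then the smallest $\gamma$ (a mild-regularization
  preference); the winner is refit on the full training set;
* held-out accuracy is the plain fraction of correct test predictions.

Arranging the five-fold CV *inside* the hyperparameter search on the
training split, with a single final evaluation on the untouched 20%, is the
only arrangement under which reporting one test accuracy per cell is
coherent; the alternative reading (CV as the reported metric) would leave
the 0.8/0.2 split purposeless. The kernel is RBF, with a `linear` option,
since the tuning step is defined over an RBF width. No SVM implementation
ships with the supported R environment, so the C-SVM dual is solved
in-package as a dense quadratic program (`quadprog`); at ~100 training
subjects this is exact and fast, and the trainer is validated against an
independent libsvm-based solver's frozen outputs to within that solver's
own convergence tolerance.

A structural guarantee worth stating: held-out labels cannot influence
training. The test suite verifies this bit-for-bit by flipping every test
label and asserting the selected features and fitted model are unchanged.

## The synthetic cohort: what it emulates, and what it does not

All tests run on a seeded generator (`simulate_study()`) emulating the
statistical skeleton the analysis assumes:

* **Normative cohort** ($N = 650$ by default): patch thickness
  $t_{ij} = \mu_j + \beta_a(a_i - \bar a) + \beta_s\,\mathbf 1[\mathrm F] +
  u_i + \varepsilon_{ij}$ with ages uniform on [40, 80] years, baseline
  $\mu = 2.5$ mm, age slope $-0.005$ mm/yr, sex offset $0.02$ mm, subject
  intercept SD $0.12$ mm and patch noise SD $0.15$ mm — magnitudes in the
  range surface-based morphometry reports for regional thickness.
  $\bar a$ is the midpoint of the age range. Thickness is floored at
  0.1 mm (with a warning) so reference SDs and z-scores stay finite.
* **Patients** ($N = 135$, ages $\sim N(63.5, 6.8^2)$ truncated inside the
  normative range, handedness 119:12:4 R:L:A, right-skewed symptom/diagnosis
  durations): a latent half-normal severity $s_i$ (right-skewed disability,
  as in an early-disease cohort) subtracts $0.3\,s_i$ mm on a designated
  79-patch "extremity" set only.
* **Scores**: extremity $= \mathrm{round}(19 s_i + N(0,3))$ (median ≈ 13);
  total motor adds an independent half-normal non-extremity component
  (median total ≈ 20, and total ≥ extremity always); the cognitive score is
  $\mathrm{round}(N(27.5, 2))$ clamped to [0, 30] and **independent of
  severity** — the joint distribution of motor and cognitive decline is not
  characterized in the data this mirrors, so independence is the explicit,
  conservative assumption, and it doubles as a built-in type-I-error probe.
  Scores are generated continuous and rounded, matching ordinal scales.
* **Follow-ups** at 1 and 3 years add $h(\delta + \kappa s_i)$ plus fresh
  noise before rounding. The severity coupling $\kappa$ (defaults 1.5/yr
  extremity, 1.0/yr non-extremity, 0 cognitive) is what makes baseline
  cortical state informative about future progression at all; without it
  progression would be pure noise and no classifier could beat chance. The
  default drifts (0.4/yr motor, −0.3/yr cognitive) put progressor fractions
  in the 0.55–0.65 range over 1–3 years.

The generator does **not** emulate scanner/site effects, spatial
correlation between neighbouring patches beyond the shared subject
intercept, measurement floor/ceiling artifacts in clinical scales, or any
motor–cognitive coupling. A green test therefore establishes that the
*statistical machinery* is correct under the stated model — exact p-values,
calibrated null TPF, leak-free classification — not that the pipeline's
effect sizes on real data will match; the synthetic planted effects are
deliberately stronger than the weak associations typical of real cohorts,
so structure-recovery tests discriminate sharply between correct and
broken code.

```{r example}
cfg <- cohort_config(n_normative = 200, n_patients = 20, n_patches = 100,
                     age_range = c(55, 75), seed = 42)
study <- simulate_study(cfg)
m <- map_cohort(study$patients$thickness, study$patients$demographics,
                study$normative)
head(tpf(m, patch_set(cfg$roi_patches, "extremity")), 3)
```

## Numerical and degenerate-input policy

* **Degenerate references** (zero patch SD) yield `NA` z/p, are excluded
  from thin calling and from both TPF numerator and denominator, and are
  counted in the mapping log.
* **Rank-deficient designs** in the association models (a constant
  covariate, e.g. a single-sex cohort) are an error naming the column;
  nothing is dropped silently.
* **Classifier degeneracies**: a class absent from a training split is an
  error suggesting stratification; a single-member class can at worst cost
  one CV fold, which is skipped with a message.
* **Determinism**: every stochastic step takes an explicit seed; the
  end-to-end pipeline writes a manifest with md5 hashes of all outputs, and
  two runs from the same configuration are byte-identical.
* The SVM dual adds a ridge of $10^{-8}\max(\mathrm{diag}\,Q)$ (escalated
  ×100 up to three times if the QP solver balks) to keep the kernel matrix
  numerically positive definite, e.g. under duplicated subjects.

## Known limitations

* Exact matching needs a dense normative cohort; with sparse age coverage
  the ±2-year window starves and the discrete p-value grid coarsens. The
  `min_ref` guard (default 10) and the $n < 20$ warning make this loud.
* The similarity step for choosing a best-matching functional network is a
  plain spatial Pearson correlation over shared vertices — a minimal
  functional stand-in for more elaborate task-to-network cross-mapping
  pipelines, and documented as such. Likewise the mask-projection overlap
  rule (≥ 50% of a patch's vertices, configurable) is this package's own
  convention; published patch sets should be loaded from file instead.
* Wholly out of scope: surface reconstruction and thickness estimation from
  images, vertex-level normative modeling, regression-based normative
  curves (GAMs/quantiles), site harmonization, and ordinal outcome models.
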