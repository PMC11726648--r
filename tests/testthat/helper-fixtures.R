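# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small but fully matched study: ~26 same-sex references per patient.
small_config <- function(...) {
  cohort_config(n_normative = 260, n_patients = 40, n_patches = 120,
                age_range = c(55, 75), patient_age_mean = 65,
                patient_age_sd = 4, seed = 7, ...)
}

small_study <- function() cached("small_study", simulate_study(small_config()))

small_map <- function() cached("small_map", {
  st <- small_study()
  suppressWarnings(map_cohort(st$patients$thickness,
                              st$patients$demographics, st$normative))
})

# Pipeline fixture: tight age range so every patient has >= 20 references.
fixture_config <- function() {
  cohort_config(n_normative = 150, n_patients = 30, n_patches = 80,
                age_range = c(60, 70), patient_age_mean = 65,
                patient_age_sd = 3, seed = 11)
}

fixture_classifier_config <- function() {
  classifier_config(n_features = 6, c_grid = c(0.1, 1, 10),
                    gamma_grid = c(0.001, 0.01, 0.1), seed = 5)
}

# Planted-signal world for the progression classifier: deep focal atrophy and
# a strong severity-coupled motor drift (low-severity patients improve,
# high-severity patients worsen, so classes are balanced but separable).
planted_signal_config <- function(seed) {
  cohort_config(n_normative = 400, n_patients = 135, n_patches = 300,
                age_range = c(55, 75), patient_age_mean = 65,
                patient_age_sd = 4,
                roi_patches = round(seq(2, 299, length.out = 79)),
                atrophy_scale = 0.3, subject_sd = 0.08,
                patch_noise_sd = 0.12, score_noise_sd = 1.5,
                progression_drift = c(extremity = -1.5, nonextremity = -1,
                                      cognitive = -0.3),
                progression_coupling = c(extremity = 3, nonextremity = 1.5,
                                         cognitive = 0),
                seed = seed)
}

# Zero-signal world: no atrophy anywhere, progression independent of severity.
zero_signal_config <- function(seed) {
  cohort_config(n_normative = 400, n_patients = 135, n_patches = 300,
                age_range = c(55, 75), patient_age_mean = 65,
                patient_age_sd = 4,
                roi_patches = round(seq(2, 299, length.out = 79)),
                atrophy_scale = 0, score_noise_sd = 1.5,
                progression_drift = c(extremity = 0, nonextremity = 0,
                                      cognitive = 0),
                progression_coupling = c(extremity = 0, nonextremity = 0,
                                         cognitive = 0),
                seed = seed)
}

# --- independent oracles ----------------------------------------------------

# Normal-equations least squares, written against the closed form only.
ols_oracle <- function(y, X) {
  Xd <- cbind(`(Intercept)` = 1, X)
  XtX <- t(Xd) %*% Xd
  beta <- solve(XtX, t(Xd) %*% y)
  res <- y - Xd %*% beta
  n <- length(y)
  p <- ncol(X)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  sigma2 <- rss / (n - p - 1)
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  list(beta = drop(beta), r2 = r2,
       r2_adjusted = 1 - (1 - r2) * (n - 1) / (n - p - 1),
       p_values = drop(2 * stats::pt(-abs(tval), n - p - 1)))
}

# Literal enumeration of all 2^n sign assignments of the signed-rank test.
wilcoxon_brute <- function(bl, fu) {
  d <- fu - bl
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  eps <- 1e-9
  p <- min(1, 2 * min(mean(vs <= v + eps), mean(vs >= v - eps)))
  list(v = v, p = p, n_nonzero = n)
}

# Two Gaussian blobs, linearly separable up to `sep`.
make_blobs <- function(n_per = 20, d = 2, sep = 3, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(n_per * d), n_per, d),
               matrix(stats::rnorm(n_per * d, mean = sep), n_per, d))
    list(x = x, y = factor(rep(c("a", "b"), each = n_per)))
  })
}

extremity_bl_scores <- function(study) {
  cl <- study$patients$clinical
  bl <- cl[cl$visit == "BL" & cl$measure == "extremity", ]
  ids <- rownames(study$patients$thickness)
  bl$value[match(ids, bl$subject_id)]
}

patient_covariates <- function(study) {
  ids <- rownames(study$patients$thickness)
  study$patients$demographics[match(ids, study$patients$demographics$subject_id),
                              c("age", "sex", "handedness", "symptom_duration")]
}
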