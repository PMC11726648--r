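#' Configuration for the synthetic study generator
#'
#' Defines the stated world the generator draws from: a normative cohort with
#' age- and sex-dependent patch-wise cortical thickness, and an early-PD-like
#' patient cohort whose atrophy is confined to a designated "extremity" patch
#' set. A latent, half-normal disease severity drives both the atrophy depth
#' on those patches and the baseline extremity motor score; the total motor
#' score adds an independent non-extremity component, and the cognitive score
#' is independent of severity altogether. Follow-up scores drift per year,
#' with the motor drift accelerating in severity so that baseline cortical
#' state carries information about future progression.
#'
#' Thickness model for subject \eqn{i}, patch \eqn{j} (mm):
#' \deqn{t_{ij} = \mu_j + \beta_a (a_i - \bar a) + \beta_s 1[\mathrm{female}_i]
#'   + u_i + \varepsilon_{ij} - \delta s_i 1[j \in \mathrm{ROI}]}
#' with \eqn{u_i \sim N(0, \sigma_u^2)}, \eqn{\varepsilon_{ij} \sim N(0,
#' \sigma_e^2)}, severity \eqn{s_i = |N(0, \sigma_s^2)|} (patients only,
#' \eqn{\delta} = `atrophy_scale`). \eqn{\bar a} is the midpoint of
#' `age_range`. Thickness is floored at 0.1 mm (warned) so z-scores stay
#' finite.
#'
#' @param n_normative Number of normative (reference) subjects.
#' @param n_patients Number of patients.
#' @param n_patches Number of cortical patches (500 per hemisphere = 1000 in
#'   the standard parcellation).
#' @param age_range Normative age range in years, `c(lo, hi)`; ages are
#'   uniform on it.
#' @param sex_ratio Fraction of females in each cohort.
#' @param baseline_mean_thickness Mean patch thickness in mm; scalar or a
#'   length-`n_patches` vector.
#' @param age_slope Thickness change per year of age (mm/year, typically
#'   negative).
#' @param sex_offset Additive thickness offset for females (mm).
#' @param subject_sd SD of the per-subject random intercept (mm).
#' @param patch_noise_sd SD of independent per-patch noise (mm).
#' @param roi_patches Integer vector of 1-based patch indices carrying the
#'   planted atrophy (the "extremity" set; 79 patches by default).
#' @param atrophy_scale Thickness lost per unit latent severity on ROI
#'   patches (mm).
#' @param severity_sd Scale of the half-normal latent severity.
#' @param extremity_scale Extremity motor score points per unit severity.
#' @param nonextremity_sd Scale of the half-normal non-extremity motor
#'   component (score points).
#' @param score_noise_sd SD of motor score noise (score points).
#' @param moca_mean,moca_sd Mean/SD of the (continuous, pre-rounding)
#'   cognitive score.
#' @param patient_age_mean,patient_age_sd Patient age distribution (normal,
#'   truncated to `age_range` shrunk by the 2-year matching window).
#' @param progression_drift Named annual drifts (score units/year) for
#'   `extremity`, `nonextremity` and `cognitive` components. Motor drifts are
#'   positive (worsening), cognitive negative (MoCA decline).
#' @param progression_coupling Named per-year drift increments per unit
#'   latent severity; nonzero motor coupling is what links baseline atrophy
#'   to future progression.
#' @param seed Integer seed; the whole study is reproducible from
#'   `(config, seed)`.
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [simulate_study()], [generate_normative()], [generate_patients()]
#' @export
cohort_config <- function(n_normative = 650,
                          n_patients = 135,
                          n_patches = 1000,
                          age_range = c(40, 80),
                          sex_ratio = 0.5,
                          baseline_mean_thickness = 2.5,
                          age_slope = -0.005,
                          sex_offset = 0.02,
                          subject_sd = 0.12,
                          patch_noise_sd = 0.15,
                          roi_patches = NULL,
                          atrophy_scale = 0.3,
                          severity_sd = 1,
                          extremity_scale = 19,
                          nonextremity_sd = 10,
                          score_noise_sd = 3,
                          moca_mean = 27.5,
                          moca_sd = 2,
                          patient_age_mean = 63.5,
                          patient_age_sd = 6.8,
                          progression_drift = c(extremity = 0.4, nonextremity = 0.4,
                                                cognitive = -0.3),
                          progression_coupling = c(extremity = 1.5, nonextremity = 1.0,
                                                   cognitive = 0),
                          seed = 1L) {
  assert_scalar_number(n_normative, "n_normative", lo = 1)
  assert_scalar_number(n_patients, "n_patients", lo = 0)
  assert_scalar_number(n_patches, "n_patches", lo = 1)
  if (length(age_range) != 2L || !all(is.finite(age_range)) ||
      age_range[1] >= age_range[2])
    tp_stop("'age_range' must be c(lo, hi) with lo < hi",
            class = "thinpatch_config_error")
  assert_scalar_number(sex_ratio, "sex_ratio", 0, 1)
  for (nm in c("age_slope", "sex_offset", "moca_mean", "patient_age_mean"))
    assert_scalar_number(get(nm), nm)
  for (nm in c("subject_sd", "patch_noise_sd", "atrophy_scale", "severity_sd",
               "extremity_scale", "nonextremity_sd", "score_noise_sd",
               "moca_sd", "patient_age_sd"))
    assert_scalar_number(get(nm), nm, lo = 0)
  if (!all(is.finite(baseline_mean_thickness)) || any(baseline_mean_thickness <= 0))
    tp_stop("'baseline_mean_thickness' must be positive and finite",
            class = "thinpatch_config_error")
  if (!length(baseline_mean_thickness) %in% c(1L, n_patches))
    tp_stop("'baseline_mean_thickness' must be scalar or length n_patches",
            class = "thinpatch_config_error")
  if (is.null(roi_patches))
    roi_patches <- default_roi_patches(n_patches)
  roi_patches <- sort(unique(as.integer(roi_patches)))
  if (length(roi_patches) == 0L || any(roi_patches < 1L) ||
      any(roi_patches > n_patches))
    tp_stop("'roi_patches' must be nonempty 1-based indices <= n_patches",
            class = "thinpatch_config_error")
  need <- c("extremity", "nonextremity", "cognitive")
  for (v in list(progression_drift, progression_coupling))
    if (!all(need %in% names(v)) || !all(is.finite(v[need])))
      tp_stop("progression_drift/progression_coupling need finite named ",
              "entries: ", paste(need, collapse = ", "),
              class = "thinpatch_config_error")
  cfg <- list(
    n_normative = as.integer(n_normative), n_patients = as.integer(n_patients),
    n_patches = as.integer(n_patches), age_range = as.numeric(age_range),
    sex_ratio = sex_ratio, baseline_mean_thickness = baseline_mean_thickness,
    age_slope = age_slope, sex_offset = sex_offset, subject_sd = subject_sd,
    patch_noise_sd = patch_noise_sd, roi_patches = roi_patches,
    atrophy_scale = atrophy_scale, severity_sd = severity_sd,
    extremity_scale = extremity_scale, nonextremity_sd = nonextremity_sd,
    score_noise_sd = score_noise_sd, moca_mean = moca_mean, moca_sd = moca_sd,
    patient_age_mean = patient_age_mean, patient_age_sd = patient_age_sd,
    progression_drift = progression_drift[need],
    progression_coupling = progression_coupling[need],
    seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' Default "extremity" patch set for a parcellation
#'
#' A fixed, arbitrary-but-reproducible set of 79 patch indices (the size of
#' the extremity-specific set obtained by masking the 1000-patch parcellation
#' with hand/leg functional networks). For parcellations smaller than 1000
#' patches the set is scaled down proportionally (at least 2 patches).
#'
#' @param n_patches Parcellation size.
#' @return Sorted integer vector of 1-based patch indices.
#' @export
default_roi_patches <- function(n_patches = 1000) {
  k <- max(2L, round(79 * n_patches / 1000))
  # deterministic spread across both "hemispheres" of the parcellation
  idx <- unique(round(seq(1, n_patches, length.out = k)))
  while (length(idx) < k) idx <- unique(c(idx, min(setdiff(seq_len(n_patches), idx))))
  sort(as.integer(idx[seq_len(k)]))
}

# Thickness floor (mm): keeps reference SDs and z-scores finite.
.THICKNESS_FLOOR <- 0.1

#' @noRd
.sim_thickness <- function(cfg, ages, female, ids, atrophy = NULL) {
  n <- length(ages)
  p <- cfg$n_patches
  mu <- rep(cfg$baseline_mean_thickness, length.out = p)
  mid_age <- mean(cfg$age_range)
  subj <- cfg$age_slope * (ages - mid_age) + cfg$sex_offset * female +
    stats::rnorm(n, 0, cfg$subject_sd)
  thick <- matrix(mu, n, p, byrow = TRUE) + subj +
    matrix(stats::rnorm(n * p, 0, cfg$patch_noise_sd), n, p)
  if (!is.null(atrophy)) thick <- thick + atrophy
  n_clip <- sum(thick < .THICKNESS_FLOOR)
  if (n_clip > 0) {
    warning(sprintf("%d thickness values clipped at the %.1f mm floor",
                    n_clip, .THICKNESS_FLOOR), call. = FALSE)
    thick[thick < .THICKNESS_FLOOR] <- .THICKNESS_FLOOR
  }
  dimnames(thick) <- list(ids, patch_labels(p))
  thick
}

#' @noRd
.sim_sex <- function(n, sex_ratio) {
  n_f <- round(n * sex_ratio)
  sample(c(rep("F", n_f), rep("M", n - n_f)))
}

#' Generate the normative cohort
#'
#' Draws `n_normative` reference subjects with ages uniform on `age_range`
#' and the thickness model described in [cohort_config()] (no atrophy term).
#' Uses the config seed, so two calls with the same config are identical.
#'
#' @param config A [cohort_config()].
#' @return List with `thickness` (subjects x patches matrix, mm) and
#'   `demographics` (data.frame: subject_id, age, sex).
#' @export
generate_normative <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    n <- config$n_normative
    ids <- sprintf("norm_%04d", seq_len(n))
    ages <- stats::runif(n, config$age_range[1], config$age_range[2])
    sex <- .sim_sex(n, config$sex_ratio)
    thick <- .sim_thickness(config, ages, as.numeric(sex == "F"), ids)
    list(thickness = thick,
         demographics = data.frame(subject_id = ids, age = ages, sex = sex,
                                   stringsAsFactors = FALSE))
  })
}

#' @noRd
.round_score <- function(x, lo, hi) as.integer(clamp(round(x), lo, hi))

#' Generate the patient cohort and its clinical visits
#'
#' Patients follow the normative thickness model minus
#' `atrophy_scale * severity` on the ROI patches only. Baseline scores:
#' extremity = `round(extremity_scale * s + noise)` clamped to \[0, 80\]
#' (a loose bound on the lateralized MDS-UPDRS III item sum), total motor =
#' extremity + an independent non-extremity component (clamped so total >=
#' extremity always holds), MoCA ~ `round(N(moca_mean, moca_sd))` clamped to
#' \[0, 30\] and independent of severity. Follow-ups at 1 and 3 years add
#' `horizon * (drift + coupling * s)` plus fresh noise to the continuous
#' score before rounding, so both progressors and non-progressors occur.
#'
#' Uses `config$seed + 1L` so the patient stream is independent of the
#' normative stream but the pair is reproducible from one config.
#'
#' @param config A [cohort_config()].
#' @return List with `thickness`, `demographics` (subject_id, age, sex,
#'   handedness, symptom_duration, diagnosis_duration), `clinical` (long
#'   data.frame: subject_id, visit in BL/Y1/Y3, measure in
#'   extremity/total_motor/cognitive, value) and `truth` (subject_id,
#'   severity, plus the ROI indices and atrophy depth as attributes).
#' @export
generate_patients <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(config$roi_patches) == 0L)
    tp_stop("roi_patches must be nonempty", class = "thinpatch_config_error")
  withr::with_seed(config$seed + 1L, {
    n <- config$n_patients
    ids <- sprintf("pat_%04d", seq_len(n))
    lo <- config$age_range[1] + 2
    hi <- config$age_range[2] - 2
    ages <- truncnorm::rtruncnorm(n, a = lo, b = hi,
                                  mean = config$patient_age_mean,
                                  sd = config$patient_age_sd)
    sex <- .sim_sex(n, config$sex_ratio)
    handed <- sample(c("R", "L", "A"), n, replace = TRUE,
                     prob = c(119, 12, 4) / 135)
    # right-skewed durations (months), moments near the clinical tables
    symptom_dur <- stats::rgamma(n, shape = 0.65, scale = 17 / 0.65)
    diagnosis_dur <- pmin(symptom_dur,
                          stats::rgamma(n, shape = 0.4, scale = 4 / 0.4))
    sev <- abs(stats::rnorm(n, 0, config$severity_sd))
    atrophy <- matrix(0, n, config$n_patches)
    atrophy[, config$roi_patches] <- -config$atrophy_scale * sev
    thick <- .sim_thickness(config, ages, as.numeric(sex == "F"), ids,
                            atrophy = atrophy)

    drift <- config$progression_drift
    coup <- config$progression_coupling
    ext_bl <- config$extremity_scale * sev +
      stats::rnorm(n, 0, config$score_noise_sd)
    nonext_bl <- abs(stats::rnorm(n, 0, config$nonextremity_sd))
    moca_bl <- stats::rnorm(n, config$moca_mean, config$moca_sd)
    visits <- list(BL = 0, Y1 = 1, Y3 = 3)
    rows <- lapply(names(visits), function(v) {
      h <- visits[[v]]
      noise <- function() if (h == 0) 0 else stats::rnorm(n, 0, config$score_noise_sd)
      ext <- ext_bl + h * (drift[["extremity"]] + coup[["extremity"]] * sev) + noise()
      nonext <- nonext_bl + h * (drift[["nonextremity"]] + coup[["nonextremity"]] * sev) + noise()
      moca <- moca_bl + h * (drift[["cognitive"]] + coup[["cognitive"]] * sev) +
        (if (h == 0) 0 else stats::rnorm(n, 0, config$moca_sd / 2))
      ext_i <- .round_score(ext, 0, 80)
      nonext_i <- .round_score(nonext, 0, 52)
      data.frame(subject_id = rep(ids, 3L),
                 visit = v,
                 measure = rep(c("extremity", "total_motor", "cognitive"), each = n),
                 value = c(ext_i, ext_i + nonext_i, .round_score(moca, 0, 30)),
                 stringsAsFactors = FALSE)
    })
    clinical <- do.call(rbind, rows)
    clinical <- clinical[order(clinical$subject_id, clinical$visit,
                               clinical$measure), ]
    rownames(clinical) <- NULL
    truth <- data.frame(subject_id = ids, severity = sev,
                        stringsAsFactors = FALSE)
    attr(truth, "roi_patches") <- config$roi_patches
    attr(truth, "atrophy_scale") <- config$atrophy_scale
    list(thickness = thick,
         demographics = data.frame(subject_id = ids, age = ages, sex = sex,
                                   handedness = handed,
                                   symptom_duration = symptom_dur,
                                   diagnosis_duration = diagnosis_dur,
                                   stringsAsFactors = FALSE),
         clinical = clinical,
         truth = truth)
  })
}

#' Generate a complete synthetic study
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_study`: list with `normative`,
#'   `patients` (see [generate_normative()], [generate_patients()]) and
#'   `config`.
#' @examples
#' cfg <- cohort_config(n_normative = 60, n_patients = 8, n_patches = 40,
#'                      age_range = c(55, 75), seed = 42)
#' study <- simulate_study(cfg)
#' dim(study$patients$thickness)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  out <- list(normative = generate_normative(config),
              patients = generate_patients(config),
              config = config)
  class(out) <- "synthetic_study"
  out
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic thin-patch study\n")
  cat(sprintf("  normative: %d subjects x %d patches\n",
              nrow(x$normative$thickness), ncol(x$normative$thickness)))
  cat(sprintf("  patients:  %d subjects, %d ROI patches, atrophy %.2f mm/severity\n",
              nrow(x$patients$thickness), length(x$config$roi_patches),
              x$config$atrophy_scale))
  cat(sprintf("  seed: %d\n", x$config$seed))
  invisible(x)
}

#' Write a synthetic study to plain-text files
#'
#' Emits the interchange files the downstream stages read: thickness CSVs
#' (normative + patients), demographics CSVs, long-format clinical CSV, the
#' ROI patch-set file and a truth JSON (latent severities).
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    normative_thickness = file.path(dir, "normative_thickness.csv"),
    patient_thickness = file.path(dir, "patient_thickness.csv"),
    normative_demographics = file.path(dir, "normative_demographics.csv"),
    patient_demographics = file.path(dir, "patient_demographics.csv"),
    clinical = file.path(dir, "clinical.csv"),
    roi = file.path(dir, "roi_patches.txt"),
    truth = file.path(dir, "truth.json"))
  write_thickness(study$normative$thickness, paths["normative_thickness"])
  write_thickness(study$patients$thickness, paths["patient_thickness"])
  utils::write.csv(study$normative$demographics,
                   paths["normative_demographics"], row.names = FALSE)
  utils::write.csv(study$patients$demographics,
                   paths["patient_demographics"], row.names = FALSE)
  utils::write.csv(study$patients$clinical, paths["clinical"], row.names = FALSE)
  write_patchset(patch_set(study$config$roi_patches, name = "roi",
                           provenance = "synthetic planted-atrophy set"),
                 paths["roi"])
  jsonlite::write_json(study$patients$truth, paths["truth"], digits = NA)
  invisible(paths)
}
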