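test_that("noise-free degenerate config reproduces the baseline exactly", {
  cfg <- cohort_config(n_normative = 12, n_patients = 6, n_patches = 20,
                       age_range = c(50, 70), subject_sd = 0, patch_noise_sd = 0,
                       age_slope = 0, sex_offset = 0, atrophy_scale = 0,
                       baseline_mean_thickness = 2.5, seed = 3)
  st <- simulate_study(cfg)
  expect_true(all(st$normative$thickness == 2.5))
  expect_true(all(st$patients$thickness == 2.5))
})

test_that("noise-free planted atrophy is exactly atrophy_scale * severity on ROI only", {
  cfg <- cohort_config(n_normative = 10, n_patients = 8, n_patches = 30,
                       age_range = c(50, 70), subject_sd = 0, patch_noise_sd = 0,
                       age_slope = 0, sex_offset = 0, atrophy_scale = 0.3,
                       roi_patches = c(3, 9, 21), seed = 5)
  st <- simulate_study(cfg)
  s <- st$patients$truth$severity
  roi <- cfg$roi_patches
  off <- setdiff(seq_len(30), roi)
  expect_equal(unname(st$patients$thickness[, roi]),
               matrix(2.5 - 0.3 * s, 8, 3), tolerance = 1e-12)
  expect_true(all(st$patients$thickness[, off] == 2.5))
})

test_that("the generator is byte-identical under a repeated seed", {
  cfg <- cohort_config(n_normative = 50, n_patients = 10, n_patches = 25,
                       age_range = c(55, 75), seed = 7)
  expect_identical(simulate_study(cfg), simulate_study(cfg))
  # and differs under another seed
  cfg2 <- cohort_config(n_normative = 50, n_patients = 10, n_patches = 25,
                        age_range = c(55, 75), seed = 8)
  expect_false(identical(simulate_study(cfg)$normative$thickness,
                         simulate_study(cfg2)$normative$thickness))
})

test_that("OLS on generated data recovers the age slope", {
  cfg <- cohort_config(n_normative = 650, n_patients = 0, n_patches = 50,
                       age_range = c(40, 80), age_slope = -0.005, seed = 21)
  nc <- generate_normative(cfg)
  fit <- summary(lm(rowMeans(nc$thickness) ~ nc$demographics$age))
  est <- fit$coefficients[2, ]
  expect_lt(abs(est["Estimate"] - (-0.005)), 3 * est["Std. Error"])
})

test_that("severity drives the baseline extremity score", {
  # planted-truth correlation positive in every one of 100 cheap replicates
  pos <- vapply(1:100, function(r) {
    cfg <- cohort_config(n_normative = 1, n_patients = 60, n_patches = 5,
                         age_range = c(55, 75), roi_patches = 1:2, seed = 1000 + r)
    pats <- generate_patients(cfg)
    bl <- pats$clinical[pats$clinical$visit == "BL" &
                          pats$clinical$measure == "extremity", ]
    cor(bl$value[match(pats$truth$subject_id, bl$subject_id)],
        pats$truth$severity) > 0
  }, logical(1))
  expect_gte(sum(pos), 99)
})

test_that("scores respect the clinical scale invariants", {
  st <- small_study()
  cl <- st$patients$clinical
  ext <- cl[cl$measure == "extremity", ]
  moca <- cl[cl$measure == "cognitive", ]
  expect_true(all(ext$value >= 0 & ext$value <= 80))
  expect_true(all(moca$value >= 0 & moca$value <= 30))
  tot <- merge(ext, cl[cl$measure == "total_motor", ],
               by = c("subject_id", "visit"))
  expect_true(all(tot$value.y >= tot$value.x))
  expect_true(all(table(cl$subject_id) == 9))  # 3 measures x BL/Y1/Y3
  expect_true(all(st$patients$truth$severity >= 0))
})

test_that("atrophy is local to the ROI patch set", {
  cfg <- cohort_config(n_normative = 2, n_patients = 200, n_patches = 120,
                       age_range = c(55, 75), patient_age_mean = 65,
                       patient_age_sd = 4, seed = 7)
  st <- list(patients = generate_patients(cfg))
  mid <- mean(cfg$age_range)
  demo <- st$patients$demographics
  expected <- 2.5 + cfg$age_slope * (demo$age - mid) +
    cfg$sex_offset * (demo$sex == "F")
  deficit_mat <- matrix(expected, nrow(st$patients$thickness),
                        cfg$n_patches) - st$patients$thickness
  roi <- cfg$roi_patches
  off <- setdiff(seq_len(cfg$n_patches), roi)
  on_roi <- mean(deficit_mat[, roi])
  off_roi <- mean(deficit_mat[, off])
  # Monte-Carlo SE of the off-ROI mean deficit
  se_off <- sd(rowMeans(deficit_mat[, off])) / sqrt(nrow(deficit_mat))
  expect_gt(on_roi, 0.05)
  expect_lt(abs(off_roi), 2 * se_off)
})

test_that("extreme atrophy is floored with a warning", {
  cfg <- cohort_config(n_normative = 5, n_patients = 5, n_patches = 10,
                       age_range = c(55, 75), atrophy_scale = 5,
                       severity_sd = 3, seed = 2)
  expect_warning(pats <- generate_patients(cfg), "clipped")
  expect_true(all(pats$thickness >= 0.1))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(age_range = c(70, 50)), "age_range")
  expect_error(cohort_config(subject_sd = -1), "subject_sd")
  expect_error(cohort_config(age_slope = NaN), "age_slope")
  expect_error(cohort_config(n_patches = 10, roi_patches = c(5, 11)),
               "roi_patches")
  expect_error(cohort_config(sex_ratio = 1.5), "sex_ratio")
})

test_that("write_study emits readable, consistent interchange files", {
  st <- simulate_study(cohort_config(n_normative = 40, n_patients = 8,
                                     n_patches = 15, age_range = c(55, 75),
                                     seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  back <- read_thickness(paths["patient_thickness"])
  expect_identical(dimnames(back), dimnames(st$patients$thickness))
  expect_equal(back, st$patients$thickness, tolerance = 1e-12)
  expect_identical(read_patchset(paths["roi"])$indices,
                   st$config$roi_patches)
  cl <- read_clinical(paths["clinical"])
  expect_equal(nrow(cl), nrow(st$patients$clinical))
})
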