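test_that("matched reference keeps all and only same-sex subjects within the window", {
  cohort <- data.frame(subject_id = c("a", "b", "c", "d"),
                       age = c(58, 62, 62.1, 60),
                       sex = c("F", "F", "F", "M"))
  pat <- list(subject_id = "p1", age = 60, sex = "F")
  ref <- suppressWarnings(match_reference(pat, cohort, min_ref = 1))
  expect_identical(ref$member_ids, c("a", "b"))  # 62.1 just outside, M excluded
  # inclusive bound: exactly +/- 2 years is in
  cohort2 <- data.frame(subject_id = "e", age = 62, sex = "F")
  expect_identical(suppressWarnings(
    match_reference(pat, cohort2, min_ref = 1))$n_ref, 1L)
  # empty match errors, naming the patient
  expect_error(match_reference(list(subject_id = "p2", age = 40, sex = "M"),
                               cohort, min_ref = 1),
               "p2.*0 matched", class = "thinpatch_matching_error")
  # small references cannot flag any patch: warned
  expect_warning(match_reference(pat, cohort, min_ref = 1), "n_ref")
})

test_that("matching equals a brute-force filter over the synthetic cohort", {
  st <- small_study()
  demo <- st$normative$demographics
  pat <- list(subject_id = "px", age = 63.5, sex = "F")
  ref <- match_reference(pat, demo)
  brute <- demo$subject_id[vapply(seq_len(nrow(demo)), function(i)
    demo$sex[i] == "F" && abs(demo$age[i] - 63.5) <= 2, logical(1))]
  expect_identical(ref$member_ids, brute)
})

test_that("z-scores match the hand-computed sample mean/SD formula", {
  ref <- matrix(c(2.0, 2.2), 2, 1)
  expect_equal(patch_zscores(c(1.9), ref), -0.2 / sd(c(2, 2.2)))
  expect_equal(patch_zscores(c(1.9), ref), -sqrt(2), tolerance = 1e-12)
  # value at the reference mean scores zero
  expect_equal(patch_zscores(c(2.1), ref), 0)
  # thinner patch, strictly smaller z
  ref2 <- matrix(rnorm(40, 2.5, 0.1), 20, 2)
  z1 <- patch_zscores(c(2.4, 2.4), ref2)
  z2 <- patch_zscores(c(2.3, 2.4), ref2)
  expect_lt(z2[1], z1[1])
  expect_identical(z2[2], z1[2])
  # degenerate reference SD: NA plus a warning
  refc <- cbind(rep(2, 5), rnorm(5))
  expect_warning(z <- patch_zscores(c(2, 0), refc), "zero reference SD")
  expect_true(is.na(z[1]) && is.finite(z[2]))
})

test_that("rank p-values hit the exact extremes and count ties conservatively", {
  ref <- matrix(seq(2.0, 2.95, by = 0.05), 20, 1)
  expect_equal(patch_pvalues(1.5, ref), 1 / 21)
  expect_equal(patch_pvalues(3.5, ref), 1)
  # a tie with one reference value counts toward the <= set
  expect_equal(patch_pvalues(2.0, ref), 2 / 21)
  # p lives on the discrete grid k/(n_ref+1), per patient
  st <- small_map()
  mult <- st$p * (st$n_ref + 1)  # recycles n_ref down each column
  expect_lt(max(abs(mult - round(mult)), na.rm = TRUE), 1e-9)
})

test_that("null p-values are calibrated to the discrete uniform", {
  n <- 4000
  withr::with_seed(31, {
    ref <- matrix(rnorm(30 * n), 30, n)
    x <- rnorm(n)
  })
  p <- patch_pvalues(x, ref)
  target <- 1 / 31  # floor(0.05 * 31)/31
  se <- sqrt(target * (1 - target) / n)
  expect_lt(abs(mean(p <= 0.05) - target), 3 * se)
})

test_that("thin calls use a strict threshold and no correction by default", {
  expect_identical(call_thin(c(0.05, 1 / 31, 1)), c(FALSE, TRUE, FALSE))
  expect_error(call_thin(0.5, alpha = 1), "alpha",
               class = "thinpatch_config_error")
  expect_error(call_thin(c(0.5, 0)), class = "thinpatch_validation_error")
  # optional BH mode can only reduce the number of calls
  p <- c(0.001, 0.02, 0.04, 0.2, 0.8)
  expect_lte(sum(call_thin(p, correct = "BH")), sum(call_thin(p)))
})

test_that("TPF is the thin fraction over the requested patch set", {
  thin <- rep(FALSE, 120)
  thin[c(2, 30, 50, 99)] <- TRUE
  fake <- structure(list(thin = matrix(thin, 1, dimnames = list("p1", NULL))),
                    class = "map_result")
  set79 <- patch_set(1:79, "roi")
  res <- tpf(fake, set79)
  expect_equal(res$tpf, 3 / 79)
  expect_equal(res$n_thin, 3L)
  # whole-brain denominator is the full parcellation
  expect_equal(tpf(fake)$tpf, 4 / 120)
  # zero case
  fake$thin[] <- FALSE
  expect_equal(tpf(fake, set79)$tpf, 0)
  expect_error(tpf(fake, integer(0)), class = "thinpatch_config_error")
})

test_that("TPF decomposes exactly over any partition of the parcellation", {
  m <- small_map()
  p <- ncol(m$thin)
  whole <- tpf(m)
  for (r in 1:25) {
    idx <- withr::with_seed(r, sample(p, sample(2:(p - 2), 1)))
    a <- tpf(m, patch_set(idx))
    b <- tpf(m, patch_set(setdiff(seq_len(p), idx)))
    expect_identical(a$n_thin + b$n_thin, whole$n_thin)
  }
})

test_that("z and p order patches coherently and thin calls are monotone", {
  withr::with_seed(5, {
    ref <- matrix(rnorm(30 * 50, 2.5, 0.1), 30, 50)
    x <- rnorm(50, 2.4, 0.1)
  })
  z <- patch_zscores(x, ref)
  p <- patch_pvalues(x, ref)
  # z/p coherence: the patient's rank among the pooled reference values is
  # the same whether computed on raw thickness or on its z-analogues
  # (standardization is monotone), and that rank determines p exactly
  for (j in c(1, 17, 50)) {
    z_ref <- (ref[, j] - mean(ref[, j])) / sd(ref[, j])
    rank_x <- rank(c(x[j], ref[, j]), ties.method = "max")[1]
    rank_z <- rank(c(z[j], z_ref), ties.method = "max")[1]
    expect_identical(rank_x, rank_z)
    expect_equal(p[j], rank_x / (nrow(ref) + 1))
  }
  # decreasing a patch's thickness never un-thins it
  thin0 <- call_thin(p)
  x2 <- x - 0.2
  thin1 <- call_thin(patch_pvalues(x2, ref))
  expect_true(all(thin1 >= thin0))
})

test_that("cohort mapping is deterministic and consistent with per-patient calls", {
  st <- small_study()
  m1 <- small_map()
  m2 <- suppressWarnings(map_cohort(st$patients$thickness,
                                    st$patients$demographics, st$normative))
  expect_identical(m1$z, m2$z)
  expect_identical(m1$thin, m2$thin)
  one <- suppressWarnings(map_patient(
    st$patients$demographics[3, ], st$patients$thickness[3, ], st$normative))
  expect_identical(unname(m1$z[3, ]), unname(one$z))
  expect_identical(unname(m1$p[3, ]), unname(one$p))
  expect_identical(unname(m1$n_ref[3]), one$n_ref)
  # tidy export carries every cell
  td <- tidy_patch_stats(m1)
  expect_equal(nrow(td), prod(dim(m1$z)))
})

test_that("null expectation helper matches the discrete attainable rate", {
  expect_equal(null_tpf_expectation(30), 1 / 31)
  expect_equal(null_tpf_expectation(19), 0)   # 1/20 = 0.05 is not < 0.05
  expect_equal(null_tpf_expectation(39), 1 / 40)  # 2/40 sits exactly at alpha
  expect_equal(null_tpf_expectation(40), 2 / 41)
  # brute-force count of the attainable grid, strict threshold
  for (n in c(10, 25, 59, 99))
    expect_equal(null_tpf_expectation(n),
                 sum(seq_len(n + 1) / (n + 1) < 0.05) / (n + 1))
})
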