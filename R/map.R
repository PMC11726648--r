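#' Select the age- and sex-matched normative reference for one patient
#'
#' The reference subgroup is all normative subjects of the same sex whose age
#' lies within `age_window` years of the patient's age (bounds inclusive),
#' kept in cohort order.
#'
#' @param patient One-row data.frame (or list) with `subject_id`, `age`,
#'   `sex`.
#' @param normative_demographics Normative demographics data.frame
#'   (`subject_id`, `age`, `sex`).
#' @param age_window Half-width of the age window in years (default 2).
#' @param min_ref Minimum acceptable reference size; fewer matches is an
#'   error naming the patient. With fewer than 20 references no patch can
#'   ever be called thin at alpha = 0.05 (the smallest attainable rank
#'   p-value is 1/(n_ref + 1) >= 0.05), so a warning is issued below 20.
#' @return Object of class `reference_subset`: list with `patient_id`,
#'   `member_ids`, `n_ref`, `age_window`.
#' @export
match_reference <- function(patient, normative_demographics,
                            age_window = 2, min_ref = 10) {
  assert_scalar_number(age_window, "age_window", lo = 0)
  sel <- normative_demographics$sex == patient$sex &
    abs(normative_demographics$age - patient$age) <= age_window
  members <- normative_demographics$subject_id[sel]
  n_ref <- length(members)
  if (n_ref < min_ref)
    tp_stop(sprintf("patient %s: only %d matched references (min_ref = %d)",
                    patient$subject_id, n_ref, min_ref),
            class = "thinpatch_matching_error")
  if (n_ref < 20)
    warning(sprintf(paste0("patient %s: n_ref = %d < 20; no patch can reach ",
                           "p < 0.05"), patient$subject_id, n_ref),
            call. = FALSE)
  structure(list(patient_id = as.character(patient$subject_id),
                 member_ids = as.character(members),
                 n_ref = n_ref, age_window = age_window),
            class = "reference_subset")
}

#' Per-patch z-scores against a matched reference
#'
#' \eqn{z_j = (x_j - \bar r_j) / s_j} with the sample SD (denominator
#' `n_ref - 1`). Patches whose reference SD is zero are degenerate: their z
#' (and downstream thin call) is `NA` and a warning reports the count.
#'
#' @param x Patient thickness vector (length = n patches).
#' @param ref Reference thickness matrix (n_ref x n patches).
#' @return Numeric z vector, `NA` at degenerate patches.
#' @export
patch_zscores <- function(x, ref) {
  if (nrow(ref) < 2) tp_stop("need n_ref >= 2 for a sample SD")
  if (length(x) != ncol(ref)) tp_stop("patient/reference patch mismatch")
  if (!all(is.finite(x)) || !all(is.finite(ref)))
    tp_stop("non-finite thickness values", class = "thinpatch_validation_error")
  m <- colMeans(ref)
  s <- matrixStats::colSds(ref)
  z <- (x - m) / s
  deg <- s == 0
  if (any(deg)) {
    z[deg] <- NA_real_
    warning(sprintf("%d patches with zero reference SD excluded", sum(deg)),
            call. = FALSE)
  }
  z
}

#' Exact rank permutation p-values for per-patch thinness
#'
#' For patch \eqn{j}, the patient's value is pooled with its \eqn{n}
#' reference values; under exchangeability each of the \eqn{n + 1} ranks is
#' equally likely, and enumerating all orderings ("all possible permutations
#' without replacement") gives the exact left-tail p-value
#' \deqn{p_j = \frac{1 + \#\{r_{ij} \le x_j\}}{n + 1}.}
#' Ties count toward the \eqn{\le} set (conservative: fewer thin calls).
#' Thinness (low thickness) is the alternative of interest, so small values
#' get small p; a patient above every reference gets \eqn{p = 1}.
#'
#' @inheritParams patch_zscores
#' @return Numeric p vector with values in `{k/(n_ref+1), k = 1..n_ref+1}`.
#' @export
patch_pvalues <- function(x, ref) {
  if (length(x) != ncol(ref)) tp_stop("patient/reference patch mismatch")
  if (!all(is.finite(x)) || !all(is.finite(ref)))
    tp_stop("non-finite thickness values", class = "thinpatch_validation_error")
  n_ref <- nrow(ref)
  k <- colSums(ref <= matrix(x, n_ref, length(x), byrow = TRUE))
  (1 + k) / (n_ref + 1)
}

#' Call significantly thin patches
#'
#' `thin_j = (p_j < alpha)`, strict inequality and no multiple-testing
#' correction across the patches (faithful to the method's definition of a
#' "significantly thin" patch). `NA` p-values (degenerate patches) propagate
#' as `NA`.
#'
#' @param p p-value vector in (0, 1].
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param correct Optional multiplicity correction applied before the
#'   threshold, one of `"none"` (default, faithful) or a method accepted by
#'   [stats::p.adjust()] (e.g. `"BH"`).
#' @return Logical vector.
#' @export
call_thin <- function(p, alpha = 0.05, correct = "none") {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1)
    tp_stop("'alpha' must be in (0, 1)", class = "thinpatch_config_error")
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1))
    tp_stop("p-values must lie in (0, 1]", class = "thinpatch_validation_error")
  if (!identical(correct, "none")) p <- stats::p.adjust(p, method = correct)
  p < alpha
}

#' Score one patient against the normative cohort
#'
#' Convenience wrapper: matched reference, z-scores, exact rank p-values and
#' thin calls for a single patient.
#'
#' @param patient One-row patient demographics (`subject_id`, `age`, `sex`).
#' @param patient_thickness Patient thickness vector.
#' @param normative A list with `thickness` and `demographics` (as returned
#'   by [generate_normative()]).
#' @param alpha Thinness level (default 0.05).
#' @inheritParams match_reference
#' @return Object of class `patch_stats`: list with `patient_id`, `z`, `p`,
#'   `thin`, `alpha`, `n_ref`.
#' @export
map_patient <- function(patient, patient_thickness, normative,
                        alpha = 0.05, age_window = 2, min_ref = 10) {
  ref_set <- match_reference(patient, normative$demographics,
                             age_window = age_window, min_ref = min_ref)
  ref <- normative$thickness[ref_set$member_ids, , drop = FALSE]
  z <- patch_zscores(patient_thickness, ref)
  p <- patch_pvalues(patient_thickness, ref)
  p[is.na(z)] <- NA_real_  # degenerate reference: excluded from thin calling
  structure(list(patient_id = ref_set$patient_id, z = z, p = p,
                 thin = call_thin(p, alpha), alpha = alpha,
                 n_ref = ref_set$n_ref),
            class = "patch_stats")
}

#' Score a whole patient cohort against the normative cohort
#'
#' Runs [map_patient()] for every row of the patient thickness matrix and
#' assembles patient-by-patch matrices of z-scores, p-values and thin calls.
#' Per-patient small-reference warnings are collected into one summary
#' warning; patients that cannot be matched abort with an error naming them.
#'
#' @param patient_thickness Patients x patches thickness matrix (rownames =
#'   subject ids).
#' @param patient_demographics Patient demographics data.frame.
#' @param normative List with `thickness` and `demographics`.
#' @inheritParams map_patient
#' @return Object of class `map_result`: list with matrices `z`, `p`,
#'   `thin`, vector `n_ref`, and `alpha`, `age_window`, `n_degenerate`.
#' @export
map_cohort <- function(patient_thickness, patient_demographics, normative,
                       alpha = 0.05, age_window = 2, min_ref = 10) {
  ids <- rownames(patient_thickness)
  if (is.null(ids)) tp_stop("patient thickness matrix must have rownames")
  ord <- match(ids, patient_demographics$subject_id)
  if (anyNA(ord))
    tp_stop("patients missing from demographics: ",
            paste(utils::head(ids[is.na(ord)], 3), collapse = ", "),
            class = "thinpatch_validation_error")
  demo <- patient_demographics[ord, , drop = FALSE]
  n <- length(ids)
  p_mat <- z_mat <- matrix(NA_real_, n, ncol(patient_thickness),
                           dimnames = dimnames(patient_thickness))
  n_ref <- integer(n)
  small <- character(0)
  for (i in seq_len(n)) {
    st <- withCallingHandlers(
      map_patient(demo[i, ], patient_thickness[i, ], normative,
                  alpha = alpha, age_window = age_window, min_ref = min_ref),
      warning = function(w) {
        if (grepl("n_ref", conditionMessage(w)))
          small <<- c(small, ids[i])
        invokeRestart("muffleWarning")
      })
    z_mat[i, ] <- st$z
    p_mat[i, ] <- st$p
    n_ref[i] <- st$n_ref
  }
  if (length(small) > 0)
    warning(sprintf("%d patients with n_ref < 20 (no patch can reach p < 0.05): %s",
                    length(small),
                    paste(utils::head(small, 5), collapse = ", ")),
            call. = FALSE)
  n_deg <- sum(is.na(z_mat))
  structure(list(z = z_mat, p = p_mat, thin = call_thin(p_mat, alpha),
                 n_ref = stats::setNames(n_ref, ids), alpha = alpha,
                 age_window = age_window, n_degenerate = n_deg),
            class = "map_result")
}

#' @export
print.map_result <- function(x, ...) {
  cat(sprintf("MAP result: %d patients x %d patches (alpha = %g)\n",
              nrow(x$z), ncol(x$z), x$alpha))
  cat(sprintf("  matched reference sizes: %d-%d (median %g)\n",
              min(x$n_ref), max(x$n_ref), stats::median(x$n_ref)))
  cat(sprintf("  mean whole-brain TPF: %.4f\n", mean(x$thin, na.rm = TRUE)))
  invisible(x)
}

#' Tidy per-patch statistics
#'
#' @param map_result A [map_cohort()] result.
#' @return Long data.frame: `patient_id`, `patch`, `z`, `p`, `thin`.
#' @export
tidy_patch_stats <- function(map_result) {
  stopifnot(inherits(map_result, "map_result"))
  data.frame(patient_id = rep(rownames(map_result$z), ncol(map_result$z)),
             patch = rep(colnames(map_result$z), each = nrow(map_result$z)),
             z = as.vector(map_result$z),
             p = as.vector(map_result$p),
             thin = as.vector(map_result$thin),
             stringsAsFactors = FALSE)
}

#' Thin-patch fraction over a patch set
#'
#' TPF = (number of thin patches within the set) / (number of set patches
#' considered). With `patch_set = NULL` the denominator is the full
#' parcellation (whole-brain TPF). Degenerate patches (`NA` thin calls) are
#' excluded from numerator and denominator.
#'
#' @param map_result A [map_cohort()] result (or a single `patch_stats`).
#' @param patch_set A [patch_set()] (or plain integer indices), or `NULL`
#'   for whole brain.
#' @param name Label recorded in the output (defaults to the patch set's
#'   name or `"whole_brain"`).
#' @return Data.frame: `patient_id`, `patch_set`, `n_patches_considered`,
#'   `n_thin`, `tpf`.
#' @export
tpf <- function(map_result, patch_set = NULL, name = NULL) {
  if (inherits(map_result, "patch_stats")) {
    thin <- matrix(map_result$thin, nrow = 1,
                   dimnames = list(map_result$patient_id, NULL))
  } else {
    stopifnot(inherits(map_result, "map_result"))
    thin <- map_result$thin
  }
  if (is.null(patch_set)) {
    idx <- seq_len(ncol(thin))
    name <- name %||% "whole_brain"
  } else {
    if (inherits(patch_set, "patch_set")) {
      name <- name %||% patch_set$name
      idx <- patch_set$indices
    } else {
      idx <- as.integer(patch_set)
      name <- name %||% "patch_set"
    }
    if (length(idx) == 0)
      tp_stop("empty patch set", class = "thinpatch_config_error")
    if (any(idx < 1L) || any(idx > ncol(thin)) || anyDuplicated(idx))
      tp_stop("patch set indices out of range or duplicated",
              class = "thinpatch_config_error")
  }
  sub <- thin[, idx, drop = FALSE]
  considered <- rowSums(!is.na(sub))
  n_thin <- rowSums(sub, na.rm = TRUE)
  data.frame(patient_id = rownames(thin), patch_set = name,
             n_patches_considered = as.integer(considered),
             n_thin = as.integer(n_thin),
             tpf = ifelse(considered > 0, n_thin / considered, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Expected whole-brain TPF under the null
#'
#' For a patient exchangeable with its reference, each patch is called thin
#' with probability `#\{k : k/(n_ref+1) < alpha\} / (n_ref + 1)` — the
#' number of attainable rank p-values strictly below `alpha` — which is
#' therefore the expected TPF over any patch set under the null. This is
#' `floor(alpha (n_ref+1)) / (n_ref+1)` except when `alpha (n_ref+1)` is an
#' integer, where the strict threshold excludes one more grid point.
#'
#' @param n_ref Reference size(s).
#' @param alpha Thinness level.
#' @return Expected null TPF, vectorized over `n_ref`.
#' @export
null_tpf_expectation <- function(n_ref, alpha = 0.05) {
  (ceiling(alpha * (n_ref + 1)) - 1) / (n_ref + 1)
}
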