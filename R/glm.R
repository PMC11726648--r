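#' Composite extremity motor subscore
#'
#' Sums the lateralized extremity items of the MDS-UPDRS III motor exam:
#' rigidity of the four extremities (item 3.3, neck excluded), finger
#' tapping (3.4), hand movements (3.5), pronation-supination (3.6),
#' toe tapping (3.7) and leg agility (3.8), each scored 0-4 per side — 14
#' sub-items in total, so the subscore ranges 0-56. (Downstream score
#' containers allow values up to 80 as a loose bound; the attainable maximum
#' of this composite is 56.)
#'
#' @param item_scores Named numeric vector (or list) of the 20 sub-items;
#'   required names are given by [extremity_item_names()]. Missing items are
#'   an error — no imputation.
#' @return Integer subscore in \[0, 80\].
#' @examples
#' items <- setNames(rep(0, 20), extremity_item_names())
#' items[c("3.4R", "3.4L")] <- c(2, 1)
#' extremity_subscore(items)  # 3
#' @export
extremity_subscore <- function(item_scores) {
  item_scores <- unlist(item_scores)
  need <- extremity_item_names()
  missing <- setdiff(need, names(item_scores))
  if (length(missing) > 0)
    tp_stop("missing MDS-UPDRS III sub-items: ",
            paste(missing, collapse = ", "),
            class = "thinpatch_missing_data_error")
  vals <- item_scores[need]
  if (anyNA(vals) || any(vals < 0 | vals > 4) || any(vals != round(vals)))
    tp_stop("item scores must be integers in [0, 4]",
            class = "thinpatch_validation_error")
  as.integer(sum(vals))
}

#' @rdname extremity_subscore
#' @export
extremity_item_names <- function() {
  c(sprintf("3.3%s", c("RUE", "LUE", "RLE", "LLE")),
    as.vector(t(outer(sprintf("3.%d", 4:8), c("R", "L"), paste0))))
}

#' Covariate-adjusted linear model of a clinical score on TPF
#'
#' Ordinary least squares of the outcome on TPF plus the standard
#' confounders: age, sex (one dummy), handedness (two dummies, L and A
#' against the right-handed reference) and symptom duration. The TPF
#' p-value is the two-sided t-test on its coefficient; adjusted
#' \eqn{R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1)} with \eqn{p} non-intercept
#' regressors.
#'
#' Constant or collinear covariate columns are an error naming the column
#' (e.g. `sex` in a single-sex cohort); drop them from `covariates` — or
#' pass `covariates = NULL` for the unadjusted model — rather than relying
#' on silent removal.
#'
#' @param outcome Numeric clinical score vector.
#' @param tpf_values Numeric TPF vector (same subject order).
#' @param covariates Data.frame with any of `age`, `sex`, `handedness`,
#'   `symptom_duration`, or `NULL` for no adjustment.
#' @param outcome_name,predictor_name Labels recorded in the fit.
#' @return Object of class `tpf_glm`: list with `outcome_name`,
#'   `predictor_name`, `n`, `coefficients`, `tpf_coefficient`,
#'   `tpf_p_value`, `r2`, `r2_adjusted` and the underlying `lm` fit.
#' @export
fit_tpf_model <- function(outcome, tpf_values, covariates = NULL,
                          outcome_name = "outcome", predictor_name = "tpf") {
  n <- length(outcome)
  if (length(tpf_values) != n)
    tp_stop("outcome and tpf lengths differ", class = "thinpatch_validation_error")
  if (anyNA(outcome) || anyNA(tpf_values))
    tp_stop("missing values in outcome or tpf", class = "thinpatch_validation_error")
  df <- data.frame(.outcome = outcome, tpf = tpf_values)
  if (!is.null(covariates)) {
    if (nrow(covariates) != n)
      tp_stop("covariates must have one row per subject",
              class = "thinpatch_validation_error")
    keep <- intersect(c("age", "sex", "handedness", "symptom_duration"),
                      names(covariates))
    for (nm in keep) {
      col <- covariates[[nm]]
      if (anyNA(col))
        tp_stop("missing values in covariate '", nm, "'",
                class = "thinpatch_missing_data_error")
      if (nm == "sex") col <- factor(col, levels = c("M", "F"))
      if (nm == "handedness") col <- factor(col, levels = c("R", "L", "A"))
      if (is.factor(col)) col <- droplevels(col)
      if (length(unique(col)) < 2)
        tp_stop("covariate '", nm, "' is constant (collinear with the ",
                "intercept); drop it from the model",
                class = "thinpatch_fit_error")
      df[[nm]] <- col
    }
  }
  fit <- stats::lm(.outcome ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    tp_stop("rank-deficient design; collinear column(s): ",
            paste(bad, collapse = ", "), class = "thinpatch_fit_error")
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  structure(list(outcome_name = outcome_name, predictor_name = predictor_name,
                 n = n, coefficients = stats::coef(fit),
                 tpf_coefficient = unname(ct["tpf", "Estimate"]),
                 tpf_p_value = unname(ct["tpf", "Pr(>|t|)"]),
                 r2 = sm$r.squared, r2_adjusted = sm$adj.r.squared,
                 fit = fit),
            class = "tpf_glm")
}

#' @export
print.tpf_glm <- function(x, ...) {
  cat(sprintf("TPF model: %s ~ %s + covariates (n = %d)\n",
              x$outcome_name, x$predictor_name, x$n))
  cat(sprintf("  tpf coefficient %.4g (p = %.4g), R2 = %.4f, adj. R2 = %.4f\n",
              x$tpf_coefficient, x$tpf_p_value, x$r2, x$r2_adjusted))
  invisible(x)
}

#' Compare restricted vs. unrestricted TPF models by adjusted R-squared
#'
#' Declares the model with the higher adjusted \eqn{R^2} the winner (exact
#' equality is a tie) and reports both TPF p-values against the 0.05
#' significance convention.
#'
#' @param fit_restricted,fit_unrestricted [fit_tpf_model()] fits of the same
#'   outcome on the restricted (domain-specific) and unrestricted
#'   (whole-brain) TPF.
#' @return Object of class `tpf_comparison`: list with `outcome_name`,
#'   `winner` (`"restricted"`, `"unrestricted"` or `"tie"`) and a
#'   two-row summary data.frame (`table`).
#' @export
compare_by_adjusted_r2 <- function(fit_restricted, fit_unrestricted) {
  stopifnot(inherits(fit_restricted, "tpf_glm"),
            inherits(fit_unrestricted, "tpf_glm"))
  if (!identical(fit_restricted$outcome_name, fit_unrestricted$outcome_name) ||
      fit_restricted$n != fit_unrestricted$n)
    tp_stop("fits must model the same outcome on the same subjects",
            class = "thinpatch_usage_error")
  d <- fit_restricted$r2_adjusted - fit_unrestricted$r2_adjusted
  winner <- if (d > 0) "restricted" else if (d < 0) "unrestricted" else "tie"
  tab <- data.frame(
    model = c("restricted", "unrestricted"),
    r2_adjusted = c(fit_restricted$r2_adjusted, fit_unrestricted$r2_adjusted),
    tpf_p_value = c(fit_restricted$tpf_p_value, fit_unrestricted$tpf_p_value),
    significant = c(fit_restricted$tpf_p_value < 0.05,
                    fit_unrestricted$tpf_p_value < 0.05),
    stringsAsFactors = FALSE)
  structure(list(outcome_name = fit_restricted$outcome_name, winner = winner,
                 table = tab),
            class = "tpf_comparison")
}

#' @export
print.tpf_comparison <- function(x, ...) {
  cat(sprintf("Adjusted-R2 comparison for '%s': winner = %s\n",
              x$outcome_name, x$winner))
  print(x$table, row.names = FALSE)
  invisible(x)
}
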