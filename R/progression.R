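#' Dichotomize patients into progressors and non-progressors
#'
#' A patient progresses on a motor measure if the score shows any increase
#' between baseline and follow-up (`delta = fu - bl > 0`), and on the
#' cognitive measure (MoCA) if it shows any decrease (`delta < 0`); zero
#' change is a non-progressor under both rules. Subjects missing either
#' visit are excluded with a message (complete scores at all visits were an
#' inclusion criterion for the design this mirrors).
#'
#' @param clinical Long clinical data.frame (`subject_id`, `visit`,
#'   `measure`, `value`).
#' @param measure One of `"extremity"`, `"total_motor"`, `"cognitive"`.
#' @param horizon Follow-up visit, `"Y1"` or `"Y3"`.
#' @return Data.frame: `subject_id`, `measure`, `horizon`, `bl`, `fu`,
#'   `delta`, `progressor`.
#' @export
label_progressors <- function(clinical, measure, horizon = c("Y1", "Y3")) {
  horizon <- match.arg(horizon)
  measure <- match.arg(measure, c("extremity", "total_motor", "cognitive"))
  sub <- clinical[clinical$measure == measure, , drop = FALSE]
  bl <- sub[sub$visit == "BL", c("subject_id", "value")]
  fu <- sub[sub$visit == horizon, c("subject_id", "value")]
  m <- merge(bl, fu, by = "subject_id", suffixes = c("_bl", "_fu"))
  all_ids <- unique(sub$subject_id)
  dropped <- setdiff(all_ids, m$subject_id)
  ok <- stats::complete.cases(m)
  dropped <- c(dropped, m$subject_id[!ok])
  if (length(dropped) > 0)
    message(sprintf("%d subjects excluded for incomplete %s/%s visits",
                    length(dropped), "BL", horizon))
  m <- m[ok, , drop = FALSE]
  delta <- m$value_fu - m$value_bl
  progressor <- if (measure == "cognitive") delta < 0 else delta > 0
  data.frame(subject_id = m$subject_id, measure = measure, horizon = horizon,
             bl = m$value_bl, fu = m$value_fu, delta = delta,
             progressor = progressor, stringsAsFactors = FALSE)
}

#' @noRd
.signed_rank_prep <- function(bl, fu) {
  if (length(bl) != length(fu))
    tp_stop("paired vectors must have equal length",
            class = "thinpatch_validation_error")
  if (length(bl) < 5)
    tp_stop("need at least 5 pairs", class = "thinpatch_validation_error")
  d <- fu - bl
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  r <- rank(abs(nz))  # midranks for ties
  list(d = d, nz = nz, r = r)
}

#' Exact null distribution of the signed-rank statistic
#'
#' Probability mass of V = sum of ranks of positive differences over all
#' 2^n equiprobable sign assignments, for arbitrary (mid)ranks. Midranks are
#' half-integers at worst, so doubling them gives an integer convolution
#' identical to full enumeration.
#'
#' @param r Vector of (mid)ranks of the nonzero |differences|.
#' @return List with `support` (attainable V values as multiples of 0.5)
#'   and `prob`.
#' @keywords internal
signed_rank_exact_distribution <- function(r) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), f[seq_len(total + 1L - ri)])
    f <- f + shifted
  }
  list(support = (0:total) / 2, prob = f / 2^length(r))
}

#' Wilcoxon signed-rank test with exact tie-aware enumeration
#'
#' Paired test of baseline vs. follow-up scores. Zero differences are
#' dropped (classic rule, not Pratt), remaining absolute differences are
#' midranked, and V is the sum of ranks of the positive differences. The
#' two-sided p-value is exact — computed from the full distribution over all
#' `2^n` sign assignments (including ties) — when the number of nonzero
#' differences is at most `exact_limit`, and otherwise uses the normal
#' approximation with tie and continuity corrections. The two-sided p is
#' `min(1, 2 * min(P(V <= v), P(V >= v)))`.
#'
#' @param bl,fu Paired score vectors (length >= 5).
#' @param exact_limit Largest n_nonzero for exact enumeration (default 25).
#' @return Object of class `wilcoxon_result`: `n_pairs`, `n_nonzero`,
#'   `v_statistic`, `p_value`, `method` (`"exact"`, `"normal_approx"` or
#'   `"degenerate"`).
#' @examples
#' wilcoxon_signed_rank(c(10, 12, 9, 15, 11), c(11, 14, 12, 15, 13))
#' @export
wilcoxon_signed_rank <- function(bl, fu, exact_limit = 25) {
  prep <- .signed_rank_prep(bl, fu)
  n_pairs <- length(prep$d)
  n <- length(prep$nz)
  if (n == 0) {
    warning("all differences zero: degenerate signed-rank test", call. = FALSE)
    return(structure(list(n_pairs = n_pairs, n_nonzero = 0L, v_statistic = 0,
                          p_value = 1, method = "degenerate"),
                     class = "wilcoxon_result"))
  }
  v <- sum(prep$r[prep$nz > 0])
  if (n <= exact_limit) {
    dist <- signed_rank_exact_distribution(prep$r)
    eps <- 1e-9
    p_le <- sum(dist$prob[dist$support <= v + eps])
    p_ge <- sum(dist$prob[dist$support >= v - eps])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(prep$r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- v - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(n_pairs = n_pairs, n_nonzero = as.integer(n),
                 v_statistic = v, p_value = p, method = method),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed rank: V = %g, p = %.4g (%s; %d/%d nonzero pairs)\n",
              x$v_statistic, x$p_value, x$method, x$n_nonzero, x$n_pairs))
  invisible(x)
}

#' Visit-comparison table across all clinical measures
#'
#' Runs [wilcoxon_signed_rank()] on baseline vs. follow-up for each measure
#' present, mirroring a demographics-table "BL vs. Y3" column.
#'
#' @param clinical Long clinical data.frame.
#' @param visits Length-2 character vector, baseline then follow-up.
#' @return Data.frame: `measure`, `n`, `median_bl`, `median_fu`, `v`, `p`,
#'   `method`.
#' @export
wilcoxon_table <- function(clinical, visits = c("BL", "Y3")) {
  measures <- unique(clinical$measure)
  rows <- lapply(measures, function(ms) {
    sub <- clinical[clinical$measure == ms, ]
    bl <- sub[sub$visit == visits[1], c("subject_id", "value")]
    fu <- sub[sub$visit == visits[2], c("subject_id", "value")]
    m <- merge(bl, fu, by = "subject_id")
    w <- wilcoxon_signed_rank(m$value.x, m$value.y)
    data.frame(measure = ms, n = nrow(m),
               median_bl = stats::median(m$value.x),
               median_fu = stats::median(m$value.y),
               v = w$v_statistic, p = w$p_value, method = w$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
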