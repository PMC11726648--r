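# Soft-margin C-SVM trained by solving the dual QP directly with
# quadprog::solve.QP. At the cohort sizes this pipeline sees (~100 training
# subjects) the dense dual is small; no decomposition (SMO) is needed.

#' @noRd
.kernel_matrix <- function(X, Y, kernel, gamma) {
  if (kernel == "linear") return(X %*% t(Y))
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  exp(-gamma * pmax(d2, 0))
}

#' Train a kernel support vector machine
#'
#' Solves the C-SVM dual
#' \deqn{\min_\alpha \tfrac12 \alpha^\top Q \alpha - 1^\top \alpha,\quad
#'   0 \le \alpha_i \le C,\ y^\top\alpha = 0,\qquad
#'   Q_{ij} = y_i y_j K(x_i, x_j)}
#' as a dense quadratic program (a small diagonal ridge keeps Q numerically
#' positive definite). The intercept comes from the free support vectors, or
#' from the KKT bounds when none are free.
#'
#' @param x Numeric feature matrix (subjects x features).
#' @param y Two-level factor (or coercible); the first level maps to the
#'   negative class.
#' @param cost Box constraint C > 0.
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param gamma RBF width; default `1/ncol(x)`.
#' @return Object of class `tp_svm`.
#' @export
svm_fit <- function(x, y, cost = 1, kernel = c("rbf", "linear"),
                    gamma = 1 / ncol(x)) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2)
    tp_stop("svm_fit needs exactly two classes, got ", nlevels(y),
            class = "thinpatch_validation_error")
  assert_scalar_number(cost, "cost", lo = 1e-12)
  assert_scalar_number(gamma, "gamma", lo = 0)
  yy <- ifelse(as.integer(y) == 1L, -1, 1)
  n <- nrow(x)
  K <- .kernel_matrix(x, x, kernel, gamma)
  Q <- (yy %o% yy) * K
  dvec <- rep(1, n)
  Amat <- cbind(yy, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-cost, n))
  ridge <- 1e-8 * max(diag(Q))
  alpha <- NULL
  for (attempt in 1:4) {
    sol <- tryCatch(
      quadprog::solve.QP(Q + diag(ridge, n), dvec, Amat, bvec, meq = 1),
      error = function(e) NULL)
    if (!is.null(sol)) { alpha <- sol$solution; break }
    ridge <- ridge * 100
  }
  if (is.null(alpha))
    tp_stop("SVM dual QP failed to solve (degenerate kernel matrix)",
            class = "thinpatch_fit_error")
  alpha <- clamp(alpha, 0, cost)
  eps <- max(1e-8, 1e-6 * cost)
  o <- as.vector(K %*% (alpha * yy))
  r <- yy - o
  free <- alpha > eps & alpha < cost - eps
  if (any(free)) {
    b <- mean(r[free])
  } else {
    lower <- r[(alpha <= eps & yy > 0) | (alpha >= cost - eps & yy < 0)]
    upper <- r[(alpha <= eps & yy < 0) | (alpha >= cost - eps & yy > 0)]
    b <- mean(c(if (length(lower)) max(lower) else NULL,
                if (length(upper)) min(upper) else NULL))
  }
  sv <- alpha > eps
  structure(list(x = x[sv, , drop = FALSE], coefs = (alpha * yy)[sv],
                 b = b, kernel = kernel, gamma = gamma, cost = cost,
                 levels = levels(y), n_sv = sum(sv)),
            class = "tp_svm")
}

#' @export
print.tp_svm <- function(x, ...) {
  cat(sprintf("C-SVM (%s kernel): C = %g, gamma = %g, %d support vectors\n",
              x$kernel, x$cost, x$gamma, x$n_sv))
  invisible(x)
}

#' Predict from a fitted SVM
#'
#' @param object A [svm_fit()] model.
#' @param newdata Feature matrix with the training columns.
#' @param type `"class"` (default) or `"decision"` for the raw decision
#'   values.
#' @param ... Unused.
#' @return Factor of predicted classes, or numeric decision values.
#' @export
predict.tp_svm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  K <- .kernel_matrix(newdata, object$x, object$kernel, object$gamma)
  dec <- as.vector(K %*% object$coefs) + object$b
  if (type == "decision") return(dec)
  factor(object$levels[ifelse(dec > 0, 2L, 1L)], levels = object$levels)
}
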