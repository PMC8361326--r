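#' Kernel specification
#'
#' @param kind `"linear"`, `"polynomial"` or `"rbf"`.
#' @param degree Polynomial degree (default 3).
#' @param gamma RBF width, a positive number or `"auto"` for `1/d` with `d`
#'   the (per-network) selected feature count, resolved at training time.
#' @param coef0 Polynomial offset (default 1).
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(kind = c("linear", "polynomial", "rbf"),
                        degree = 3L, gamma = "auto", coef0 = 1) {
  kind <- match.arg(kind)
  if (!identical(gamma, "auto") && (!is.numeric(gamma) || gamma <= 0))
    stop("gamma must be positive or \"auto\"")
  structure(list(kind = kind, degree = as.integer(degree), gamma = gamma,
                 coef0 = coef0),
            class = "kernel_spec")
}

#' Evaluate a kernel between two sets of rows
#'
#' Linear: inner products. Polynomial: `(inner + coef0)^degree`. RBF:
#' `exp(-gamma * ||a - b||^2)`. An `"auto"` gamma resolves to
#' `1 / ncol(rows_a)`.
#'
#' @param rows_a,rows_b Matrices with matching column counts.
#' @param spec A [kernel_spec()].
#' @return `nrow(rows_a) x nrow(rows_b)` kernel matrix.
#' @export
compute_kernel <- function(rows_a, rows_b, spec) {
  rows_a <- as.matrix(rows_a); rows_b <- as.matrix(rows_b)
  if (ncol(rows_a) != ncol(rows_b)) stop("column counts differ")
  ip <- tcrossprod(rows_a, rows_b)
  switch(spec$kind,
    linear = ip,
    polynomial = (ip + spec$coef0)^spec$degree,
    rbf = {
      g <- if (identical(spec$gamma, "auto")) 1 / max(1L, ncol(rows_a))
           else spec$gamma
      d2 <- outer(rowSums(rows_a^2), rowSums(rows_b^2), "+") - 2 * ip
      exp(-g * pmax(d2, 0))
    })
}

#' Train a soft-margin SVM from the dual
#'
#' Maximizes the dual objective
#' \deqn{\sum_i \alpha_i - \tfrac12 \sum_{i,j} \alpha_i \alpha_j y_i y_j
#'   k(x_i, x_j)}
#' subject to \eqn{\sum_i \alpha_i y_i = 0} and \eqn{0 \le \alpha_i \le C},
#' by sequential minimal optimization with maximal-violating-pair working
#' set selection (compiled inner loop). The bias is the average of
#' `y_i - f_0(x_i)` over margin support vectors (`0 < alpha_i < C`); when
#' no margin vector exists it is the midpoint of the KKT violation bounds
#' at the box constraints.
#'
#' @param kernel Square symmetric PSD kernel matrix of the training rows.
#' @param labels -1/+1 vector, both classes present.
#' @param C Positive box constraint.
#' @param tol KKT violation tolerance (stopping rule).
#' @param max_iter Iteration cap; hitting it returns the best iterate with
#'   a warning.
#' @param alpha0 Optional feasible warm-start alpha.
#' @return List with `alpha`, `bias`, `objective` (dual value),
#'   `iterations`, `converged`.
#' @export
train_svm <- function(kernel, labels, C, tol = 1e-8, max_iter = 500000L,
                      alpha0 = NULL) {
  K <- as.matrix(kernel)
  y <- as.numeric(labels)
  n <- length(y)
  if (nrow(K) != n || ncol(K) != n) stop("kernel/label dimension mismatch")
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2)
    stop("labels must be -1/+1 with both classes present")
  if (max(abs(K - t(K))) > 1e-6) stop("kernel matrix is not symmetric")
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-6 * max(1, max(abs(K))))
    stop("kernel matrix is not positive semidefinite within tolerance")
  if (C <= 0) stop("C must be positive")
  sol <- smo_cpp(K, y, C, tol, as.integer(max_iter),
                 if (is.null(alpha0)) numeric(0) else as.numeric(alpha0))
  if (!sol$converged)
    warning("SMO iteration cap reached; returning current iterate")
  alpha <- sol$alpha; G <- sol$G
  yG <- -y * G
  margin <- alpha > 1e-7 & alpha < C - 1e-7
  bias <- if (any(margin)) mean(yG[margin]) else {
    up <- (y == 1 & alpha < C - 1e-12) | (y == -1 & alpha > 1e-12)
    lo <- (y == -1 & alpha < C - 1e-12) | (y == 1 & alpha > 1e-12)
    if (any(up) && any(lo)) (max(yG[up]) + min(yG[lo])) / 2 else 0
  }
  objective <- sum(alpha) - 0.5 * sum(alpha * (G + 1))
  list(alpha = alpha, bias = bias, objective = objective,
       iterations = sol$iterations, converged = sol$converged)
}

# dual objective only, warm-startable; skips the validation done by
# train_svm (used inside the MKL line search on pre-checked kernels)
.svm_objective <- function(K, y, C, tol, alpha0 = NULL) {
  sol <- smo_cpp(K, y, C, tol, 500000L,
                 if (is.null(alpha0)) numeric(0) else alpha0)
  list(objective = sum(sol$alpha) - 0.5 * sum(sol$alpha * (sol$G + 1)),
       alpha = sol$alpha, G = sol$G, converged = sol$converged)
}
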