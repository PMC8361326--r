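#' Two-class F-score of every feature
#'
#' For feature i with positive/negative group means `xbar+`, `xbar-`,
#' overall mean `xbar` and group sample variances `s+^2`, `s-^2`
#' (denominators n-1), the score is
#'
#' \deqn{F(i) = \frac{(\bar x_i^{(+)} - \bar x_i)^2 + (\bar x_i^{(-)} -
#'   \bar x_i)^2}{s_{+}^2(i) + s_{-}^2(i)}}
#'
#' the ratio of between-group to within-group variation. Larger scores mark
#' more discriminative features. A zero denominator with a non-zero
#' numerator (constant within both groups but different means, i.e. perfect
#' separation) scores `Inf` and ranks first; 0/0 scores 0.
#'
#' @param features `n x p` numeric matrix.
#' @param labels Length-n vector of -1/+1; both classes need >= 2 samples.
#' @return A `selection_result` list: `scores`, `ranked` (feature indices
#'   by descending score, ties broken by lower index), `selected`
#'   (`NULL` until [select_top()]), `method = "fscore"`, and `diagnostics`
#'   with the group means and variance terms.
#' @export
f_scores <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1))) stop("labels must be -1 or +1")
  pos <- labels == 1; neg <- labels == -1
  if (sum(pos) < 2 || sum(neg) < 2)
    stop("each class needs at least 2 samples for the within-group variances")
  mu <- colMeans(features)
  xp <- features[pos, , drop = FALSE]; xn <- features[neg, , drop = FALSE]
  mup <- colMeans(xp); mun <- colMeans(xn)
  vp <- colSums(sweep(xp, 2, mup)^2) / (nrow(xp) - 1)
  vn <- colSums(sweep(xn, 2, mun)^2) / (nrow(xn) - 1)
  num <- (mup - mu)^2 + (mun - mu)^2
  den <- vp + vn
  scores <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  structure(list(scores = scores, ranked = order(-scores, seq_along(scores)),
                 selected = NULL, method = "fscore",
                 diagnostics = list(mean = mu, mean_pos = mup, mean_neg = mun,
                                    var_pos = vp, var_neg = vn)),
            class = "selection_result")
}

#' Keep the top-ranked features
#'
#' @param result A `selection_result` from [f_scores()] or
#'   [lasso_select()].
#' @param count_or_fraction Integer count in `[1, p]`, or a fraction in
#'   (0, 1) converted to `k = max(1, round(fraction * p))`.
#' @return The result with `selected` set to the first `k` ranked indices.
#' @export
select_top <- function(result, count_or_fraction) {
  p <- length(result$scores)
  k <- if (count_or_fraction > 0 && count_or_fraction < 1)
    max(1L, round(count_or_fraction * p)) else as.integer(count_or_fraction)
  if (k < 1 || k > p) stop("requested feature count outside [1, p]")
  result$selected <- result$ranked[seq_len(k)]
  result
}

#' Lasso feature selection with fivefold cross-validated penalty
#'
#' L1-penalized least-squares regression of the -1/+1 labels on
#' standardized features. The penalty is chosen from a 30-point log-spaced
#' grid spanning four decades below the smallest penalty that zeroes all
#' coefficients, by fivefold cross-validation minimizing mean squared
#' prediction error. Selected features are those with non-zero coefficients
#' at the chosen penalty; if the optimum shrinks everything to zero, the
#' smallest grid penalty with at least one non-zero coefficient is used
#' instead. Fitting is delegated to glmnet.
#'
#' @param features `n x p` matrix.
#' @param labels -1/+1 vector.
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return A `selection_result` with `scores = |coefficients|`, `ranked`,
#'   `selected` (non-zero coefficients) and `method = "lasso"`.
#' @export
lasso_select <- function(features, labels, n_folds = 5L, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1))) stop("labels must be -1 or +1")
  if (length(unique(labels)) < 2) stop("labels must contain both classes")
  n <- nrow(features)
  if (n < n_folds) stop("need at least n_folds samples")
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(n_folds), n))
  cv <- glmnet::cv.glmnet(features, labels, family = "gaussian",
                          alpha = 1, nlambda = 30, lambda.min.ratio = 1e-4,
                          foldid = foldid, standardize = TRUE,
                          grouped = nrow(features) >= 3 * n_folds)
  fit <- cv$glmnet.fit
  coef_at <- function(lam) as.numeric(stats::coef(fit, s = lam,
                                                  exact = FALSE))[-1]
  beta <- coef_at(cv$lambda.min)
  if (all(beta == 0)) {
    nz <- fit$df > 0
    if (any(nz)) beta <- coef_at(max(fit$lambda[nz]))
  }
  scores <- abs(beta)
  structure(list(scores = scores, ranked = order(-scores, seq_along(scores)),
                 selected = which(beta != 0), method = "lasso",
                 diagnostics = list(lambda = cv$lambda.min,
                                    cv_mse = cv$cvm, lambda_grid = cv$lambda)),
            class = "selection_result")
}

#' Export a ranked selection as a data frame / CSV
#'
#' @param result A `selection_result`.
#' @param provenance Optional provenance data frame
#'   (from a `feature_table`) supplying feature names.
#' @param path Optional CSV output path.
#' @return Data frame with feature id, provenance string, score, rank and
#'   selected flag.
#' @export
selection_table <- function(result, provenance = NULL, path = NULL) {
  p <- length(result$scores)
  rk <- integer(p); rk[result$ranked] <- seq_len(p)
  df <- data.frame(
    feature = seq_len(p),
    name = if (!is.null(provenance)) provenance$name else NA_character_,
    score = result$scores, rank = rk,
    selected = seq_len(p) %in% result$selected)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
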