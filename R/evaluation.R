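#' Fold-wise feature normalization
#'
#' `fit_scaler` computes per-feature mean and standard deviation
#' (denominator n-1) on training rows only; `apply_scaler` z-scores any
#' rows with those statistics. A constant training feature (SD = 0) gets
#' SD 1, so it becomes 0 on the training rows and `(x - mean)` on test
#' rows. Test rows are always scaled with training statistics — never
#' their own — which is what keeps the cross-validation leakage-free.
#'
#' @param train_features Matrix with >= 2 rows.
#' @return `fit_scaler`: list with `mean` and `sd` vectors.
#' @export
fit_scaler <- function(train_features) {
  train_features <- as.matrix(train_features)
  if (nrow(train_features) < 2) stop("need at least 2 training rows")
  mu <- colMeans(train_features)
  sd <- sqrt(colSums(sweep(train_features, 2, mu)^2) /
               (nrow(train_features) - 1))
  sd[sd == 0] <- 1
  list(mean = mu, sd = sd)
}

#' @rdname fit_scaler
#' @param features Rows to transform.
#' @param scaler Result of `fit_scaler`.
#' @export
apply_scaler <- function(features, scaler) {
  features <- as.matrix(features)
  sweep(sweep(features, 2, scaler$mean), 2, scaler$sd, "/")
}

#' Confusion-matrix performance metrics
#'
#' Accuracy `(TP+TN)/(TP+FN+TN+FP)`, sensitivity `TP/(TP+FN)` and
#' specificity `TN/(TN+FP)`. The positive class is the patient group by
#' convention.
#'
#' @param TP,FN,TN,FP Non-negative integer counts; each class must be
#'   non-empty (`TP+FN >= 1`, `TN+FP >= 1`).
#' @return Named list `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(TP, FN, TN, FP) {
  cnt <- c(TP, FN, TN, FP)
  if (any(cnt < 0) || any(cnt != round(cnt))) stop("counts must be non-negative integers")
  if (TP + FN < 1 || TN + FP < 1) stop("each class must contain at least one subject")
  list(accuracy = (TP + TN) / (TP + FN + TN + FP),
       sensitivity = TP / (TP + FN),
       specificity = TN / (TN + FP))
}

#' ROC curve and AUC from decision values
#'
#' AUC is the rank (Mann–Whitney) statistic: the probability that a random
#' positive outscores a random negative, ties counted one half. ROC points
#' sweep every observed threshold from the pooled decision values.
#'
#' @param decision_values Numeric scores (larger = more positive).
#' @param labels -1/+1 vector, both classes present.
#' @return List with `auc` and `roc_points` (data frame `fpr`, `tpr`).
#' @export
roc_auc <- function(decision_values, labels) {
  y <- as.numeric(labels)
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2)
    stop("labels must be -1/+1 with both classes present")
  npos <- sum(y == 1); nneg <- sum(y == -1)
  r <- rank(decision_values, ties.method = "average")
  auc <- (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  th <- c(Inf, sort(unique(decision_values), decreasing = TRUE))
  pts <- t(vapply(th, function(t) {
    pred_pos <- decision_values >= t
    c(fpr = sum(pred_pos & y == -1) / nneg,
      tpr = sum(pred_pos & y == 1) / npos)
  }, numeric(2)))
  list(auc = auc, roc_points = data.frame(fpr = pts[, "fpr"],
                                          tpr = pts[, "tpr"]))
}

# one training/scoring pass shared by every fold: scale -> select ->
# split by mode -> fit -> score the held-out rows
.fit_fold <- function(tab, train_idx, test_idx, C, count_or_fraction,
                      spec, selection, mode, seed = 1L) {
  Xtr <- tab$features[train_idx, , drop = FALSE]
  ytr <- tab$labels[train_idx]
  scaler <- fit_scaler(Xtr)
  Xtr <- apply_scaler(Xtr, scaler)
  Xte <- apply_scaler(tab$features[test_idx, , drop = FALSE], scaler)

  sel_res <- if (selection == "fscore") f_scores(Xtr, ytr)
             else lasso_select(Xtr, ytr, seed = seed)
  selected <- if (selection == "fscore")
    select_top(sel_res, count_or_fraction)$selected
  else {
    s <- sel_res$selected
    if (length(s) == 0) s <- sel_res$ranked[1]
    s
  }

  kinds <- c("FN", "FA", "MD")
  if (mode == "multi_kernel") {
    sel_nets <- lapply(kinds, function(k)
      selected[selected %in% network_block(tab, k)])
    net_kinds <- kinds
  } else if (mode == "single_kernel_fused") {
    sel_nets <- list(sort(selected))
    net_kinds <- "fused"
  } else if (grepl("^single_network:", mode)) {
    k <- sub("^single_network:", "", mode)
    if (!k %in% kinds) stop("unknown network kind in mode: ", mode)
    blk <- network_block(tab, k)
    s <- selected[selected %in% blk]
    if (length(s) == 0) {    # fall back to the block's top-ranked feature
      rk <- sel_res$ranked
      s <- rk[rk %in% blk][1]
    }
    sel_nets <- list(sort(s))
    net_kinds <- k
  } else stop("unknown mode: ", mode)
  sel_nets <- lapply(sel_nets, sort)

  model <- fit_mkl_model(
    lapply(sel_nets, function(s) Xtr[, s, drop = FALSE]),
    ytr, C, spec, selected_per_network = sel_nets,
    network_kinds = net_kinds, scaler = scaler)
  dec <- decision_values(model,
    lapply(sel_nets, function(s) Xte[, s, drop = FALSE]))
  pw <- if (spec$kind == "linear") primal_weights_linear(model) else NULL
  list(model = model, decision = dec, selected = sort(selected),
       selected_per_network = sel_nets, beta = model$beta,
       primal_weights = pw)
}

#' Leave-one-out cross-validation of the multi-weight classifier
#'
#' Each subject is held out once; on the remaining subjects, in order:
#' normalization statistics are fitted, features are selected (F-score
#' top-k or lasso), the selected columns are split per network
#' (`multi_kernel`), kept pooled as one concatenated vector
#' (`single_kernel_fused`, direct data fusion), or restricted to one
#' network block (`single_network:FN/FA/MD`); the (multi-)kernel SVM is
#' trained and the held-out subject scored. Nothing from the held-out
#' subject influences scaling, selection or training.
#'
#' @param tab A `feature_table`.
#' @param C Box constraint.
#' @param count_or_fraction Feature count or fraction for
#'   [select_top()] (ignored by lasso, which selects by its penalty).
#' @param spec A [kernel_spec()].
#' @param selection `"fscore"` or `"lasso"`.
#' @param mode `"multi_kernel"`, `"single_kernel_fused"` or
#'   `"single_network:FN"` / `":FA"` / `":MD"`.
#' @param seed Seed forwarded to the lasso fold assignment.
#' @return An `evaluation_report`: confusion counts, accuracy /
#'   sensitivity / specificity, `auc`, `roc_points`, per-fold records and
#'   the configuration.
#' @export
loocv <- function(tab, C = 1, count_or_fraction = 0.0014,
                  spec = kernel_spec("linear"), selection = "fscore",
                  mode = "multi_kernel", seed = 1L) {
  stopifnot(inherits(tab, "feature_table"))
  selection <- match.arg(selection, c("fscore", "lasso"))
  n <- nrow(tab$features)
  if (n < 4 || sum(tab$labels == 1) < 2 || sum(tab$labels == -1) < 2)
    stop("need n >= 4 with both classes >= 2")
  folds <- lapply(seq_len(n), function(i) {
    ft <- .fit_fold(tab, setdiff(seq_len(n), i), i, C, count_or_fraction,
                    spec, selection, mode, seed = seed)
    list(test_subject_id = tab$subject_ids[i],
         true_label = tab$labels[i],
         predicted_label = predict_labels(ft$decision),
         decision_value = ft$decision,
         selected_features = ft$selected,
         selected_per_network = ft$selected_per_network,
         beta = ft$beta, primal_weights = ft$primal_weights)
  })
  truth <- vapply(folds, `[[`, numeric(1), "true_label")
  pred <- vapply(folds, `[[`, numeric(1), "predicted_label")
  dec <- vapply(folds, `[[`, numeric(1), "decision_value")
  TP <- sum(truth == 1 & pred == 1); FN <- sum(truth == 1 & pred == -1)
  TN <- sum(truth == -1 & pred == -1); FP <- sum(truth == -1 & pred == 1)
  met <- confusion_metrics(TP, FN, TN, FP)
  roc <- roc_auc(dec, truth)
  structure(list(counts = c(TP = TP, FN = FN, TN = TN, FP = FP),
                 accuracy = met$accuracy, sensitivity = met$sensitivity,
                 specificity = met$specificity, auc = roc$auc,
                 roc_points = roc$roc_points, folds = folds,
                 config = list(C = C, count_or_fraction = count_or_fraction,
                               kernel = spec, selection = selection,
                               mode = mode, seed = seed)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report (%s, %s): acc %.3f, sens %.3f, spec %.3f, AUC %.3f (n = %d)\n",
    x$config$mode, x$config$selection, x$accuracy, x$sensitivity,
    x$specificity, x$auc, length(x$folds)))
  invisible(x)
}

#' Default hyperparameter grids
#'
#' The box constraint C is varied from 0.5 to 5 in steps of 0.5 (10
#' values) and the selected-feature fraction from 0.0014 to 0.0028 in
#' steps of 0.00005 (29 values).
#'
#' @return Numeric vector.
#' @export
default_c_grid <- function() seq(0.5, 5, by = 0.5)

#' @rdname default_c_grid
#' @export
default_fraction_grid <- function() seq(28L, 56L, by = 1L) / 20000

#' Grid search over C and feature fraction
#'
#' Runs one complete LOOCV per grid cell and returns the full accuracy
#' surface. The best configuration maximizes accuracy; ties are broken by
#' the smaller feature count, then the smaller C. This optimizes the same
#' cross-validation that is reported (no outer nesting), so the selected
#' cell's accuracy is an optimistically biased estimate.
#'
#' @param tab A `feature_table`.
#' @param c_grid,fraction_grid Non-empty numeric grids.
#' @inheritParams loocv
#' @return List with `best` (C, count_or_fraction, accuracy, report) and
#'   `surface` (data frame C x fraction x metrics).
#' @export
grid_search <- function(tab, c_grid = default_c_grid(),
                        fraction_grid = default_fraction_grid(),
                        spec = kernel_spec("linear"), selection = "fscore",
                        mode = "multi_kernel", seed = 1L) {
  if (length(c_grid) == 0 || length(fraction_grid) == 0)
    stop("grids must be non-empty")
  cells <- expand.grid(C = c_grid, fraction = fraction_grid,
                       KEEP.OUT.ATTRS = FALSE)
  reports <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    reports[[r]] <- loocv(tab, C = cells$C[r],
                          count_or_fraction = cells$fraction[r],
                          spec = spec, selection = selection, mode = mode,
                          seed = seed)
  }
  surface <- cbind(cells, data.frame(
    accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
    sensitivity = vapply(reports, `[[`, numeric(1), "sensitivity"),
    specificity = vapply(reports, `[[`, numeric(1), "specificity"),
    auc = vapply(reports, `[[`, numeric(1), "auc")))
  k_of <- function(f) if (f > 0 && f < 1)
    max(1, round(f * ncol(tab$features))) else f
  ord <- order(-surface$accuracy, vapply(surface$fraction, k_of, numeric(1)),
               surface$C)
  best_row <- ord[1]
  list(best = list(C = surface$C[best_row],
                   count_or_fraction = surface$fraction[best_row],
                   accuracy = surface$accuracy[best_row],
                   report = reports[[best_row]]),
       surface = surface)
}
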