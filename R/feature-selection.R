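# Two-step feature selection: linear-SVM |w_j| ranking to the optimal
# feature candidates (OFCs), then incremental feature selection (IFS) under
# repeated cross-validated random-forest AUC.

# Stratified fold assignment: both classes appear in every fold.
#' @keywords internal
#' @noRd
make_folds <- function(y, folds, seed) {
  with_seed(seed, {
    f <- integer(length(y))
    for (cls in unique(y)) {
      k <- which(y == cls)
      f[k] <- sample(rep(seq_len(folds), length.out = length(k)))
    }
    f
  })
}

#' Rank features by linear-SVM weight magnitude
#'
#' Fits a soft-margin linear-kernel SVM on z-scored features and ranks
#' features by the absolute value of their weight-vector component
#' `|w_j|`, `w = sum_i alpha_i y_i x_i` over the support vectors. Ties are
#' broken by original column order; zero-variance features receive weight 0.
#'
#' @param x numeric feature matrix with column names.
#' @param y binary labels (0/1 or a two-level factor).
#' @param C soft-margin cost constant.
#' @return List of class `svm_rank`: `weights` (named `|w_j|`, input
#'   order), `ranking` (feature names, decreasing weight), `C`.
#' @export
svm_rank <- function(x, y, C = 1.0) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  yf <- as.factor(y)
  if (nlevels(yf) != 2) stop_gs("svm_rank requires exactly two classes")
  if (min(table(yf)) < 2) stop_gs("need at least two samples per class")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  keep <- sdv > 0
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  fit <- e1071::svm(x = z, y = yf, kernel = "linear", cost = C,
                    scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  weights <- stats::setNames(numeric(ncol(x)), colnames(x))
  weights[keep] <- abs(w)
  ord <- order(-weights, seq_along(weights))
  structure(list(weights = weights,
                 ranking = colnames(x)[ord],
                 C = C),
            class = "svm_rank")
}

#' @export
print.svm_rank <- function(x, ...) {
  cat(sprintf("<svm_rank> %d features (C = %g); top 5: %s\n",
              length(x$weights), x$C,
              paste(utils::head(x$ranking, 5), collapse = ", ")))
  invisible(x)
}

#' Top-k optimal feature candidates
#'
#' @param rank an `svm_rank` result.
#' @param k number of candidates (clamped to the number of features).
#' @return Character vector: the first `min(k, n)` names of the ranking.
#' @export
top_k <- function(rank, k = 300) {
  stopifnot(inherits(rank, "svm_rank"), k >= 1)
  utils::head(rank$ranking, k)
}

# One CV round of held-out RF scores for the columns `cols` of x.
# Uses ranger holdout mode: observations with case weight 0 are excluded
# from training and r$predictions holds their all-tree predictions.
#' @keywords internal
#' @noRd
rf_cv_scores <- function(x, y01, cols, fold_id, folds, num.trees, seed,
                         probability = FALSE, compact = FALSE) {
  scores <- numeric(length(y01))
  xs <- x[, cols, drop = FALSE]
  yr <- if (probability) factor(y01, levels = c(0, 1)) else as.numeric(y01)
  # compact forests (IFS): larger leaves and 0.632 subsampling without
  # replacement; per-fit noise averages out over the folds x rounds grid
  extra <- if (compact)
    list(min.node.size = 10, sample.fraction = 0.632, replace = FALSE)
  else list()
  for (f in seq_len(folds)) {
    w <- as.numeric(fold_id != f)
    fit <- do.call(ranger::ranger,
                   c(list(x = xs, y = yr, num.trees = num.trees,
                          mtry = max(1, floor(sqrt(ncol(xs)))),
                          probability = probability,
                          case.weights = w, holdout = TRUE,
                          num.threads = 1,
                          seed = child_seed(seed, f)),
                     extra))
    if (probability) scores[fold_id == f] <- fit$predictions[fold_id == f, "1"]
    else scores[fold_id == f] <- fit$predictions[fold_id == f]
  }
  scores
}

#' Incremental feature selection by repeated cross-validated RF AUC
#'
#' Grows feature prefixes `{f_1}, {f_1, f_2}, ...` over the ordered
#' candidate list and evaluates each prefix by the AUC of pooled
#' out-of-fold random-forest scores under stratified k-fold
#' cross-validation, repeated for `rounds` rounds with freshly seeded fold
#' assignments and forests. The optimal feature set (OFS) is the prefix
#' with maximal mean AUC, ties resolved to the smallest prefix.
#'
#' The forests inside IFS are compact regression forests on the 0/1 labels
#' (`num.trees` trees); their held-out predictions are used purely as
#' ranking scores for the AUC, which keeps the full 300-prefix curve
#' tractable on a single CPU.
#'
#' @param x numeric feature matrix with column names.
#' @param y binary labels (0/1).
#' @param ofc ordered candidate feature names (subset of `colnames(x)`).
#' @param folds number of CV folds.
#' @param rounds number of repetition rounds.
#' @param num.trees trees per forest inside IFS.
#' @param seed integer seed; results are deterministic given the seed.
#' @return List of class `ifs_result`: `ofc`, `auc_curve` (mean AUC per
#'   prefix), `sd_curve` (between-round SD), `ofs`, `best_auc`, `rounds`,
#'   `folds`, `seed`.
#' @export
incremental_feature_selection <- function(x, y, ofc, folds = 5, rounds = 20,
                                          num.trees = 15, seed = 1) {
  x <- as.matrix(x)
  if (!length(ofc)) stop_gs("empty candidate list")
  if (!all(ofc %in% colnames(x))) stop_gs("ofc contains unknown feature names")
  y01 <- as.integer(as.character(factor(y, labels = c(0, 1))))
  n <- length(ofc)
  auc_rounds <- matrix(NA_real_, rounds, n)
  for (r in seq_len(rounds)) {
    fold_id <- make_folds(y01, folds, child_seed(seed, r, 0))
    for (i in seq_len(n)) {
      s <- rf_cv_scores(x, y01, ofc[seq_len(i)], fold_id, folds,
                        num.trees, child_seed(seed, r, i), compact = TRUE)
      auc_rounds[r, i] <- auc_rank(y01, s)
    }
  }
  curve <- colMeans(auc_rounds)
  sdc <- apply(auc_rounds, 2, stats::sd)
  best <- which(curve >= max(curve) - 1e-12)[1]
  structure(list(ofc = ofc,
                 auc_curve = curve,
                 sd_curve = sdc,
                 auc_rounds = auc_rounds,
                 ofs = ofc[seq_len(best)],
                 best_auc = curve[best],
                 rounds = rounds, folds = folds, seed = seed),
            class = "ifs_result")
}

#' @export
print.ifs_result <- function(x, ...) {
  cat(sprintf("<ifs_result> %d candidates, %d-fold CV x %d rounds\n",
              length(x$ofc), x$folds, x$rounds))
  cat(sprintf(" optimal feature set: %d features, mean AUC %.4f\n",
              length(x$ofs), x$best_auc))
  invisible(x)
}

#' Export an IFS curve as TSV
#'
#' @param ifs an `ifs_result`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_ifs_curve <- function(ifs, path) {
  utils::write.table(
    data.frame(prefix_size = seq_along(ifs$auc_curve),
               mean_auc = ifs$auc_curve, sd_auc = ifs$sd_curve),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
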