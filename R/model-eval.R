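# Random-forest training, scoring, the six performance measures
# (Sn/Sp/Pre/ACC/MCC/AUC) with ROC curves, specificity-calibrated decision
# thresholds, repeated cross-validation and proteome screening.

#' Rank-statistic AUC
#'
#' Area under the ROC curve by the Mann-Whitney statistic: the probability
#' that a random positive outscores a random negative, ties counted 1/2.
#'
#' @param y binary labels (0/1).
#' @param scores numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(y, scores) {
  y <- as.integer(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop_gs("AUC undefined: both classes required")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics and ROC at a decision threshold
#'
#' Calls are `score >= threshold`. Sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)`, accuracy `(TP+TN)/n`, Matthews
#' correlation coefficient with the zero-denominator convention MCC = 0,
#' and rank-statistic AUC. The ROC curve is swept over all score
#' thresholds and anchored at (0,0) and (1,1).
#'
#' @param y binary labels (0/1).
#' @param scores numeric scores.
#' @param threshold decision threshold (default 0.5).
#' @return List of class `metrics_report`: `sensitivity`, `specificity`,
#'   `precision`, `accuracy`, `mcc`, `auc`, `roc` (data.frame `fpr`,
#'   `tpr`), `threshold`, and the confusion counts.
#' @export
compute_metrics <- function(y, scores, threshold = 0.5) {
  y <- as.integer(y)
  stopifnot(length(y) == length(scores))
  if (!length(y)) stop_gs("empty input")
  if (length(unique(y)) < 2) stop_gs("AUC undefined: both classes required")
  call_pos <- scores >= threshold
  tp <- sum(call_pos & y == 1)
  tn <- sum(!call_pos & y == 0)
  fp <- sum(call_pos & y == 0)
  fn <- sum(!call_pos & y == 1)
  den <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(den == 0)) 0 else
    (tp * tn - fp * fn) / sqrt(prod(as.numeric(den)))
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1), numeric(1)) / sum(y == 1)
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0), numeric(1)) / sum(y == 0)
  roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  roc <- roc[order(roc$fpr, roc$tpr), , drop = FALSE]
  structure(list(sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
                 accuracy = (tp + tn) / length(y),
                 mcc = mcc,
                 auc = auc_rank(y, scores),
                 roc = roc,
                 threshold = threshold,
                 counts = c(tp = tp, tn = tn, fp = fp, fn = fn)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> threshold %.3f\n", x$threshold))
  cat(sprintf(" Sn %.4f  Sp %.4f  Pre %s  ACC %.4f  MCC %.4f  AUC %.4f\n",
              x$sensitivity, x$specificity,
              ifelse(is.na(x$precision), "NA", sprintf("%.4f", x$precision)),
              x$accuracy, x$mcc, x$auc))
  invisible(x)
}

#' Train the random-forest site classifier
#'
#' Fits a probability forest on a labeled feature matrix. Prediction
#' refuses feature matrices whose column names or order differ from the
#' training features.
#'
#' @param x numeric feature matrix with column names.
#' @param y binary labels (0/1).
#' @param feature_names feature subset to train on (default: all columns).
#' @param num.trees number of trees.
#' @param seed integer seed for the forest.
#' @return Object of class `glyco_rf`.
#' @export
train_rf <- function(x, y, feature_names = colnames(x), num.trees = 500,
                     seed = 1) {
  x <- as.matrix(x)
  yf <- factor(as.integer(y), levels = c(0, 1))
  if (nlevels(droplevels(yf)) < 2) stop_gs("both classes required to train")
  stopifnot(all(feature_names %in% colnames(x)))
  xs <- x[, feature_names, drop = FALSE]
  forest <- ranger::ranger(x = xs, y = yf, num.trees = num.trees,
                           mtry = max(1, floor(sqrt(ncol(xs)))),
                           probability = TRUE, num.threads = 1, seed = seed)
  structure(list(feature_names = feature_names,
                 num.trees = num.trees,
                 seed = seed,
                 forest = forest,
                 meta = list(n = nrow(xs), p = ncol(xs),
                             class_counts = table(yf))),
            class = "glyco_rf")
}

#' @export
print.glyco_rf <- function(x, ...) {
  cat(sprintf("<glyco_rf> %d trees on %d features (n = %d; seed %d)\n",
              x$num.trees, length(x$feature_names), x$meta$n, x$seed))
  invisible(x)
}

#' Score sites with a trained forest
#'
#' @param model a `glyco_rf`.
#' @param x feature matrix; columns must equal the training features in
#'   name and order.
#' @return Numeric vector of positive-class probabilities in `[0, 1]`.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "glyco_rf"))
  x <- as.matrix(x)
  if (!all(model$feature_names %in% colnames(x)))
    stop_gs("feature names do not match the trained model")
  xs <- x[, model$feature_names, drop = FALSE]
  if (!identical(colnames(xs), model$feature_names))
    stop_gs("feature order does not match the trained model")
  as.numeric(stats::predict(model$forest, data = xs,
                            num.threads = 1)$predictions[, "1"])
}

#' Decision threshold at a target specificity
#'
#' Smallest threshold `t` (among observed scores, plus one value just above
#' the maximum) such that the fraction of negatives scoring strictly below
#' `t` reaches the target specificity under the `score >= t` calling rule.
#'
#' @param neg_scores scores of negative (non-site) examples.
#' @param target_sp target specificity (default 0.99, the high-confidence
#'   proteome-screening level).
#' @return List with `threshold` and the achieved `specificity`.
#' @export
threshold_at_specificity <- function(neg_scores, target_sp = 0.99) {
  if (!length(neg_scores)) stop_gs("no negative scores")
  cand <- c(sort(unique(neg_scores)), max(neg_scores) + 1e-9)
  sp <- vapply(cand, function(t) mean(neg_scores < t), numeric(1))
  k <- which(sp >= target_sp)[1]
  if (is.na(k)) k <- length(cand)
  list(threshold = cand[k], specificity = sp[k])
}

#' Repeated stratified cross-validation of the RF classifier
#'
#' For each round, assigns stratified folds, pools the held-out forest
#' scores over folds, and computes the six performance measures. Mean
#' metrics over rounds are reported alongside the per-round values.
#'
#' @param x numeric feature matrix.
#' @param y binary labels (0/1).
#' @param feature_names feature subset (default all columns).
#' @param folds number of folds.
#' @param rounds number of repetition rounds.
#' @param num.trees trees per forest.
#' @param threshold decision threshold for the thresholded metrics.
#' @param seed integer seed.
#' @return List of class `cv_result`: `per_round` (list of
#'   `metrics_report`), `mean` (named vector of mean Sn/Sp/Pre/ACC/MCC/AUC),
#'   `folds`, `rounds`, `seed`.
#' @export
cross_validate <- function(x, y, feature_names = colnames(x), folds = 5,
                           rounds = 20, num.trees = 500, threshold = 0.5,
                           seed = 1) {
  x <- as.matrix(x)[, feature_names, drop = FALSE]
  y01 <- as.integer(y)
  if (min(table(y01)) < folds)
    stop_gs("too few samples in a class for ", folds, "-fold stratification")
  per_round <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    fold_id <- make_folds(y01, folds, child_seed(seed, r, 0))
    s <- rf_cv_scores(x, y01, colnames(x), fold_id, folds, num.trees,
                      child_seed(seed, r, 1), probability = TRUE)
    per_round[[r]] <- compute_metrics(y01, s, threshold)
  }
  metric_names <- c("sensitivity", "specificity", "precision", "accuracy",
                    "mcc", "auc")
  m <- vapply(per_round, function(r) unlist(r[metric_names]), numeric(6))
  structure(list(per_round = per_round,
                 mean = rowMeans(m),
                 folds = folds, rounds = rounds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV x %d rounds\n", x$folds, x$rounds))
  cat(" mean:", paste(sprintf("%s %.4f", names(x$mean), x$mean),
                      collapse = "  "), "\n")
  invisible(x)
}

#' Screen candidate sites at a calibrated threshold
#'
#' Scores every candidate site of an encoded feature table and calls sites
#' with `score >= threshold`. Site numbering in the output uses the PDB
#' author numbering carried in the site metadata.
#'
#' @param model a `glyco_rf`.
#' @param feats encoded feature data.frame from [encode_sites()] (row-bound
#'   over structures), with metadata columns.
#' @param threshold decision threshold, typically from
#'   [threshold_at_specificity()].
#' @param sites optional site-record data.frame aligned with `feats`
#'   supplying `author` numbers and sequon flags.
#' @return List with `sites` (per-candidate table: score, call, sequon) and
#'   `proteins` (per-structure called-site counts).
#' @export
screen <- function(model, feats, threshold, sites = NULL) {
  fm <- feature_matrix(feats)
  if (nrow(fm$meta) == 0)
    return(list(sites = data.frame(), proteins = data.frame()))
  scores <- predict_scores(model, fm$x)
  out <- fm$meta
  out$author <- if (!is.null(sites)) sites$author else NA
  out$sequon <- if (!is.null(sites)) sites$sequon else NA
  out$score <- scores
  out$call <- scores >= threshold
  agg <- stats::aggregate(call ~ structure_id, data = out, FUN = sum)
  names(agg)[2] <- "n_called"
  list(sites = out, proteins = agg)
}
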