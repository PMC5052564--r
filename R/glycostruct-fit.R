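# The user-facing model class: one fitting function running the two-step
# feature selection and the final random forest, returning a classed object
# with the usual methods.

#' Fit a structure-aware glycosylation-site classifier
#'
#' Runs the full modelling pipeline on an encoded site feature matrix:
#' (1) linear-SVM weight ranking of all features ([svm_rank()]),
#' (2) truncation to the top-`k` optimal feature candidates ([top_k()]),
#' (3) incremental feature selection under repeated cross-validated
#'     random-forest AUC ([incremental_feature_selection()]), and
#' (4) a final probability random forest trained on the optimal feature
#'     set ([train_rf()]).
#'
#' @param x numeric feature matrix with named columns (typically from
#'   [encode_sites()] via [feature_matrix()]), or a data.frame from
#'   [encode_sites()] in which case labels are taken from its metadata.
#' @param y binary labels (0/1); ignored when `x` carries labels.
#' @param glyco_type `"N"` or `"O"`, recorded in the model.
#' @param k number of optimal feature candidates kept after SVM ranking.
#' @param C SVM soft-margin cost.
#' @param folds,rounds cross-validation scheme used inside IFS.
#' @param ifs.trees trees per forest inside IFS (compact forests keep the
#'   full candidate curve tractable).
#' @param num.trees trees of the final forest.
#' @param seed integer seed governing all randomness.
#' @return Object of class `glycostruct`: the `svm_rank` result, the
#'   `ifs_result`, the selected feature names (`ofs`), the fitted
#'   `glyco_rf` model, and the call configuration.
#' @examples
#' \donttest{
#' ds <- generate_dataset(synth_spec(n_proteins = 12, seed = 7),
#'                        plant_rule(seed = 7))
#' feats <- do.call(rbind, lapply(names(ds$structures), function(sid)
#'   encode_sites(ds$structures[[sid]], ds$pssms[[sid]], ds$sites)))
#' fm <- feature_matrix(feats)
#' fit <- glycostruct(fm$x, fm$y, k = 40, rounds = 2, seed = 1)
#' print(fit)
#' }
#' @export
glycostruct <- function(x, y = NULL, glyco_type = "N", k = 300, C = 1.0,
                        folds = 5, rounds = 20, ifs.trees = 15,
                        num.trees = 500, seed = 1) {
  if (is.data.frame(x) && "label" %in% colnames(x)) {
    fm <- feature_matrix(x)
    x <- fm$x
    y <- fm$y
  }
  x <- as.matrix(x)
  y <- as.integer(y)
  if (anyNA(y)) stop_gs("labels contain unknowns; filter before fitting")
  rank <- svm_rank(x, y, C = C)
  ofc <- top_k(rank, k)
  ifs <- incremental_feature_selection(x, y, ofc, folds = folds,
                                       rounds = rounds,
                                       num.trees = ifs.trees,
                                       seed = child_seed(seed, 1))
  model <- train_rf(x, y, feature_names = ifs$ofs, num.trees = num.trees,
                    seed = child_seed(seed, 2))
  structure(list(glyco_type = glyco_type,
                 rank = rank,
                 ifs = ifs,
                 ofs = ifs$ofs,
                 model = model,
                 n = nrow(x), p = ncol(x),
                 config = list(k = k, C = C, folds = folds, rounds = rounds,
                               ifs.trees = ifs.trees, num.trees = num.trees,
                               seed = seed)),
            class = "glycostruct")
}

#' @export
print.glycostruct <- function(x, ...) {
  cat(sprintf("Structure-aware %s-glycosylation site classifier\n", x$glyco_type))
  cat(sprintf("  training sites: %d   input features: %d\n", x$n, x$p))
  cat(sprintf("  optimal feature set: %d features (IFS mean CV AUC %.4f)\n",
              length(x$ofs), x$ifs$best_auc))
  cat(sprintf("  final forest: %d trees\n", x$model$num.trees))
  invisible(x)
}

#' @export
summary.glycostruct <- function(object, ...) {
  w <- object$rank$weights[object$ofs]
  tab <- data.frame(num = seq_along(object$ofs),
                    feature = object$ofs,
                    svm_weight = unname(w))
  out <- list(glyco_type = object$glyco_type,
              n = object$n, p = object$p,
              ofs = tab,
              best_auc = object$ifs$best_auc,
              auc_curve = object$ifs$auc_curve,
              config = object$config)
  class(out) <- "summary.glycostruct"
  out
}

#' @export
print.summary.glycostruct <- function(x, ...) {
  cat(sprintf("%s-glycosylation classifier: %d sites, %d -> %d features\n",
              x$glyco_type, x$n, x$p, nrow(x$ofs)))
  cat(sprintf("IFS best mean CV AUC: %.4f at prefix %d\n", x$best_auc,
              nrow(x$ofs)))
  cat("Selected optimal features:\n")
  print(x$ofs, row.names = FALSE)
  invisible(x)
}

#' @export
coef.glycostruct <- function(object, all = FALSE, ...) {
  if (all) object$rank$weights
  else object$rank$weights[object$ofs]
}

#' Predict glycosylation-site scores or calls
#'
#' @param object a fitted `glycostruct` model.
#' @param newdata feature matrix or [encode_sites()] data.frame containing
#'   at least the model's selected features.
#' @param type `"score"` for positive-class probabilities, `"class"` for
#'   thresholded 0/1 calls.
#' @param threshold decision threshold for `type = "class"`.
#' @param ... unused.
#' @return Numeric score vector or integer call vector.
#' @export
predict.glycostruct <- function(object, newdata,
                                type = c("score", "class"),
                                threshold = 0.5, ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata) && "label" %in% colnames(newdata))
    newdata <- feature_matrix(newdata)$x
  s <- predict_scores(object$model, as.matrix(newdata))
  if (type == "score") s else as.integer(s >= threshold)
}

#' Plot the incremental-feature-selection curve
#'
#' Mean cross-validated AUC against prefix size, with the selected prefix
#' marked.
#'
#' @param x a fitted `glycostruct` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.glycostruct <- function(x, ...) {
  curve <- x$ifs$auc_curve
  graphics::plot(seq_along(curve), curve, type = "l",
                 xlab = "number of top-ranked features",
                 ylab = "mean CV AUC", ...)
  best <- length(x$ofs)
  graphics::abline(v = best, lty = 2, col = "grey40")
  graphics::points(best, curve[best], pch = 19, col = "red3")
  invisible(x)
}
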