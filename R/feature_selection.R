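# Univariate feature screening: ROC/AUC of each feature's ability to
# separate positive from negative pairs, keeping features with AUC above a
# threshold (default 0.6). AUC is the Mann-Whitney rank statistic (ties
# count 0.5), which equals the trapezoidal area under the ROC curve.

#' ROC curve and AUC for one score vector
#'
#' AUC equals the probability that a random positive outscores a random
#' negative, with ties counted 0.5 (the Mann-Whitney identity). Missing
#' scores are dropped with a reported count. The ROC points sweep all
#' distinct score cutoffs from high to low, starting at (0, 0) and ending
#' at (1, 1).
#'
#' @param scores_pos,scores_neg numeric score vectors for positives and
#'   negatives; both must be non-empty after dropping `NA`.
#' @param feature_name optional label.
#' @return object of class `feature_evaluation`: list with `feature_name`,
#'   `auc` and `roc_points` (data.frame `fpr`, `tpr`).
#' @export
roc_auc <- function(scores_pos, scores_neg, feature_name = "score") {
  nna <- sum(is.na(scores_pos)) + sum(is.na(scores_neg))
  if (nna > 0) message(nna, " missing score(s) dropped for ", feature_name)
  scores_pos <- scores_pos[!is.na(scores_pos)]
  scores_neg <- scores_neg[!is.na(scores_neg)]
  np <- length(scores_pos)
  nn <- length(scores_neg)
  if (np == 0 || nn == 0) stop("both score classes must be non-empty")
  r <- rank(c(scores_pos, scores_neg))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  # ROC points: descending cutoffs over distinct observed scores
  cuts <- sort(unique(c(scores_pos, scores_neg)), decreasing = TRUE)
  tp <- cumsum(vapply(cuts, function(c_) sum(scores_pos == c_), 0))
  fp <- cumsum(vapply(cuts, function(c_) sum(scores_neg == c_), 0))
  roc <- data.frame(fpr = c(0, fp / nn), tpr = c(0, tp / np))
  structure(list(feature_name = feature_name, auc = auc, roc_points = roc),
            class = "feature_evaluation")
}

#' @export
print.feature_evaluation <- function(x, ...) {
  cat(sprintf("Feature %s: AUC = %.4f (%d ROC points)\n", x$feature_name,
              x$auc, nrow(x$roc_points)))
  invisible(x)
}

#' Evaluate every feature column against pair labels
#'
#' Per-feature complete-case: pairs with a missing value for a feature are
#' dropped from that feature's ROC only.
#'
#' @param fm a `feature_matrix`.
#' @param labels a `labeled_pairs` object covering (a subset of) the rows.
#' @return named list of `feature_evaluation` objects, one per feature
#'   column present in `fm`.
#' @export
evaluate_features <- function(fm, labels) {
  key <- pair_key(fm)
  is_pos <- key %in% pair_key(labels$positives)
  is_neg <- key %in% pair_key(labels$negatives)
  feats <- intersect(feature_names(), names(fm))
  if (length(feats) == 0) feats <- setdiff(names(fm), c("from", "to"))
  out <- lapply(feats, function(f) {
    suppressMessages(roc_auc(fm[[f]][is_pos], fm[[f]][is_neg],
                             feature_name = f))
  })
  names(out) <- feats
  out
}

#' Select informative features by AUC threshold
#'
#' Keeps features whose AUC is strictly greater than the threshold, sorted
#' by decreasing AUC. Features that score higher for non-interacting pairs
#' (AUC < 0.5) are not sign-flipped; they simply fail the one-sided screen.
#'
#' @param evals list of `feature_evaluation` objects (from
#'   [evaluate_features()] or [roc_auc()]).
#' @param threshold AUC cutoff (default 0.6).
#' @return character vector of selected feature names (possibly empty, with
#'   a warning).
#' @export
select_informative_features <- function(evals, threshold = 0.6) {
  aucs <- vapply(evals, function(e) e$auc, 0)
  nms <- vapply(evals, function(e) e$feature_name, "")
  keep <- aucs > threshold
  if (!any(keep)) {
    warning("no feature exceeds AUC threshold ", threshold)
    return(character(0))
  }
  unname(nms[keep][order(-aucs[keep])])
}
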