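# Interactome-size estimation from prediction counts and accuracy. The
# predicted count mixes true interactions recovered at the model's
# sensitivity with non-interactions leaking through at (1 - specificity):
#
#   N_interactome * sensitivity + (N_allpairs - N_interactome) * (1 - specificity) = N_predict
#
# which is solved for N_interactome. Identifiability requires
# sensitivity > 1 - specificity.

#' Estimate the true interactome size
#'
#' Solves the linear prediction-count equation for the number of true
#' interactions, given the predicted count, the number of candidate pairs,
#' and the model's sensitivity and specificity.
#'
#' @param n_predict number of predicted associations.
#' @param n_all_pairs number of candidate gene pairs.
#' @param sensitivity fraction of true interactions the model recovers.
#' @param specificity fraction of non-interacting pairs correctly excluded.
#' @return object of class `size_estimate` with `n_interactome`,
#'   `expected_true_in_predictions` (= n_interactome x sensitivity),
#'   `coverage` (= sensitivity) and the inputs. The estimate is clamped to
#'   \[0, n_all_pairs\] with a warning if the raw solution falls outside.
#' @export
estimate_interactome_size <- function(n_predict, n_all_pairs, sensitivity,
                                      specificity) {
  stopifnot(n_predict >= 0, n_all_pairs > 0, n_predict <= n_all_pairs,
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  fpr <- 1 - specificity
  if (sensitivity <= fpr) {
    stop("not identifiable: requires sensitivity > 1 - specificity (",
         signif(sensitivity, 4), " <= ", signif(fpr, 4), ")")
  }
  n_int <- (n_predict - n_all_pairs * fpr) / (sensitivity - fpr)
  if (n_int < 0 || n_int > n_all_pairs) {
    warning("estimate ", signif(n_int, 4), " outside [0, n_all_pairs]; clamped")
    n_int <- min(max(n_int, 0), n_all_pairs)
  }
  structure(list(n_interactome = n_int,
                 n_predict = n_predict,
                 n_all_pairs = n_all_pairs,
                 sensitivity = sensitivity,
                 specificity = specificity,
                 expected_true_in_predictions = n_int * sensitivity,
                 coverage = sensitivity),
            class = "size_estimate")
}

#' @export
print.size_estimate <- function(x, ...) {
  cat(sprintf(
    "Interactome size estimate: %.0f (from %d predictions over %d pairs; sens %.4f, spec %.4f)\n",
    x$n_interactome, x$n_predict, x$n_all_pairs, x$sensitivity,
    x$specificity))
  invisible(x)
}

#' Expected true positives, reliability and coverage of a prediction set
#'
#' The expected number of true interactions among the predictions is the
#' interactome size times the sensitivity; reliability is that count
#' divided by the number of predicted-only associations (known interactions
#' excluded from the denominator); coverage equals the sensitivity.
#'
#' @param n_interactome (estimated) number of true interactions.
#' @param sensitivity model sensitivity; when estimated at both the
#'   training and the evaluation stage, the lower of the two is the
#'   conservative choice.
#' @param n_predicted_only number of predicted-only associations (> 0).
#' @return list with `expected_true`, `reliability`, `coverage`.
#' @export
reliability_and_coverage <- function(n_interactome, sensitivity,
                                     n_predicted_only) {
  stopifnot(n_interactome > 0, sensitivity > 0, sensitivity <= 1)
  if (n_predicted_only <= 0) stop("n_predicted_only must be positive")
  expected_true <- n_interactome * sensitivity
  list(expected_true = expected_true,
       reliability = expected_true / n_predicted_only,
       coverage = sensitivity)
}
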