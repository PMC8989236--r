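# Gaussian-kernel soft-margin SVM on the labeled pair set: stratified 5-fold
# cross-validated grid search over (sigma, C) maximizing the harmonic mean of
# sensitivity and specificity, final training at the chosen point, and
# all-pairs scoring. Training/prediction delegate to LIBSVM via e1071;
# feature standardization and missing-value imputation are learned on
# training data only and reused verbatim at prediction time.

#' Harmonic mean of sensitivity and specificity
#'
#' `2ab/(a+b)`, defined as 0 when both are 0. The model-selection objective.
#'
#' @param sensitivity,specificity values in \[0, 1\] (vectorized).
#' @return harmonic mean(s).
#' @export
harmonic_mean <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1 | specificity < 0 |
            specificity > 1)) {
    stop("sensitivity and specificity must be in [0, 1]")
  }
  s <- sensitivity + specificity
  ifelse(s == 0, 0, 2 * sensitivity * specificity / s)
}

#' SVM configuration
#'
#' @param sigma_grid Gaussian kernel widths to search (sigma; the LIBSVM
#'   `gamma` is `1/(2 sigma^2)`).
#' @param cost_grid soft-margin costs C to search.
#' @param folds number of cross-validation folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @param imputation `"zero"` (mean-impute in standardized space) or
#'   `"median"` (standardized median).
#' @return object of class `svm_config`.
#' @export
svm_config <- function(sigma_grid = 2^seq(-6, 4, by = 2),
                       cost_grid = 2^seq(-2, 8, by = 2),
                       folds = 5, seed = 1,
                       imputation = c("zero", "median")) {
  stopifnot(length(sigma_grid) > 0, length(cost_grid) > 0, folds >= 2,
            all(sigma_grid > 0), all(cost_grid > 0))
  structure(list(sigma_grid = sigma_grid, cost_grid = cost_grid,
                 folds = folds, seed = seed,
                 imputation = match.arg(imputation)),
            class = "svm_config")
}

# Standardize + impute a numeric feature matrix. If scaler is NULL it is
# learned (training path); otherwise reused verbatim (prediction path).
prepare_x <- function(x, scaler = NULL, imputation = "zero") {
  x <- as.matrix(x)
  if (is.null(scaler)) {
    mu <- apply(x, 2, mean, na.rm = TRUE)
    sg <- apply(x, 2, sd, na.rm = TRUE)
    mu[is.na(mu)] <- 0
    sg[is.na(sg) | sg == 0] <- 1
    med <- apply(sweep(sweep(x, 2, mu), 2, sg, "/"), 2, stats::median,
                 na.rm = TRUE)
    med[is.na(med)] <- 0
    scaler <- list(center = mu, scale = sg, median = med)
  }
  z <- sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
  fill <- if (imputation == "zero") rep(0, ncol(z)) else scaler$median
  for (j in seq_len(ncol(z))) z[is.na(z[, j]), j] <- fill[j]
  list(x = z, scaler = scaler)
}

# Stratified fold assignment: positives and negatives are split separately
# so every fold preserves the class ratio.
make_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# rows of the feature matrix for the labeled pairs, with class labels
labeled_xy <- function(fm, labels, features) {
  key <- pair_key(fm)
  pos <- match(pair_key(labels$positives), key)
  neg <- match(pair_key(labels$negatives), key)
  if (anyNA(pos) || anyNA(neg)) {
    stop("labels cover pairs absent from the feature matrix")
  }
  idx <- c(pos, neg)
  y <- factor(rep(c("pos", "neg"), c(length(pos), length(neg))),
              levels = c("neg", "pos"))
  list(x = as.matrix(fm[idx, features, drop = FALSE]), y = y)
}

fit_svm <- function(x, y, sigma, cost) {
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             gamma = 1 / (2 * sigma^2), cost = cost, scale = FALSE)
}

# signed decision margin, oriented so positive class has positive margin
svm_margin <- function(fit, x, flip = NULL, y = NULL) {
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")[, 1]
  if (is.null(flip)) {
    # orient using training labels: positives should have higher margins
    flip <- mean(dv[y == "pos"]) < mean(dv[y == "neg"])
  }
  list(margin = if (flip) -dv else dv, flip = flip)
}

#' Cross-validated grid search over (sigma, C)
#'
#' Stratified k-fold cross-validation at every grid point; per point the
#' fold-averaged sensitivity and specificity (at decision margin 0) and
#' their harmonic mean are reported, and the point maximizing the harmonic
#' mean is chosen (ties resolved by grid order). Deterministic under the
#' config seed.
#'
#' @param fm a `feature_matrix` containing rows for every labeled pair.
#' @param labels a `labeled_pairs` object.
#' @param config an `svm_config`.
#' @param features feature columns to use (e.g. the AUC-selected set);
#'   default all feature columns present.
#' @return object of class `cv_report`: data.frame `grid` (sigma, cost,
#'   sensitivity, specificity, harmonic_mean) plus `chosen` (named list).
#' @export
grid_search_cv <- function(fm, labels, config = svm_config(),
                           features = NULL) {
  if (is.null(features)) features <- intersect(feature_names(), names(fm))
  if (nrow(labels$positives) < config$folds) {
    stop("fewer positives (", nrow(labels$positives), ") than folds (",
         config$folds, ")")
  }
  xy <- labeled_xy(fm, labels, features)
  fold <- make_folds(xy$y, config$folds, config$seed)
  grid <- expand.grid(sigma = config$sigma_grid, cost = config$cost_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$sensitivity <- NA_real_
  grid$specificity <- NA_real_
  for (g in seq_len(nrow(grid))) {
    sens <- spec <- numeric(config$folds)
    for (f in seq_len(config$folds)) {
      tr <- fold != f
      prep <- prepare_x(xy$x[tr, , drop = FALSE],
                        imputation = config$imputation)
      fit <- fit_svm(prep$x, xy$y[tr], grid$sigma[g], grid$cost[g])
      te <- prepare_x(xy$x[!tr, , drop = FALSE], scaler = prep$scaler,
                      imputation = config$imputation)
      trm <- svm_margin(fit, prep$x, y = xy$y[tr])
      m <- svm_margin(fit, te$x, flip = trm$flip)$margin
      yte <- xy$y[!tr]
      sens[f] <- mean(m[yte == "pos"] > 0)
      spec[f] <- mean(m[yte == "neg"] <= 0)
    }
    grid$sensitivity[g] <- mean(sens)
    grid$specificity[g] <- mean(spec)
  }
  grid$harmonic_mean <- harmonic_mean(grid$sensitivity, grid$specificity)
  best <- which.max(grid$harmonic_mean)
  structure(list(grid = grid,
                 chosen = list(sigma = grid$sigma[best],
                               cost = grid$cost[best],
                               sensitivity = grid$sensitivity[best],
                               specificity = grid$specificity[best],
                               harmonic_mean = grid$harmonic_mean[best]),
                 features = features, config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  with(x$chosen, cat(sprintf(
    "CV grid search (%d points): chosen sigma=%g cost=%g | sens=%.3f spec=%.4f hmean=%.3f\n",
    nrow(x$grid), sigma, cost, sensitivity, specificity, harmonic_mean)))
  invisible(x)
}

#' Train the final SVM at the chosen grid point
#'
#' Fits on all labeled rows with the standardization/imputation learned on
#' those rows; the returned model carries the scaler so prediction applies
#' it verbatim (no leakage).
#'
#' @param fm a `feature_matrix`.
#' @param labels a `labeled_pairs` object.
#' @param chosen list with `sigma` and `cost` (e.g. `cv_report$chosen`).
#' @param features feature columns to use.
#' @param imputation `"zero"` or `"median"`.
#' @return object of class `fa_model`.
#' @export
train_final <- function(fm, labels, chosen, features = NULL,
                        imputation = "zero") {
  if (is.null(features)) features <- intersect(feature_names(), names(fm))
  xy <- labeled_xy(fm, labels, features)
  if (length(unique(xy$y)) < 2) stop("labels are single-class")
  prep <- prepare_x(xy$x, imputation = imputation)
  fit <- fit_svm(prep$x, xy$y, chosen$sigma, chosen$cost)
  flip <- svm_margin(fit, prep$x, y = xy$y)$flip
  structure(list(fit = fit, scaler = prep$scaler, features = features,
                 chosen = chosen, imputation = imputation, flip = flip),
            class = "fa_model")
}

#' @export
print.fa_model <- function(x, ...) {
  cat(sprintf("Gaussian-kernel SVM: sigma=%g cost=%g, %d features, %d SVs\n",
              x$chosen$sigma, x$chosen$cost, length(x$features),
              nrow(x$fit$SV)))
  invisible(x)
}

#' Decision margins for pairs in a feature matrix
#'
#' @param model an `fa_model`.
#' @param fm a `feature_matrix` containing the model's feature columns.
#' @return numeric margins; `> 0` means predicted association.
#' @export
predict_margin <- function(model, fm) {
  x <- as.matrix(fm[, model$features, drop = FALSE])
  z <- prepare_x(x, scaler = model$scaler,
                 imputation = model$imputation)$x
  svm_margin(model$fit, z, flip = model$flip)$margin
}

#' Score all pairs of a gene universe and build the predicted network
#'
#' Builds features for every unordered pair of the universe, scores them
#' with the trained model, keeps pairs with margin > 0 (edge score =
#' margin), then merges in the known positive interactions (union), so the
#' final network contains inferred associations together with the curated
#' known interactions.
#'
#' @param model an `fa_model`.
#' @param universe character vector of gene IDs (length >= 2).
#' @param bundle an `evidence_bundle` used to build pair features.
#' @param known_positives optional canonical pair data.frame merged in
#'   afterwards.
#' @return an `fa_network`; attribute `n_predicted` holds the count of
#'   margin-positive pairs before the union and attribute `predicted_only`
#'   their pair data.frame (used to evaluate the model against held-out
#'   interactions without crediting the merged known set).
#' @export
predict_all_pairs <- function(model, universe, bundle,
                              known_positives = NULL) {
  universe <- sort(unique(as.character(universe)))
  if (length(universe) < 2) stop("universe must contain at least 2 genes")
  cmb <- combn(universe, 2)
  pairs <- data.frame(from = cmb[1, ], to = cmb[2, ],
                      stringsAsFactors = FALSE)
  fm <- suppressMessages(build_feature_matrix(pairs, bundle))
  m <- predict_margin(model, fm)
  pred <- pairs[!is.na(m) & m > 0, , drop = FALSE]
  pred$score <- m[!is.na(m) & m > 0]
  n_predicted <- nrow(pred)
  predicted_only <- pred[, c("from", "to")]
  if (!is.null(known_positives) && nrow(known_positives) > 0) {
    known <- data.frame(from = known_positives$from,
                        to = known_positives$to, score = NA_real_,
                        stringsAsFactors = FALSE)
    pred <- rbind(pred, known)
  }
  net <- network(pred, nodes = universe)
  attr(net, "n_predicted") <- n_predicted
  attr(net, "predicted_only") <- predicted_only
  net
}
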