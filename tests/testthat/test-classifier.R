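# Classifier tests run on a reduced planted fixture (80 genes, strong
# effects, 1:20 ratio) so grid searches stay fast; the full-ratio protocol
# is exercised in the acceptance suite.

sep_fixture <- function(seed = 41) {
  cfg <- small_fixture(seed = seed,
                       effects = list(interolog = 0.8, phylo = 0.95,
                                      domain = 0.8, coloc = 0.9,
                                      coexpr = 0.95, annot = 0.9))
  truth <- generate_true_interactome(cfg)
  bdl <- generate_evidence(truth, cfg)
  pos <- truth$net$edges[, c("from", "to")]
  genes <- rownames(bdl$expression)
  neg <- sample_negatives(genes, pos, seed = seed,
                          n_negatives = 15 * nrow(pos))
  fm <- suppressMessages(build_feature_matrix(rbind(pos, neg), bdl))
  list(fm = fm, labels = labeled_pairs(pos, neg), bundle = bdl,
       genes = genes, truth = truth)
}

test_that("harmonic mean follows its closed form", {
  expect_equal(harmonic_mean(0.2, 1.0), 1 / 3, tolerance = 1e-9)
  expect_equal(harmonic_mean(0.0, 0.99), 0.0)
  for (x in c(0.1, 0.5, 0.9)) expect_equal(harmonic_mean(x, x), x)
  expect_equal(harmonic_mean(0, 0), 0)
  expect_error(harmonic_mean(1.2, 0.5), "\\[0, 1\\]")
})

test_that("svm_config validates grids and folds", {
  expect_error(svm_config(sigma_grid = numeric(0)))
  expect_error(svm_config(folds = 1))
  expect_error(svm_config(cost_grid = -1))
})

test_that("grid search separates a strongly planted fixture", {
  fx <- sep_fixture(41)
  cv <- grid_search_cv(fx$fm, fx$labels,
                       svm_config(sigma_grid = c(1, 4), cost_grid = c(1, 10),
                                  seed = 1))
  expect_gte(cv$chosen$harmonic_mean, 0.9)
  expect_true(all(cv$grid$specificity >= 0 & cv$grid$specificity <= 1))
})

test_that("a single grid point is reported as chosen, deterministically", {
  fx <- sep_fixture(42)
  cv1 <- grid_search_cv(fx$fm, fx$labels,
                        svm_config(sigma_grid = 2, cost_grid = 5, seed = 3))
  expect_equal(nrow(cv1$grid), 1)
  expect_equal(cv1$chosen$sigma, 2)
  expect_equal(cv1$chosen$cost, 5)
  cv2 <- grid_search_cv(fx$fm, fx$labels,
                        svm_config(sigma_grid = 2, cost_grid = 5, seed = 3))
  expect_identical(cv1$grid, cv2$grid)
})

test_that("shuffled labels yield near-zero harmonic mean", {
  fx <- sep_fixture(43)
  hm <- numeric(3)
  for (s in 1:3) {
    set.seed(100 + s)
    allp <- rbind(fx$labels$positives, fx$labels$negatives)
    idx <- sample(nrow(allp))
    np <- nrow(fx$labels$positives)
    shuf <- labeled_pairs(allp[idx[seq_len(np)], ],
                          allp[idx[-seq_len(np)], ])
    cv <- grid_search_cv(fx$fm, shuf,
                         svm_config(sigma_grid = 4, cost_grid = 10,
                                    seed = s))
    hm[s] <- cv$chosen$harmonic_mean
  }
  expect_true(all(hm <= 0.2))
})

test_that("fewer positives than folds is an error", {
  fx <- sep_fixture(44)
  tiny <- labeled_pairs(fx$labels$positives[1:3, ],
                        fx$labels$negatives[1:30, ])
  expect_error(grid_search_cv(fx$fm, tiny, svm_config(folds = 5)),
               "fewer positives")
})

test_that("final model recovers its own training positives and is deterministic", {
  fx <- sep_fixture(45)
  chosen <- list(sigma = 1, cost = 100)
  model <- train_final(fx$fm, fx$labels, chosen)
  m <- predict_margin(model, fx$fm)
  key <- pair_key(fx$fm)
  is_pos <- key %in% pair_key(fx$labels$positives)
  expect_gte(mean(m[is_pos] > 0), 0.95)
  model2 <- train_final(fx$fm, fx$labels, chosen)
  expect_identical(predict_margin(model2, fx$fm), m)
})

test_that("scaler is learned once and reused verbatim at prediction", {
  fx <- sep_fixture(46)
  model <- train_final(fx$fm, fx$labels, list(sigma = 4, cost = 10))
  # predicting any subset must use the stored scaler, not refit it
  sub <- fx$fm[1:10, ]
  m_sub <- predict_margin(model, sub)
  m_all <- predict_margin(model, fx$fm)[1:10]
  expect_equal(m_sub, m_all, tolerance = 1e-10)
})

test_that("degenerate all-constant features do not crash training", {
  fm <- canonical_pairs(sprintf("a%d", 1:20), sprintf("b%d", 1:20))
  fm$coexpr.pcc <- 0
  fm$phylo.jaccard <- 0
  class(fm) <- c("feature_matrix", "data.frame")
  lab <- labeled_pairs(fm[1:5, 1:2], fm[6:20, 1:2])
  model <- train_final(fm, lab, list(sigma = 1, cost = 1),
                       features = c("coexpr.pcc", "phylo.jaccard"))
  expect_true(all(is.finite(predict_margin(model, fm))))
})

test_that("all-pairs prediction unions known positives without duplication", {
  fx <- sep_fixture(47)
  cv <- grid_search_cv(fx$fm, fx$labels,
                       svm_config(sigma_grid = 4, cost_grid = 10, seed = 1))
  model <- train_final(fx$fm, fx$labels, cv$chosen)
  known <- fx$labels$positives[1:30, ]
  net <- predict_all_pairs(model, fx$genes, fx$bundle,
                           known_positives = known)
  n_pred <- attr(net, "n_predicted")
  overlap <- sum(pair_key(known) %in% pair_key(attr(net, "predicted_only")))
  expect_equal(nrow(net$edges), n_pred + nrow(known) - overlap)
  expect_error(predict_all_pairs(model, "one_gene", fx$bundle), "at least 2")
})
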