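test_that("neighbour enrichment matches a direct hypergeometric oracle", {
  # star: g0 connected to n1..n5; all 5 neighbours carry T; background:
  # 100 annotated genes, 5 with T (the neighbours themselves)
  nb <- sprintf("n%d", 1:5)
  others <- sprintf("o%d", 1:95)
  net <- network(data.frame(from = "g0", to = nb))
  ann <- rbind(data.frame(gene = nb, term = "T"),
               data.frame(gene = c(nb, others),
                          term = "Tbg"))  # everyone has a background term
  pr <- neighbor_enrichment_predict("g0", net, ann, p_cutoff = 1)
  pT <- pr$p[pr$term == "T"]
  # oracle: P(X >= 5), X ~ Hypergeom(N=100, K=5, n=5), by direct summation
  N <- 100; K <- 5; n <- 5
  oracle <- sum(vapply(5:5, function(k)
    choose(K, k) * choose(N - K, n - k) / choose(N, n), 0))
  expect_equal(pT, oracle, tolerance = 1e-12)
  # the common term is not enriched
  expect_gt(pr$p[pr$term == "Tbg"], 0.5)
})

test_that("gene's own annotations are excluded from its evidence", {
  net <- network(data.frame(from = "g0", to = c("n1", "n2")))
  ann <- data.frame(gene = c("g0", "n1", "n2", "x1", "x2"),
                    term = c("T", "T", "T", "A", "A"))
  pr <- neighbor_enrichment_predict("g0", net, ann, p_cutoff = 1)
  # background is 4 annotated genes (g0 removed), K = 2 genes with T
  expect_equal(pr$p[pr$term == "T"],
               choose(2, 2) * choose(2, 0) / choose(4, 2), tolerance = 1e-12)
})

test_that("isolated genes and p_cutoff = 1 behave per contract", {
  net <- network(data.frame(from = "a", to = "b"), nodes = c("a", "b", "c"))
  ann <- data.frame(gene = c("a", "b"), term = c("T1", "T2"))
  expect_equal(nrow(neighbor_enrichment_predict("c", net, ann)), 0)
  pr <- neighbor_enrichment_predict("a", net, ann, p_cutoff = 1)
  expect_equal(pr$term, "T2")  # every neighbour term present
})

test_that("precision and recall follow their asymmetric definitions", {
  split <- annotation_split(old = data.frame(gene = "h", term = "Told"),
                            new = data.frame(gene = "g", term = "T1"))
  preds <- data.frame(gene = c("g", "g"), term = c("T1", "T2"),
                      p = c(0.01, 0.01))
  pc <- precision_recall_curve(preds, split)
  expect_equal(pc$points$precision, 0.5)  # (g,T1) in all; (g,T2) not
  expect_equal(pc$points$recall, 1.0)     # the one new annotation found
  # alternative denominator: recall against predicted
  pc2 <- precision_recall_curve(preds, split,
                                recall_denominator = "predicted")
  expect_equal(pc2$points$recall, 0.5)
})

test_that("recall is monotone in the p cutoff", {
  set.seed(71)
  genes <- sprintf("g%d", 1:30)
  preds <- data.frame(gene = sample(genes, 100, TRUE),
                      term = sample(c("A", "B", "C"), 100, TRUE),
                      p = runif(100))
  preds <- preds[!duplicated(preds[, 1:2]), ]
  new <- preds[sample(nrow(preds), 10), c("gene", "term")]
  old <- data.frame(gene = "zz", term = "A")
  split <- annotation_split(old, new)
  pc <- precision_recall_curve(preds, split)
  pts <- pc$points[order(pc$points$cutoff), ]
  expect_true(all(diff(pts$recall) >= 0))
})

test_that("annotation_split rejects overlap between old and new", {
  df <- data.frame(gene = "g", term = "T")
  expect_error(annotation_split(df, df), "overlap")
})

test_that("the true modular network beats its rewired copy at GBA", {
  wins <- 0
  reps <- 5
  for (s in 1:reps) {
    cfg <- small_fixture(seed = 700 + s)
    truth <- generate_true_interactome(cfg)
    ann <- generate_annotation_split(truth, cfg)
    pr_true <- gba_benchmark(truth$net, ann$split)
    rw <- degree_preserving_rewire(truth$net, seed = s)
    pr_rw <- gba_benchmark(rw, ann$split)
    if (pr_true$pr_auc > pr_rw$pr_auc) wins <- wins + 1
  }
  expect_gte(wins, reps - 1)
})
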