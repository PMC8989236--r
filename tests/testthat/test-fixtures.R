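test_that("fixture config validates its invariants", {
  expect_error(fixture_config(n_genes = 50, n_modules = 6,
                              module_size = 10), "exceeds")
  expect_error(fixture_config(p_in = 0.1, p_out = 0.2))
  expect_error(fixture_config(withheld_fraction = 1.5), "withheld")
})

test_that("true interactome is a seeded stochastic block model", {
  cfg <- small_fixture(seed = 81)
  t1 <- generate_true_interactome(cfg)
  t2 <- generate_true_interactome(cfg)
  expect_identical(t1$net$edges, t2$net$edges)
  # degenerate: p_in = 1, p_out = 0 -> disjoint cliques
  cfgc <- fixture_config(n_genes = 30, n_modules = 3, module_size = 10,
                         p_in = 1, p_out = 0, seed = 2)
  cl <- generate_true_interactome(cfgc)
  expect_equal(nrow(cl$net$edges), 3 * choose(10, 2))
  memb <- cl$membership
  expect_true(all(memb[cl$net$edges$from] == memb[cl$net$edges$to]))
})

test_that("within-module edge counts match the binomial expectation", {
  cfg <- small_fixture()
  n_within_pairs <- cfg$n_modules * choose(cfg$module_size, 2)
  counts <- vapply(1:25, function(s) {
    tr <- generate_true_interactome(small_fixture(seed = 900 + s))
    memb <- tr$membership
    sum(memb[tr$net$edges$from] == memb[tr$net$edges$to] &
          memb[tr$net$edges$from] > 0)
  }, 0)
  mu <- n_within_pairs * cfg$p_in
  sigma <- sqrt(n_within_pairs * cfg$p_in * (1 - cfg$p_in))
  expect_lt(abs(mean(counts) - mu), 3 * sigma / sqrt(25))
})

test_that("zero-effect categories carry no signal, planted ones do", {
  cfg <- small_fixture(seed = 82,
                       effects = list(coexpr = 0, phylo = 0.9,
                                      domain = 0, coloc = 0,
                                      interolog = 0, annot = 0))
  truth <- generate_true_interactome(cfg)
  bdl <- generate_evidence(truth, cfg)
  pos <- truth$net$edges[, c("from", "to")]
  neg <- sample_negatives(rownames(bdl$expression), pos, seed = 1,
                          n_negatives = 5 * nrow(pos))
  fm <- suppressMessages(build_feature_matrix(rbind(pos, neg), bdl))
  lb <- labeled_pairs(pos, neg)
  ev <- evaluate_features(fm, lb)
  expect_lt(abs(ev[["coexpr.pcc"]]$auc - 0.5), 0.08)
  expect_gt(ev[["phylo.pearson"]]$auc, 0.8)
})

test_that("interologs are planted as conserved foreign edges", {
  cfg <- small_fixture(seed = 83,
                       effects = list(interolog = 1, phylo = 0, domain = 0,
                                      coloc = 0, coexpr = 0, annot = 0))
  truth <- generate_true_interactome(cfg)
  bdl <- generate_evidence(truth, cfg)
  pos <- truth$net$edges[, c("from", "to")]
  fm <- suppressMessages(build_feature_matrix(pos, bdl))
  # with effect 1, every true edge whose endpoints have orthologs in a
  # species is conserved there; most edges should be supported somewhere
  expect_gt(mean(fm$interolog.n_species >= 1), 0.8)
})

test_that("observed-network sampling follows sens/spec", {
  genes <- sprintf("g%03d", 1:150)
  true_pairs <- sample_negatives(genes, canonical_pairs(character(0),
                                                        character(0)),
                                 seed = 84, n_negatives = 300)
  tn <- network(true_pairs, nodes = genes)
  # sens = spec = 1 reproduces the truth exactly
  obs1 <- generate_observed_network(tn, genes, 1, 1, seed = 1)
  expect_setequal(pair_key(obs1$edges), pair_key(tn$edges))
  # sens = 0.5: kept true edges within binomial bounds
  kept <- vapply(1:20, function(s) {
    o <- generate_observed_network(tn, genes, 0.5, 1, seed = s)
    sum(pair_key(o$edges) %in% pair_key(tn$edges))
  }, 0)
  expect_lt(abs(mean(kept) - 150), 3 * sqrt(300 * 0.25) / sqrt(20))
  # false positives are non-edges
  obs2 <- generate_observed_network(tn, genes, 0.5, 0.99, seed = 3)
  fp <- setdiff(pair_key(obs2$edges), pair_key(tn$edges))
  expect_gt(length(fp), 0)
  expect_false(any(fp %in% pair_key(tn$edges)))
})

test_that("annotation split withholds the configured fraction", {
  cfg <- small_fixture(seed = 85, annot_noise = 0)
  truth <- generate_true_interactome(cfg)
  ann <- generate_annotation_split(truth, cfg)
  n_old <- nrow(ann$split$old)
  n_new <- nrow(ann$split$new)
  n_pairs <- cfg$n_modules * cfg$module_size
  expect_equal(n_new, floor(cfg$withheld_fraction * n_pairs))
  expect_equal(n_old + n_new, n_pairs)
  # with zero noise, term membership equals module membership
  for (m in names(truth$modules)) {
    got <- sort(ann$split$all$gene[ann$split$all$term == m])
    expect_equal(got, sort(truth$modules[[m]]))
  }
  expect_equal(sort(ann$collection$sets$set_id), sort(names(truth$modules)))
})

test_that("evidence bundles survive a round trip through a directory", {
  cfg <- small_fixture(seed = 86)
  truth <- generate_true_interactome(cfg)
  bdl <- generate_evidence(truth, cfg)
  d <- withr::local_tempdir()
  write_evidence_dir(bdl, d)
  back <- read_evidence_dir(d)
  pairs <- truth$net$edges[1:10, c("from", "to")]
  fm1 <- suppressMessages(build_feature_matrix(pairs, bdl))
  fm2 <- suppressMessages(build_feature_matrix(pairs, back))
  expect_equal(as.data.frame(fm1), as.data.frame(fm2), tolerance = 1e-9)
})
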