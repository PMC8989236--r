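bundle <- tiny_bundle()

test_that("interolog feature counts supporting species", {
  # g1-g2: conserved in human (h1-h2) and rat (r1-r2) -> 2
  expect_equal(interolog_feature(c("g1", "g2"), bundle), 2L)
  # g2-g3: only rat (r2-r3) -> 1; g1-g3: none -> 0
  expect_equal(interolog_feature(c("g2", "g3"), bundle), 1L)
  expect_equal(interolog_feature(c("g1", "g3"), bundle), 0L)
})

test_that("phylogenetic profile features match their definitions", {
  f <- phylo_profile_features(c("g1", "g2"), bundle$phylo)
  expect_equal(f[["jaccard"]], 2 / 3)  # {s1,s2,s4} vs {s1,s4}
  ident <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0))
  fi <- phylo_profile_features(c("a", "b"), ident)
  expect_equal(fi[["pearson"]], 1.0)
  expect_equal(fi[["mi"]], 1.0)  # two balanced identical profiles: 1 bit
  const <- rbind(a = c(1, 1, 1, 1), b = c(1, 0, 1, 0))
  expect_true(is.na(phylo_profile_features(c("a", "b"), const)[["pearson"]]))
})

test_that("mutual information equals the brute-force 2x2 oracle", {
  set.seed(9)
  for (i in 1:25) {
    x <- rbinom(8, 1, 0.5)
    y <- rbinom(8, 1, 0.5)
    f <- phylo_profile_features(c("a", "b"), rbind(a = x, b = y))
    expect_equal(f[["mi"]], brute_mi(x, y), tolerance = 1e-12)
  }
})

test_that("domain features enumerate the scored cross pairs", {
  # D(g1)={d1,d2}, D(g2)={d3}; scored (d1,d3)=0.9 -> (1, .9, .9, 1/2)
  f <- domain_features(c("g1", "g2"), bundle)
  expect_equal(unname(f), c(1, 0.9, 0.9, 0.5))
  # two scored pairs among 4 cross pairs
  b2 <- evidence_bundle(
    domains = data.frame(gene = c("x", "x", "y", "y"),
                         domain = c("d1", "d2", "d3", "d4")),
    domain_scores = data.frame(domain_a = c("d1", "d2"),
                               domain_b = c("d3", "d4"),
                               score = c(0.5, 0.7)))
  expect_equal(unname(domain_features(c("x", "y"), b2)), c(2, 0.7, 1.2, 0.5))
  # empty domain set -> all zero
  expect_equal(unname(domain_features(c("g1", "nodomains"), bundle)),
               c(0, 0, 0, 0))
})

test_that("colocalization features follow the shared-compartment rules", {
  # C(g1)={nuc .9, cyt .4}, C(g2)={nuc .8} -> (1, 1/2, .8, 1)
  f <- colocalization_features(c("g1", "g2"), bundle)
  expect_equal(unname(f), c(1, 0.5, 0.8, 1))
  expect_equal(unname(colocalization_features(c("g1", "g3"), bundle)),
               c(0, 0, 0, 0))
  b2 <- evidence_bundle(compartments = data.frame(
    gene = c("x", "y"), compartment = c("nuc", "nuc"),
    confidence = c(1, 1)))
  expect_equal(unname(colocalization_features(c("x", "y"), b2)),
               c(1, 1, 1, 1))
})

test_that("coexpression features: correlation sign and mutual rank", {
  em <- rbind(x = c(1, 2, 3), y = c(2, 4, 6), z = c(6, 4, 2))
  expect_equal(coexpression_features(c("x", "y"), em)[["pcc"]], 1.0)
  expect_equal(coexpression_features(c("x", "z"), em)[["pcc"]], -1.0)
  # with 3 genes each gene's partner list has 2 entries; |r| = 1 everywhere,
  # so ranks fall back to the lexical tie-break
  f <- coexpression_features(c("x", "y"), em)
  expect_true(f[["mutual_rank"]] >= 1)
  cm <- rbind(x = c(1, 1, 1), y = c(1, 2, 3))
  expect_true(all(is.na(coexpression_features(c("x", "y"), cm))))
})

test_that("annotation features use -log2 information content", {
  # shared terms of g1,g2: {T1 freq .01} -> max_ic = -log2(.01)
  f <- annotation_features(c("g1", "g2"), bundle)
  expect_equal(f[["n_shared"]], 1)
  expect_equal(f[["jaccard"]], 0.5)  # {T1} / {T1,T2}
  expect_equal(f[["max_ic"]], -log2(0.01), tolerance = 1e-6)
  expect_equal(unname(annotation_features(c("g2", "g3"), bundle)), c(0, 0, 0))
  bad <- bundle
  bad$term_freq <- c(T1 = 0.01)  # T2 missing
  expect_error(annotation_features(c("g1", "g1x"), bad), NA)
})

test_that("feature matrix agrees with the per-pair reference path", {
  pairs <- canonical_pairs(c("g1", "g1", "g2"), c("g2", "g3", "g3"))
  fm <- build_feature_matrix(pairs, bundle)
  for (i in seq_len(nrow(pairs))) {
    p <- c(pairs$from[i], pairs$to[i])
    expect_equal(fm$interolog.n_species[i], as.numeric(interolog_feature(p, bundle)))
    expect_equal(unname(unlist(fm[i, c("phylo.jaccard", "phylo.pearson", "phylo.mi")])),
                 unname(phylo_profile_features(p, bundle$phylo)),
                 tolerance = 1e-10)
    expect_equal(unname(unlist(fm[i, c("domain.n_scored", "domain.max_score",
                                       "domain.sum_score", "domain.density")])),
                 unname(domain_features(p, bundle)), tolerance = 1e-10)
    expect_equal(unname(unlist(fm[i, c("coloc.n_shared", "coloc.jaccard",
                                       "coloc.max_conf", "coloc.any")])),
                 unname(colocalization_features(p, bundle)), tolerance = 1e-10)
    expect_equal(unname(unlist(fm[i, c("coexpr.pcc", "coexpr.mutual_rank")])),
                 unname(coexpression_features(p, bundle$expression)),
                 tolerance = 1e-10)
    expect_equal(unname(unlist(fm[i, c("annot.n_shared", "annot.jaccard",
                                       "annot.max_ic")])),
                 unname(annotation_features(p, bundle)), tolerance = 1e-10)
  }
})

test_that("feature matrix path matches per-pair path on generated data", {
  cfg <- small_fixture(seed = 21)
  truth <- generate_true_interactome(cfg)
  bdl <- generate_evidence(truth, cfg)
  genes <- rownames(bdl$expression)
  set.seed(3)
  pairs <- canonical_pairs(sample(genes, 12), sample(genes, 12))
  pairs <- pairs[pairs$from != pairs$to, ]
  fm <- suppressMessages(build_feature_matrix(pairs, bdl))
  for (i in seq_len(nrow(pairs))) {
    p <- c(pairs$from[i], pairs$to[i])
    expect_equal(unname(unlist(fm[i, c("domain.n_scored", "domain.max_score",
                                       "domain.sum_score", "domain.density")])),
                 unname(domain_features(p, bdl)), tolerance = 1e-10)
    expect_equal(unname(unlist(fm[i, c("coexpr.pcc", "coexpr.mutual_rank")])),
                 unname(coexpression_features(p, bdl$expression)),
                 tolerance = 1e-10)
    expect_equal(unname(unlist(fm[i, c("phylo.jaccard", "phylo.pearson",
                                       "phylo.mi")])),
                 unname(phylo_profile_features(p, bdl$phylo)),
                 tolerance = 1e-10)
  }
})

test_that("all features are symmetric in the pair", {
  cfg <- small_fixture(seed = 22)
  truth <- generate_true_interactome(cfg)
  bdl <- generate_evidence(truth, cfg)
  genes <- rownames(bdl$expression)
  set.seed(4)
  a <- sample(genes, 10)
  b <- sample(setdiff(genes, a), 10)
  fwd <- suppressMessages(build_feature_matrix(canonical_pairs(a, b), bdl))
  rev <- suppressMessages(build_feature_matrix(canonical_pairs(b, a), bdl))
  expect_equal(fwd[feature_names()], rev[feature_names()])
  # bounded ranges
  stacked <- fwd[feature_names()]
  expect_true(all(stacked$phylo.jaccard >= 0 & stacked$phylo.jaccard <= 1,
                  na.rm = TRUE))
  expect_true(all(abs(stacked$coexpr.pcc) <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(stacked$coexpr.mutual_rank >= 1, na.rm = TRUE))
  expect_true(all(stacked$domain.density >= 0 & stacked$domain.density <= 1))
})

test_that("missingness is category-local and orphan rows go all-NA", {
  b <- tiny_bundle()
  b$expression <- b$expression[c("g1", "g2"), ]  # g3 loses expression only
  fm <- build_feature_matrix(canonical_pairs(c("g1", "g1"), c("g2", "g3")), b)
  r3 <- fm[fm$to == "g3", ]
  expect_true(is.na(r3$coexpr.pcc) && is.na(r3$coexpr.mutual_rank))
  expect_false(is.na(r3$domain.n_scored))
  # a gene in no source at all -> whole row NA, with a message
  expect_message(
    fm2 <- build_feature_matrix(canonical_pairs("g1", "ghost"), b),
    "absent from every")
  expect_true(all(is.na(fm2[1, feature_names()])))
  # empty pair list -> empty matrix with full header
  fm0 <- build_feature_matrix(canonical_pairs(character(0), character(0)), b)
  expect_equal(nrow(fm0), 0)
  expect_true(all(feature_names() %in% names(fm0)))
})

test_that("feature matrices round-trip through TSV", {
  fm <- build_feature_matrix(canonical_pairs("g1", "g2"), tiny_bundle())
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, tf)
  back <- read_feature_matrix(tf)
  expect_equal(as.data.frame(back), as.data.frame(fm), tolerance = 1e-9)
})
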