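test_that("inter-set density enumerates cross pairs correctly", {
  net <- network(data.frame(from = c("g1", "a1", "a2"),
                            to = c("g2", "b1", "b3")),
                 nodes = c("g1", "g2", "a1", "a2", "b1", "b2", "b3"))
  expect_equal(interset_density("g1", "g2", net), 1.0)
  expect_equal(interset_density(c("a1", "a2"), c("b1", "b2", "b3"), net),
               2 / 6)
  expect_equal(interset_density("b2", "g1", net), 0.0)
  # symmetry
  expect_equal(interset_density(c("a1", "a2"), c("b1", "b2", "b3"), net),
               interset_density(c("b1", "b2", "b3"), c("a1", "a2"), net))
})

test_that("overlapping sets count each unordered cross pair once", {
  # A = B = {x, y, z}: cross pairs are the 3 unordered pairs
  net <- network(data.frame(from = c("x", "x"), to = c("y", "z")))
  expect_equal(interset_density(c("x", "y", "z"), c("x", "y", "z"), net),
               2 / 3)
})

test_that("density drops genes absent from the network, errors when all", {
  net <- network(data.frame(from = "a", to = "b"))
  expect_message(d <- interset_density(c("a", "zz"), "b", net), "dropped")
  expect_equal(d, 1.0)
  expect_error(suppressMessages(interset_density("q1", "q2", net)),
               "empty after restriction")
})

test_that("q1 applies the fixed density cutoff and an empirical background", {
  net <- random_net(60, 0.05, seed = 61)
  # plant a dense bipartite pair
  a <- net$nodes[1:8]
  b <- net$nodes[9:16]
  extra <- expand.grid(from = a, to = b, stringsAsFactors = FALSE)
  dense <- suppressWarnings(network(rbind(net$edges[, 1:2], extra),
                                    nodes = net$nodes))
  q <- q1_test(a, b, dense, n_background = 99, seed = 1)
  expect_true(q$pass)
  expect_equal(q$empirical_p, 1 / 100)  # observed beats every draw
  q2 <- q1_test(net$nodes[17:20], net$nodes[21:24], net,
                density_cutoff = 0.5, n_background = 49, seed = 1)
  expect_false(q2$pass)
})

test_that("rewiring preserves degree sequences exactly and stays simple", {
  skip_if_not_installed("igraph")
  for (s in 1:20) {
    net <- random_net(sample(20:60, 1), runif(1, 0.05, 0.2), seed = 600 + s)
    rw <- degree_preserving_rewire(net, seed = s)
    expect_identical(network_degree(rw), network_degree(net))
    expect_equal(nrow(rw$edges), nrow(net$edges))
    expect_true(all(rw$edges$from != rw$edges$to))
    expect_false(anyDuplicated(pair_key(rw$edges)) > 0)
    # independent degree oracle
    g <- igraph::graph_from_data_frame(rw$edges[, 1:2], directed = FALSE,
                                       vertices = rw$nodes)
    expect_identical(as.integer(igraph::degree(g)[net$nodes]),
                     unname(network_degree(net)))
  }
})

test_that("rewiring a triangle returns it unchanged", {
  tri <- network(data.frame(from = c("a", "b", "c"), to = c("b", "c", "a")))
  rw <- degree_preserving_rewire(tri, n_swaps = 500, seed = 7)
  expect_setequal(pair_key(rw$edges), pair_key(tri$edges))
})

test_that("rewiring actually moves edges on non-rigid graphs", {
  net <- random_net(50, 0.1, seed = 63)
  rw <- degree_preserving_rewire(net, seed = 1)
  expect_gt(mean(!(pair_key(rw$edges) %in% pair_key(net$edges))), 0.3)
  # reproducible under seed
  rw2 <- degree_preserving_rewire(net, seed = 1)
  expect_identical(rw$edges, rw2$edges)
})

test_that("q2 p-value hits the pseudocount floor for planted structure", {
  net <- random_net(60, 0.03, seed = 64)
  a <- net$nodes[1:8]
  b <- net$nodes[9:16]
  extra <- expand.grid(from = a, to = b, stringsAsFactors = FALSE)
  dense <- suppressWarnings(network(rbind(net$edges[, 1:2], extra),
                                    nodes = net$nodes))
  p <- suppressWarnings(q2_test(a, b, dense, n_null = 99, seed = 2))
  expect_equal(p, 1 / 100)
})

test_that("q2 warns when the null count cannot reach the cutoff", {
  net <- random_net(30, 0.1, seed = 65)
  expect_warning(q2_test(net$nodes[1:4], net$nodes[5:8], net, n_null = 50,
                         seed = 1, p_cutoff = 0.001),
                 "cannot reach")
})

test_that("run_gsla flags the planted module and is byte-deterministic", {
  cfg <- small_fixture(seed = 66)
  truth <- generate_true_interactome(cfg)
  ann <- generate_annotation_split(truth, cfg)
  set.seed(1)
  gde <- sample(truth$modules[["M2"]], 12)
  res <- suppressWarnings(
    run_gsla(gde, ann$collection, truth$net, n_null = 199,
             n_background = 199, p_cutoff = 0.01, seed = 5))
  expect_s3_class(res, "gsla_result")
  expect_equal(res$set_id[1], "M2")
  expect_true(res$reported[1])
  expect_false(any(res$reported[-1]))
  # contributing edges cross the query and the reported set
  ce <- attr(res, "contributing_edges")[["M2"]]
  expect_true(all(ce$from %in% c(gde, truth$modules[["M2"]]) &
                    ce$to %in% c(gde, truth$modules[["M2"]])))
  # identical query + seed -> byte-identical report
  res2 <- suppressWarnings(
    run_gsla(gde, ann$collection, truth$net, n_null = 199,
             n_background = 199, p_cutoff = 0.01, seed = 5))
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_gsla_report(res, f1)
  write_gsla_report(res2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("run_gsla warns on small queries and errors on unmapped ones", {
  cfg <- small_fixture(seed = 67)
  truth <- generate_true_interactome(cfg)
  ann <- generate_annotation_split(truth, cfg)
  gde <- truth$modules[["M1"]][1:5]
  expect_warning(run_gsla(gde, ann$collection, truth$net, n_null = 99,
                          n_background = 49, p_cutoff = 0.05, seed = 1),
                 "50-200")
  expect_error(suppressWarnings(
    run_gsla(c("nope1", "nope2"), ann$collection, truth$net, n_null = 99,
             seed = 1)),
    "no query gene")
})
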