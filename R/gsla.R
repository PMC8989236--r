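# Gene set linkage analysis (GSLA): the inter-set association density
# statistic and its two significance tests. Q1 asks whether the density
# between the query gene set and a biological-process gene set exceeds a
# background level (fixed cutoff, plus an empirical comparison against
# random gene sets of the same sizes). Q2 asks whether the density can only
# be observed in the biologically correct network, by comparing against
# degree-preserving randomizations of the network (double edge swaps), which
# controls for gene-set composition effects such as hubs.

restrict_to_network <- function(set, net, label = "set") {
  set <- unique(as.character(set))
  keep <- set[set %in% net$nodes]
  nd <- length(set) - length(keep)
  if (nd > 0) message(nd, " gene(s) in ", label, " absent from the network; dropped")
  keep
}

# number of unordered cross pairs {a, b}, a in A, b in B, a != b, counted
# once; overlap-aware
n_cross_pairs <- function(a, b) {
  ov <- length(intersect(a, b))
  length(a) * length(b) - ov - ov * (ov - 1) / 2
}

cross_edge_count <- function(a, b, net) {
  inA <- net$edges$from %in% a
  inB <- net$edges$to %in% b
  inA2 <- net$edges$to %in% a
  inB2 <- net$edges$from %in% b
  sum((inA & inB) | (inA2 & inB2))
}

#' Inter-set association density
#'
#' The number of network edges crossing two gene sets divided by the number
#' of possible unordered cross pairs (self-pairs excluded; overlapping
#' members counted once). Genes absent from the network are dropped with a
#' reported count.
#'
#' @param set_a,set_b character vectors of gene IDs.
#' @param net an `fa_network`.
#' @return density in \[0, 1\]; 0 when no cross pair exists.
#' @export
interset_density <- function(set_a, set_b, net) {
  a <- restrict_to_network(set_a, net, "set_a")
  b <- restrict_to_network(set_b, net, "set_b")
  if (length(a) == 0 && length(b) == 0) {
    stop("both sets empty after restriction to the network")
  }
  denom <- n_cross_pairs(a, b)
  if (denom == 0) return(0)
  cross_edge_count(a, b, net) / denom
}

# densities between random node sets of the same sizes (background draws)
background_densities <- function(size_a, size_b, net, n_draws) {
  u <- net$edges$from
  v <- net$edges$to
  vapply(seq_len(n_draws), function(i) {
    a <- sample(net$nodes, size_a)
    b <- sample(net$nodes, size_b)
    denom <- n_cross_pairs(a, b)
    if (denom == 0) return(0)
    sum((u %in% a & v %in% b) | (u %in% b & v %in% a)) / denom
  }, 0)
}

#' Q1 test: density against background
#'
#' Passes when the observed inter-set density exceeds the fixed cutoff.
#' Also reports an add-one empirical p-value against densities between
#' uniformly random node sets of the same sizes.
#'
#' @param set_a,set_b character vectors of gene IDs.
#' @param net an `fa_network`.
#' @param density_cutoff fixed density cutoff (default 0.01).
#' @param n_background number of random-set background draws (default 1000).
#' @param seed optional RNG seed.
#' @return list with `density`, `pass` and `empirical_p`.
#' @export
q1_test <- function(set_a, set_b, net, density_cutoff = 0.01,
                    n_background = 1000, seed = NULL) {
  a <- restrict_to_network(set_a, net, "set_a")
  b <- restrict_to_network(set_b, net, "set_b")
  if (length(a) > length(net$nodes) || length(b) > length(net$nodes)) {
    stop("set larger than the network")
  }
  d <- suppressMessages(interset_density(a, b, net))
  if (!is.null(seed)) set.seed(seed)
  bg <- background_densities(length(a), length(b), net, n_background)
  list(density = d, pass = d > density_cutoff,
       empirical_p = (1 + sum(bg >= d)) / (1 + n_background))
}

#' Degree-preserving network randomization
#'
#' Randomizes the edges by repeated double edge swaps; every node keeps its
#' exact degree, the graph stays simple, and the edge count is preserved.
#' When no valid swap exists (e.g. a triangle) the network is returned
#' unchanged after the attempted swaps.
#'
#' @param net an `fa_network`.
#' @param n_swaps number of attempted swaps (default `10 * n_edges`).
#' @param seed optional RNG seed.
#' @return a rewired `fa_network` over the same nodes (edge scores are not
#'   carried over).
#' @export
degree_preserving_rewire <- function(net, n_swaps = NULL, seed = NULL) {
  stopifnot(inherits(net, "fa_network"))
  m <- nrow(net$edges)
  if (is.null(n_swaps)) n_swaps <- 10L * m
  if (!is.null(seed)) set.seed(seed)
  if (m == 0) return(net)
  fi <- match(net$edges$from, net$nodes)
  ti <- match(net$edges$to, net$nodes)
  rw <- cpp_rewire(fi, ti, length(net$nodes), as.integer(n_swaps))
  network(data.frame(from = net$nodes[rw[, 1]], to = net$nodes[rw[, 2]],
                     stringsAsFactors = FALSE),
          nodes = net$nodes)
}

#' Q2 test: density against a degree-preserving null
#'
#' Add-one permutation p-value of the observed inter-set density against
#' the densities observed in independently rewired copies of the network
#' (each null preserves every node's degree).
#'
#' @param set_a,set_b character vectors of gene IDs.
#' @param net an `fa_network`.
#' @param n_null number of null networks (default 1000). A warning is
#'   emitted when the add-one p-value floor `1/(n_null+1)` cannot reach
#'   `p_cutoff`.
#' @param n_swaps attempted swaps per null (default `10 * n_edges`).
#' @param seed optional RNG seed.
#' @param p_cutoff intended reporting cutoff, used only for the floor
#'   warning (default 0.001).
#' @return the permutation p-value in (0, 1\].
#' @export
q2_test <- function(set_a, set_b, net, n_null = 1000, n_swaps = NULL,
                    seed = NULL, p_cutoff = 0.001) {
  if (n_null < 1 / p_cutoff - 1) {
    warning("n_null = ", n_null, " cannot reach p_cutoff = ", p_cutoff,
            " (p floor is ", signif(1 / (n_null + 1), 3), ")")
  }
  a <- restrict_to_network(set_a, net, "set_a")
  b <- restrict_to_network(set_b, net, "set_b")
  obs <- suppressMessages(interset_density(a, b, net))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_swaps)) n_swaps <- 10L * nrow(net$edges)
  ai <- match(a, net$nodes)
  bi <- match(b, net$nodes)
  fi <- match(net$edges$from, net$nodes)
  ti <- match(net$edges$to, net$nodes)
  cnt <- cpp_null_cross_counts(fi, ti, length(net$nodes),
                               list(ai, bi),
                               matrix(c(1L, 2L), 1), as.integer(n_null),
                               as.integer(n_swaps))
  denom <- n_cross_pairs(a, b)
  nulls <- if (denom == 0) rep(0, n_null) else cnt[1, ] / denom
  (1 + sum(nulls >= obs)) / (1 + n_null)
}

#' Run gene set linkage analysis
#'
#' Scores every gene set in the collection against the query gene list
#' (e.g. differentially expressed genes): inter-set density, the Q1 fixed
#' cutoff and empirical background test, and the Q2 degree-preserving
#' permutation test. The null network ensemble is generated once per query
#' and reused across all gene sets (the null concerns the network, not the
#' set). A set is reported when `density > density_cutoff` and
#' `q2_p < p_cutoff`.
#'
#' @param gde character vector of query gene IDs (differentially expressed
#'   genes). A warning suggests 50-200 genes for focused annotations.
#' @param collection a `gene_set_collection` of biological-process sets.
#' @param net an `fa_network` (the reference association network).
#' @param density_cutoff Q1 density cutoff (default 0.01).
#' @param p_cutoff Q2 p-value cutoff (default 0.001).
#' @param n_null number of degree-preserving null networks (default 1000).
#' @param n_background number of random-set draws for the Q1 empirical
#'   p-value (default 1000).
#' @param seed RNG seed; identical query + seed gives a byte-identical
#'   report.
#' @return data.frame of class `gsla_result`, one row per gene set, sorted
#'   by `q2_p` then decreasing density; attribute `contributing_edges`
#'   holds, for each reported set, the cross edges between the query and
#'   the set; attribute `params` records the query parameters.
#' @export
run_gsla <- function(gde, collection, net, density_cutoff = 0.01,
                     p_cutoff = 0.001, n_null = 1000, n_background = 1000,
                     seed = 1) {
  stopifnot(inherits(collection, "gene_set_collection"),
            inherits(net, "fa_network"))
  stopifnot(density_cutoff > 0, density_cutoff < 1, p_cutoff > 0,
            p_cutoff < 1)
  if (n_null < 1 / p_cutoff - 1) {
    warning("n_null = ", n_null, " cannot reach p_cutoff = ", p_cutoff,
            " (p floor is ", signif(1 / (n_null + 1), 3), ")")
  }
  gde <- unique(as.character(gde))
  if (length(gde) == 0) stop("empty query gene list")
  gde_net <- gde[gde %in% net$nodes]
  if (length(gde_net) == 0) {
    stop("no query gene maps into the network; unmapped: ",
         paste(utils::head(gde, 10), collapse = ", "))
  }
  nd <- length(gde) - length(gde_net)
  if (nd > 0) message(nd, " query gene(s) absent from the network; dropped")
  if (length(gde) < 50 || length(gde) > 200) {
    warning("query has ", length(gde),
            " genes; 50-200 genes are suggested for focused annotations")
  }
  set.seed(seed)
  k <- nrow(collection$sets)
  members_net <- lapply(collection$members, function(m) m[m %in% net$nodes])
  density <- numeric(k)
  q1_p <- numeric(k)
  for (i in seq_len(k)) {
    b <- members_net[[i]]
    denom <- n_cross_pairs(gde_net, b)
    density[i] <- if (denom == 0) 0 else
      cross_edge_count(gde_net, b, net) / denom
    bg <- background_densities(length(gde_net), length(b), net, n_background)
    q1_p[i] <- (1 + sum(bg >= density[i])) / (1 + n_background)
  }
  # one null ensemble per query, shared across all sets
  fi <- match(net$edges$from, net$nodes)
  ti <- match(net$edges$to, net$nodes)
  sets_idx <- c(list(match(gde_net, net$nodes)),
                lapply(members_net, function(m) match(m, net$nodes)))
  set_pairs <- cbind(1L, seq_len(k) + 1L)
  cnt <- cpp_null_cross_counts(fi, ti, length(net$nodes), sets_idx,
                               set_pairs, as.integer(n_null),
                               as.integer(10L * nrow(net$edges)))
  q2_p <- vapply(seq_len(k), function(i) {
    denom <- n_cross_pairs(gde_net, members_net[[i]])
    nulls <- if (denom == 0) rep(0, n_null) else cnt[i, ] / denom
    (1 + sum(nulls >= density[i])) / (1 + n_null)
  }, 0)
  res <- data.frame(set_id = collection$sets$set_id,
                    name = collection$sets$name,
                    n_members = lengths(collection$members),
                    n_in_network = lengths(members_net),
                    density = density,
                    q1_pass = density > density_cutoff,
                    q1_empirical_p = q1_p,
                    q2_p = q2_p,
                    reported = density > density_cutoff & q2_p < p_cutoff,
                    stringsAsFactors = FALSE)
  ord <- order(res$q2_p, -res$density)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  contributing <- lapply(seq_len(nrow(res)), function(i) {
    if (!res$reported[i]) return(NULL)
    b <- members_net[[res$set_id[i]]]
    e <- net$edges
    keep <- (e$from %in% gde_net & e$to %in% b) |
      (e$from %in% b & e$to %in% gde_net)
    e[keep, c("from", "to"), drop = FALSE]
  })
  names(contributing) <- res$set_id
  attr(res, "contributing_edges") <- contributing
  attr(res, "params") <- list(n_gde = length(gde),
                              n_gde_in_network = length(gde_net),
                              density_cutoff = density_cutoff,
                              p_cutoff = p_cutoff, n_null = n_null,
                              n_background = n_background, seed = seed)
  class(res) <- c("gsla_result", "data.frame")
  res
}

#' Write a GSLA report as TSV
#'
#' Leading `#` comment lines record the analysis parameters; then one row
#' per gene set; then the contributing cross edges of each reported set.
#'
#' @param res a `gsla_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gsla_report <- function(res, path) {
  p <- attr(res, "params")
  hdr <- c(sprintf("# gsla report"),
           sprintf("# n_gde\t%d", p$n_gde),
           sprintf("# n_gde_in_network\t%d", p$n_gde_in_network),
           sprintf("# density_cutoff\t%g", p$density_cutoff),
           sprintf("# p_cutoff\t%g", p$p_cutoff),
           sprintf("# n_null\t%d", p$n_null),
           sprintf("# n_background\t%d", p$n_background),
           sprintf("# seed\t%d", as.integer(p$seed)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- as.data.frame(res)
  writeLines(paste(names(df), collapse = "\t"), con)
  body <- apply(df, 1, function(r) paste(r, collapse = "\t"))
  if (length(body)) writeLines(body, con)
  ce <- attr(res, "contributing_edges")
  for (sid in names(ce)) {
    if (is.null(ce[[sid]]) || nrow(ce[[sid]]) == 0) next
    writeLines(sprintf("# contributing_edges\t%s", sid), con)
    writeLines(paste(ce[[sid]]$from, ce[[sid]]$to, sep = "\t"), con)
  }
  invisible(path)
}
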