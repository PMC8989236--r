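# Synthetic fixture generators: a modular (stochastic-block) true
# interactome, evidence with planted per-category signal, curated
# interaction records with publication metadata, an accuracy-degraded
# observed network, and a temporal annotation split. Every generator is a
# pure function of (config, seed), so the whole pipeline can be built and
# validated without external downloads.

#' Fixture configuration
#'
#' Defaults describe the standard desk-scale fixture: 300 genes, 6 modules
#' of 20 with within-module edge probability 0.3 against a 0.005
#' background, small enough for exhaustive all-pairs scoring. Effect sizes
#' are per evidence category in \[0, 1\]: 0 means the category carries no
#' signal (its features should screen out at AUC 0.5), 1 means maximal
#' planted association.
#'
#' @param n_genes total genes.
#' @param n_modules,module_size functional modules (must fit in `n_genes`).
#' @param p_in,p_out within-module / background edge probabilities
#'   (`p_in > p_out`).
#' @param effects named list of per-category effect sizes: `interolog`,
#'   `phylo`, `domain`, `coloc`, `coexpr`, `annot`.
#' @param n_samples expression samples.
#' @param n_species_panel species in the phylogenetic-profile panel.
#' @param ortholog_species reference species for interologs.
#' @param report_prob probability a true edge has curated reports.
#' @param obs_sens,obs_spec sensitivity/specificity for observed-network
#'   sampling.
#' @param withheld_fraction fraction of annotation pairs withheld as "new".
#' @param annot_noise probability of a spurious module-term annotation.
#' @param seed RNG seed.
#' @return object of class `fixture_config`.
#' @export
fixture_config <- function(n_genes = 300, n_modules = 6, module_size = 20,
                           p_in = 0.3, p_out = 0.005,
                           effects = list(interolog = 0.5, phylo = 0.8,
                                          domain = 0.6, coloc = 0.7,
                                          coexpr = 0.7, annot = 0.6),
                           n_samples = 50, n_species_panel = 20,
                           ortholog_species = c("sp1", "sp2", "sp3"),
                           report_prob = 0.85,
                           obs_sens = 0.5, obs_spec = 0.999,
                           withheld_fraction = 0.2, annot_noise = 0.05,
                           seed = 1) {
  if (n_modules * module_size > n_genes) {
    stop("module_size * n_modules exceeds n_genes")
  }
  stopifnot(p_in > p_out, p_in <= 1, p_out >= 0,
            obs_sens > 0, obs_sens <= 1, obs_spec > 0, obs_spec <= 1)
  if (withheld_fraction <= 0 || withheld_fraction >= 1) {
    stop("withheld_fraction must be in (0, 1)")
  }
  defaults <- list(interolog = 0.5, phylo = 0.8, domain = 0.6, coloc = 0.7,
                   coexpr = 0.7, annot = 0.6)
  defaults[names(effects)] <- effects
  structure(list(n_genes = n_genes, n_modules = n_modules,
                 module_size = module_size, p_in = p_in, p_out = p_out,
                 effects = defaults, n_samples = n_samples,
                 n_species_panel = n_species_panel,
                 ortholog_species = ortholog_species,
                 report_prob = report_prob, obs_sens = obs_sens,
                 obs_spec = obs_spec,
                 withheld_fraction = withheld_fraction,
                 annot_noise = annot_noise, seed = seed),
            class = "fixture_config")
}

#' Gene IDs of a fixture universe
#'
#' @param config a `fixture_config`.
#' @return character vector of `n_genes` synthetic gene IDs.
#' @export
fixture_genes <- function(config) sprintf("G%04d", seq_len(config$n_genes))

#' Generate the true modular interactome
#'
#' Stochastic block structure: genes in the same module are connected with
#' probability `p_in`, all other pairs with `p_out`.
#'
#' @param config a `fixture_config`.
#' @return list with `net` (an `fa_network`), `modules` (named list
#'   module -> member genes) and `membership` (gene -> module id, 0 for
#'   background genes).
#' @export
generate_true_interactome <- function(config) {
  set.seed(config$seed)
  genes <- fixture_genes(config)
  membership <- rep(0L, config$n_genes)
  membership[seq_len(config$n_modules * config$module_size)] <-
    rep(seq_len(config$n_modules), each = config$module_size)
  cmb <- combn(config$n_genes, 2)
  same <- membership[cmb[1, ]] == membership[cmb[2, ]] &
    membership[cmb[1, ]] > 0
  p <- ifelse(same, config$p_in, config$p_out)
  keep <- runif(ncol(cmb)) < p
  net <- network(data.frame(from = genes[cmb[1, keep]],
                            to = genes[cmb[2, keep]],
                            stringsAsFactors = FALSE),
                 nodes = genes)
  modules <- split(genes[membership > 0], membership[membership > 0])
  names(modules) <- sprintf("M%d", seq_len(config$n_modules))
  list(net = net, modules = modules,
       membership = stats::setNames(membership, genes))
}

#' Generate an evidence bundle with planted signal
#'
#' Per category, true-association structure is planted with the configured
#' effect size: module-level latent expression factors (coexpression),
#' module base profiles with bit-flip noise (phylogenetic profiles),
#' interacting domain pairs assigned to the endpoints of true edges
#' (domains), module home compartments (colocalization), module annotation
#' terms (shared annotation), and conserved foreign edges between orthologs
#' of true-edge endpoints (interologs). Effect 0 reduces a category to pure
#' background noise.
#'
#' @param truth result of [generate_true_interactome()].
#' @param config a `fixture_config`.
#' @return an `evidence_bundle`.
#' @export
generate_evidence <- function(truth, config) {
  set.seed(config$seed + 1L)
  genes <- fixture_genes(config)
  ng <- config$n_genes
  memb <- truth$membership
  ef <- config$effects
  edges <- truth$net$edges

  # expression: module latent factors
  E <- matrix(rnorm(ng * config$n_samples), ng,
              dimnames = list(genes, sprintf("S%02d", seq_len(config$n_samples))))
  fac <- matrix(rnorm(config$n_modules * config$n_samples), config$n_modules)
  inmod <- memb > 0
  if (ef$coexpr > 0 && any(inmod)) {
    E[inmod, ] <- sqrt(ef$coexpr) * fac[memb[inmod], ] +
      sqrt(1 - ef$coexpr) * E[inmod, ]
  }

  # phylogenetic profiles: module base profile + bit flips
  P <- matrix(rbinom(ng * config$n_species_panel, 1, 0.5), ng,
              dimnames = list(genes,
                              sprintf("sp%02d", seq_len(config$n_species_panel))))
  base <- matrix(rbinom(config$n_modules * config$n_species_panel, 1, 0.5),
                 config$n_modules)
  flip_p <- (1 - ef$phylo) / 2
  for (g in which(inmod)) {
    flip <- rbinom(config$n_species_panel, 1, flip_p)
    P[g, ] <- abs(base[memb[g], ] - flip)
  }

  # domains: background domains + planted interacting pairs on true edges
  n_dom <- 100
  doms <- sprintf("D%03d", seq_len(n_dom))
  n_scored <- 150
  sp <- matrix(sample(n_dom, 2 * n_scored, replace = TRUE), ncol = 2)
  sp <- sp[sp[, 1] != sp[, 2], , drop = FALSE]
  dp <- canonical_pairs(doms[sp[, 1]], doms[sp[, 2]])
  dup <- duplicated(pair_key(dp))
  domain_scores <- data.frame(domain_a = dp$from[!dup], domain_b = dp$to[!dup],
                              score = round(runif(sum(!dup), 0.3, 1), 3),
                              stringsAsFactors = FALSE)
  ndper <- sample(1:2, ng, replace = TRUE)
  domains <- data.frame(gene = rep(genes, ndper),
                        domain = doms[sample(n_dom, sum(ndper),
                                             replace = TRUE)],
                        stringsAsFactors = FALSE)
  if (ef$domain > 0 && nrow(edges) > 0) {
    plant <- runif(nrow(edges)) < ef$domain
    if (any(plant)) {
      pick <- sample(nrow(domain_scores), sum(plant), replace = TRUE)
      domains <- rbind(domains,
                       data.frame(gene = edges$from[plant],
                                  domain = domain_scores$domain_a[pick],
                                  stringsAsFactors = FALSE),
                       data.frame(gene = edges$to[plant],
                                  domain = domain_scores$domain_b[pick],
                                  stringsAsFactors = FALSE))
    }
  }
  domains <- unique(domains)

  # compartments: module home compartment + one random compartment per gene
  n_comp <- 10
  comps <- sprintf("C%02d", seq_len(n_comp))
  compartments <- data.frame(gene = genes,
                             compartment = comps[sample(n_comp, ng,
                                                        replace = TRUE)],
                             confidence = round(runif(ng, 0.3, 0.9), 3),
                             stringsAsFactors = FALSE)
  if (ef$coloc > 0 && any(inmod)) {
    home <- comps[(seq_len(config$n_modules) - 1) %% n_comp + 1]
    ishome <- which(inmod & runif(ng) < ef$coloc)
    if (length(ishome)) {
      compartments <- rbind(compartments,
                            data.frame(gene = genes[ishome],
                                       compartment = home[memb[ishome]],
                                       confidence = round(runif(length(ishome),
                                                                0.6, 1), 3),
                                       stringsAsFactors = FALSE))
    }
  }
  compartments <- compartments[!duplicated(compartments[, 1:2]), ]

  # annotations: module terms + generic background terms
  n_terms <- 40
  terms <- sprintf("T%03d", seq_len(n_terms))
  ntper <- sample(1:3, ng, replace = TRUE)
  annotations <- data.frame(gene = rep(genes, ntper),
                            term = terms[sample(n_terms, sum(ntper),
                                                replace = TRUE)],
                            stringsAsFactors = FALSE)
  if (ef$annot > 0 && any(inmod)) {
    mterms <- sprintf("TM%02d%s", rep(seq_len(config$n_modules), each = 2),
                      rep(c("a", "b"), config$n_modules))
    for (m in seq_len(config$n_modules)) {
      members <- genes[memb == m]
      for (j in 1:2) {
        hit <- members[runif(length(members)) < ef$annot]
        if (length(hit)) {
          annotations <- rbind(annotations,
                               data.frame(gene = hit,
                                          term = mterms[2 * (m - 1) + j],
                                          stringsAsFactors = FALSE))
        }
      }
    }
  }
  annotations <- unique(annotations)
  tf <- table(annotations$term)
  term_freq <- stats::setNames(
    vapply(names(tf), function(t_)
      length(unique(annotations$gene[annotations$term == t_])) / ng, 0),
    names(tf))

  # orthologs and foreign interactions
  orth <- do.call(rbind, lapply(config$ortholog_species, function(s) {
    has <- runif(ng) < 0.8
    data.frame(species = s, mouse_gene = genes[has],
               foreign_gene = paste(s, genes[has], sep = "_"),
               stringsAsFactors = FALSE)
  }))
  fi <- NULL
  for (s in config$ortholog_species) {
    om <- stats::setNames(orth$foreign_gene[orth$species == s],
                          orth$mouse_gene[orth$species == s])
    planted <- NULL
    if (ef$interolog > 0 && nrow(edges) > 0) {
      keep <- runif(nrow(edges)) < ef$interolog &
        edges$from %in% names(om) & edges$to %in% names(om)
      if (any(keep)) {
        planted <- data.frame(species = s, gene_a = om[edges$from[keep]],
                              gene_b = om[edges$to[keep]],
                              stringsAsFactors = FALSE)
      }
    }
    # background foreign edges between random orthologs
    nn <- max(10, ng %/% 2)
    ga <- sample(om, nn, replace = TRUE)
    gb <- sample(om, nn, replace = TRUE)
    noise <- data.frame(species = s, gene_a = ga, gene_b = gb,
                        stringsAsFactors = FALSE)
    noise <- noise[noise$gene_a != noise$gene_b, , drop = FALSE]
    fi <- rbind(fi, planted, noise)
  }
  rownames(fi) <- NULL

  evidence_bundle(orthologs = orth, foreign_interactions = fi,
                  phylo = P, domains = domains,
                  domain_scores = domain_scores,
                  compartments = compartments, expression = E,
                  annotations = annotations, term_freq = term_freq)
}

#' Generate curated interaction records for the true edges
#'
#' A fraction of true edges is "reported": each reported edge gets one or
#' more publications with a year and a low-/high-throughput method class,
#' emulating curated interaction databases.
#'
#' @param truth result of [generate_true_interactome()].
#' @param config a `fixture_config`.
#' @param years candidate publication years.
#' @param lt_prob probability a publication is low-throughput.
#' @return an `interaction_records` data.frame.
#' @export
generate_interaction_records <- function(truth, config,
                                         years = 2014:2021, lt_prob = 0.5) {
  set.seed(config$seed + 2L)
  edges <- truth$net$edges
  rep_edge <- runif(nrow(edges)) < config$report_prob
  edges <- edges[rep_edge, , drop = FALSE]
  if (nrow(edges) == 0) stop("no reported edges; raise report_prob")
  npub <- 1 + rpois(nrow(edges), 1.2)
  idx <- rep(seq_len(nrow(edges)), npub)
  n <- length(idx)
  interaction_records(
    gene_a = edges$from[idx], gene_b = edges$to[idx],
    publication_id = sprintf("PUB%05d", seq_len(n)),
    method_class = ifelse(runif(n) < lt_prob, "low_throughput",
                          "high_throughput"),
    year = sample(years, n, replace = TRUE))
}

#' Sample an accuracy-degraded observed network
#'
#' Each true edge is included with probability `sens`; each non-edge of the
#' universe with probability `1 - spec`. The realized edge count feeds the
#' interactome-size estimator in recovery simulations.
#'
#' @param true_net an `fa_network` of true interactions.
#' @param universe character vector of gene IDs (candidate pairs are all
#'   unordered pairs of the universe).
#' @param sens,spec sampling sensitivity and specificity in (0, 1\].
#' @param seed RNG seed.
#' @return an `fa_network`.
#' @export
generate_observed_network <- function(true_net, universe, sens, spec,
                                      seed = 1) {
  stopifnot(sens > 0, sens <= 1, spec > 0, spec <= 1)
  set.seed(seed)
  universe <- sort(unique(as.character(universe)))
  n <- length(universe)
  npairs <- n * (n - 1) / 2
  true_keys <- pair_key(true_net$edges)
  kept <- true_net$edges[runif(nrow(true_net$edges)) < sens, , drop = FALSE]
  n_fp <- rbinom(1, npairs - length(true_keys), 1 - spec)
  fp <- NULL
  if (n_fp > 0) {
    chosen <- numeric(0)
    while (length(chosen) < n_fp) {
      k <- sample(npairs, min(npairs, n_fp - length(chosen) + 20))
      ij <- pair_from_index(k, n)
      cand <- canonical_pairs(universe[ij[, 1]], universe[ij[, 2]])
      ok <- !(pair_key(cand) %in% true_keys) & !(k %in% chosen) &
        !duplicated(k)
      chosen <- c(chosen, k[ok])
    }
    ij <- pair_from_index(chosen[seq_len(n_fp)], n)
    fp <- canonical_pairs(universe[ij[, 1]], universe[ij[, 2]])
  }
  ed <- rbind(kept[, c("from", "to")], fp)
  network(ed, nodes = universe)
}

#' Generate module gene sets and a temporal annotation split
#'
#' One term per module (members = module genes, plus a configurable rate of
#' spurious members); a configured fraction of the gene-term pairs is
#' withheld as "new" annotations, the rest as "old".
#'
#' @param truth result of [generate_true_interactome()].
#' @param config a `fixture_config`.
#' @return list with `collection` (a `gene_set_collection`) and `split`
#'   (an `annotation_split`).
#' @export
generate_annotation_split <- function(truth, config) {
  w <- config$withheld_fraction
  if (w <= 0 || w >= 1) stop("withheld_fraction must be in (0, 1)")
  set.seed(config$seed + 3L)
  genes <- fixture_genes(config)
  pairs <- do.call(rbind, lapply(names(truth$modules), function(m) {
    data.frame(gene = truth$modules[[m]], term = m, stringsAsFactors = FALSE)
  }))
  if (config$annot_noise > 0) {
    nn <- rbinom(1, length(genes) * length(truth$modules),
                 config$annot_noise)
    noise <- data.frame(gene = sample(genes, nn, replace = TRUE),
                        term = sample(names(truth$modules), nn,
                                      replace = TRUE),
                        stringsAsFactors = FALSE)
    pairs <- unique(rbind(pairs, noise))
  }
  n_new <- floor(w * nrow(pairs))
  new_idx <- sample(nrow(pairs), n_new)
  split <- annotation_split(old = pairs[-new_idx, , drop = FALSE],
                            new = pairs[new_idx, , drop = FALSE])
  collection <- gene_set_collection(
    set_id = names(truth$modules),
    name = sprintf("module %s", names(truth$modules)),
    members = truth$modules)
  list(collection = collection, split = split)
}
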