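# Shared in-code fixtures for the unit tests. Everything is generated at
# test time; nothing is read from disk except files the tests write
# themselves.

# a tiny hand-built evidence bundle with known feature values
tiny_bundle <- function() {
  orth <- data.frame(
    species = c("human", "human", "human", "rat", "rat", "rat"),
    mouse_gene = c("g1", "g2", "g3", "g1", "g2", "g3"),
    foreign_gene = c("h1", "h2", "h3", "r1", "r2", "r3"),
    stringsAsFactors = FALSE)
  fi <- data.frame(
    species = c("human", "rat", "rat"),
    gene_a = c("h1", "r1", "r2"),
    gene_b = c("h2", "r2", "r3"),
    stringsAsFactors = FALSE)
  phylo <- rbind(g1 = c(1, 1, 0, 1), g2 = c(1, 0, 0, 1),
                 g3 = c(0, 1, 1, 0))
  colnames(phylo) <- paste0("s", 1:4)
  domains <- data.frame(gene = c("g1", "g1", "g2", "g3"),
                        domain = c("d1", "d2", "d3", "d4"),
                        stringsAsFactors = FALSE)
  domain_scores <- data.frame(domain_a = c("d1", "d2"),
                              domain_b = c("d3", "d4"),
                              score = c(0.9, 0.7), stringsAsFactors = FALSE)
  compartments <- data.frame(
    gene = c("g1", "g1", "g2", "g3"),
    compartment = c("nuc", "cyt", "nuc", "mem"),
    confidence = c(0.9, 0.4, 0.8, 1.0), stringsAsFactors = FALSE)
  expression <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6.1, 8),
                      g3 = c(9, 2, 5, 1))
  colnames(expression) <- paste0("smp", 1:4)
  annotations <- data.frame(gene = c("g1", "g1", "g2", "g3"),
                            term = c("T1", "T2", "T1", "T3"),
                            stringsAsFactors = FALSE)
  term_freq <- c(T1 = 0.01, T2 = 0.5, T3 = 0.2)
  evidence_bundle(orthologs = orth, foreign_interactions = fi,
                  phylo = phylo, domains = domains,
                  domain_scores = domain_scores,
                  compartments = compartments, expression = expression,
                  annotations = annotations, term_freq = term_freq)
}

# small planted-module fixture shared by several tests
small_fixture <- function(seed = 11, ...) {
  fixture_config(n_genes = 80, n_modules = 4, module_size = 15,
                 p_in = 0.35, p_out = 0.006, seed = seed, ...)
}

# random simple graph as an fa_network
random_net <- function(n_nodes, p, seed) {
  set.seed(seed)
  genes <- sprintf("n%03d", seq_len(n_nodes))
  cmb <- combn(n_nodes, 2)
  keep <- runif(ncol(cmb)) < p
  network(data.frame(from = genes[cmb[1, keep]], to = genes[cmb[2, keep]],
                     stringsAsFactors = FALSE), nodes = genes)
}

# brute-force Mann-Whitney AUC oracle: average over all pos/neg comparisons
brute_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) {
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# brute-force mutual information (bits) of two 0/1 vectors
brute_mi <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (a in 0:1) for (b in 0:1) {
    p <- sum(x == a & y == b) / n
    if (p > 0) mi <- mi + p * log2(p / ((sum(x == a) / n) * (sum(y == b) / n)))
  }
  mi
}
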