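# Per-pair feature engineering from six evidence categories:
# interologs, phylogenetic profiles, domain-domain interactions, subcellular
# colocalization, coexpression, shared annotation. The per-pair functions are
# simple reference implementations; build_feature_matrix() computes the same
# quantities vectorized over gene-by-gene matrices.

#' Assemble an evidence bundle
#'
#' Container for the six evidence categories. Any category may be `NULL`
#' (unavailable); its feature columns are then `NA` in the feature matrix.
#'
#' @param orthologs data.frame `species`, `mouse_gene`, `foreign_gene`.
#' @param foreign_interactions data.frame `species`, `gene_a`, `gene_b`
#'   (foreign-namespace IDs), the known interactions in each reference
#'   species.
#' @param phylo 0/1 numeric matrix, rows = genes, columns = species panel.
#' @param domains data.frame `gene`, `domain`.
#' @param domain_scores data.frame `domain_a`, `domain_b`, `score` with
#'   scores in \[0, 1\] (unordered domain pairs).
#' @param compartments data.frame `gene`, `compartment`, `confidence` with
#'   confidences in \[0, 1\].
#' @param expression numeric matrix, rows = genes, columns = samples.
#' @param annotations data.frame `gene`, `term`.
#' @param term_freq named numeric vector of term background frequencies in
#'   (0, 1\].
#' @return object of class `evidence_bundle`.
#' @export
evidence_bundle <- function(orthologs = NULL, foreign_interactions = NULL,
                            phylo = NULL, domains = NULL,
                            domain_scores = NULL, compartments = NULL,
                            expression = NULL, annotations = NULL,
                            term_freq = NULL) {
  if (!is.null(domain_scores)) {
    stopifnot(all(domain_scores$score >= 0 & domain_scores$score <= 1))
    dp <- canonical_pairs(domain_scores$domain_a, domain_scores$domain_b)
    domain_scores <- data.frame(domain_a = dp$from, domain_b = dp$to,
                                score = domain_scores$score,
                                stringsAsFactors = FALSE)
    domain_scores <- domain_scores[!duplicated(paste(domain_scores$domain_a,
                                                     domain_scores$domain_b)), ]
  }
  if (!is.null(compartments)) {
    stopifnot(all(compartments$confidence >= 0 & compartments$confidence <= 1))
  }
  if (!is.null(term_freq)) {
    stopifnot(all(term_freq > 0 & term_freq <= 1))
  }
  if (!is.null(phylo)) stopifnot(is.matrix(phylo), !is.null(rownames(phylo)))
  if (!is.null(expression)) {
    stopifnot(is.matrix(expression), !is.null(rownames(expression)))
  }
  structure(list(orthologs = orthologs,
                 foreign_interactions = foreign_interactions,
                 phylo = phylo, domains = domains,
                 domain_scores = domain_scores, compartments = compartments,
                 expression = expression, annotations = annotations,
                 term_freq = term_freq),
            class = "evidence_bundle")
}

#' @export
print.evidence_bundle <- function(x, ...) {
  have <- names(x)[!vapply(x, is.null, TRUE)]
  cat("Evidence bundle with:", paste(have, collapse = ", "), "\n")
  invisible(x)
}

domain_score_key <- function(a, b) {
  p <- canonical_pairs(a, b)
  paste(p$from, p$to, sep = "|")
}

#' Interolog feature: conserved interactions across reference species
#'
#' Counts the reference species in which some ortholog of the first gene is
#' known to interact with some ortholog of the second gene.
#'
#' @param pair character vector of two gene IDs.
#' @param bundle an `evidence_bundle` with `orthologs` and
#'   `foreign_interactions`.
#' @return non-negative integer count of supporting species.
#' @export
interolog_feature <- function(pair, bundle) {
  orth <- bundle$orthologs
  fi <- bundle$foreign_interactions
  if (is.null(orth) || is.null(fi)) return(NA_integer_)
  n <- 0L
  for (s in unique(orth$species)) {
    o1 <- orth$foreign_gene[orth$species == s & orth$mouse_gene == pair[1]]
    o2 <- orth$foreign_gene[orth$species == s & orth$mouse_gene == pair[2]]
    if (length(o1) == 0 || length(o2) == 0) next
    es <- fi[fi$species == s, , drop = FALSE]
    hit <- (es$gene_a %in% o1 & es$gene_b %in% o2) |
      (es$gene_a %in% o2 & es$gene_b %in% o1)
    if (any(hit)) n <- n + 1L
  }
  n
}

#' Phylogenetic-profile features for a gene pair
#'
#' Jaccard similarity of the presence sets, Pearson correlation of the 0/1
#' vectors (`NA` if either vector is constant), and the mutual information of
#' the joint presence distribution in bits.
#'
#' @param pair character vector of two gene IDs.
#' @param profiles 0/1 matrix over a shared species panel (rows = genes).
#' @return named numeric vector `jaccard`, `pearson`, `mi`.
#' @export
phylo_profile_features <- function(pair, profiles) {
  if (ncol(profiles) < 2) stop("species panel must have length >= 2")
  if (!all(pair %in% rownames(profiles))) {
    return(c(jaccard = NA_real_, pearson = NA_real_, mi = NA_real_))
  }
  x <- profiles[pair[1], ]
  y <- profiles[pair[2], ]
  if (length(x) != length(y)) stop("species panel mismatch")
  un <- sum(x | y)
  jac <- if (un == 0) 0 else sum(x & y) / un
  pea <- if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  n <- length(x)
  mi <- 0
  for (a in 0:1) {
    for (b in 0:1) {
      p <- sum(x == a & y == b) / n
      if (p > 0) {
        mi <- mi + p * log2(p / ((sum(x == a) / n) * (sum(y == b) / n)))
      }
    }
  }
  c(jaccard = jac, pearson = pea, mi = mi)
}

#' Domain-interaction features for a gene pair
#'
#' Over all cross products of the two genes' domain sets against a scored
#' domain-pair table: count of scored pairs, maximum score, sum of scores,
#' and count divided by the cross-product size. All zero when either gene
#' has no domains.
#'
#' @param pair character vector of two gene IDs.
#' @param bundle an `evidence_bundle` with `domains` and `domain_scores`.
#' @return named numeric vector `n_scored`, `max_score`, `sum_score`,
#'   `density`.
#' @export
domain_features <- function(pair, bundle) {
  d <- bundle$domains
  tab <- bundle$domain_scores
  zero <- c(n_scored = 0, max_score = 0, sum_score = 0, density = 0)
  if (is.null(d) || is.null(tab)) {
    return(c(n_scored = NA_real_, max_score = NA_real_, sum_score = NA_real_,
             density = NA_real_))
  }
  d1 <- unique(d$domain[d$gene == pair[1]])
  d2 <- unique(d$domain[d$gene == pair[2]])
  if (length(d1) == 0 || length(d2) == 0) return(zero)
  score <- stats::setNames(tab$score,
                           domain_score_key(tab$domain_a, tab$domain_b))
  cross <- expand.grid(a = d1, b = d2, stringsAsFactors = FALSE)
  s <- score[domain_score_key(cross$a, cross$b)]
  s <- s[!is.na(s)]
  c(n_scored = length(s),
    max_score = if (length(s)) max(s) else 0,
    sum_score = sum(s),
    density = length(s) / (length(d1) * length(d2)))
}

#' Subcellular colocalization features for a gene pair
#'
#' Shared-compartment count, Jaccard of compartment sets, the maximum over
#' shared compartments of the lower of the two confidences, and a 0/1
#' colocalization indicator.
#'
#' @param pair character vector of two gene IDs.
#' @param bundle an `evidence_bundle` with `compartments`.
#' @return named numeric vector `n_shared`, `jaccard`, `max_conf`, `any`.
#' @export
colocalization_features <- function(pair, bundle) {
  cp <- bundle$compartments
  if (is.null(cp)) {
    return(c(n_shared = NA_real_, jaccard = NA_real_, max_conf = NA_real_,
             any = NA_real_))
  }
  conf_of <- function(g) {
    sub <- cp[cp$gene == g, , drop = FALSE]
    if (nrow(sub) == 0) return(numeric(0))
    tapply(sub$confidence, sub$compartment, max)
  }
  c1 <- conf_of(pair[1])
  c2 <- conf_of(pair[2])
  shared <- intersect(names(c1), names(c2))
  un <- union(names(c1), names(c2))
  c(n_shared = length(shared),
    jaccard = if (length(un) == 0) 0 else length(shared) / length(un),
    max_conf = if (length(shared) == 0) 0 else
      max(pmin(c1[shared], c2[shared])),
    any = as.numeric(length(shared) >= 1))
}

#' Coexpression features for a gene pair
#'
#' Pearson correlation of the two expression profiles and the mutual rank:
#' the geometric mean of each gene's 1-based rank among the other gene's
#' partners ordered by decreasing absolute correlation (ties broken by
#' partner ID). `NA` if either profile is constant or absent.
#'
#' @param pair character vector of two gene IDs.
#' @param expression numeric matrix (rows = genes, columns = samples).
#' @return named numeric vector `pcc`, `mutual_rank`.
#' @export
coexpression_features <- function(pair, expression) {
  if (ncol(expression) < 3) stop("need >= 3 samples")
  if (!all(pair %in% rownames(expression))) {
    return(c(pcc = NA_real_, mutual_rank = NA_real_))
  }
  genes <- rownames(expression)
  sds <- apply(expression, 1, sd)
  if (sds[pair[1]] == 0 || sds[pair[2]] == 0) {
    return(c(pcc = NA_real_, mutual_rank = NA_real_))
  }
  pcc <- cor(expression[pair[1], ], expression[pair[2], ])
  rank_of <- function(g, partner) {
    others <- setdiff(genes, g)
    r <- suppressWarnings(
      as.vector(cor(expression[g, ], t(expression[others, , drop = FALSE]))))
    ord <- others[order(-abs(r), others, na.last = TRUE)]
    match(partner, ord)
  }
  r12 <- rank_of(pair[1], pair[2])
  r21 <- rank_of(pair[2], pair[1])
  c(pcc = pcc, mutual_rank = sqrt(r12 * r21))
}

#' Shared-annotation features for a gene pair
#'
#' Shared-term count, Jaccard of term sets, and the maximum information
#' content (-log2 of the background frequency) among shared terms.
#'
#' @param pair character vector of two gene IDs.
#' @param bundle an `evidence_bundle` with `annotations` and `term_freq`.
#' @return named numeric vector `n_shared`, `jaccard`, `max_ic`.
#' @export
annotation_features <- function(pair, bundle) {
  an <- bundle$annotations
  freq <- bundle$term_freq
  if (is.null(an) || is.null(freq)) {
    return(c(n_shared = NA_real_, jaccard = NA_real_, max_ic = NA_real_))
  }
  t1 <- unique(an$term[an$gene == pair[1]])
  t2 <- unique(an$term[an$gene == pair[2]])
  shared <- intersect(t1, t2)
  un <- union(t1, t2)
  if (length(shared) > 0) {
    f <- freq[shared]
    if (anyNA(f) || any(f <= 0)) {
      stop("term with zero/missing background frequency among shared terms ",
           "(frequency must include the annotated gene)")
    }
  }
  c(n_shared = length(shared),
    jaccard = if (length(un) == 0) 0 else length(shared) / length(un),
    max_ic = if (length(shared) == 0) 0 else max(-log2(freq[shared])))
}

#' Feature column names, in matrix order
#'
#' @return character vector of the 17 feature names across the six
#'   categories (category prefix before the dot).
#' @export
feature_names <- function() {
  c("interolog.n_species",
    "phylo.jaccard", "phylo.pearson", "phylo.mi",
    "domain.n_scored", "domain.max_score", "domain.sum_score",
    "domain.density",
    "coloc.n_shared", "coloc.jaccard", "coloc.max_conf", "coloc.any",
    "coexpr.pcc", "coexpr.mutual_rank",
    "annot.n_shared", "annot.jaccard", "annot.max_ic")
}

#' Evidence category of feature names
#'
#' @param features character vector of feature names.
#' @return character vector of category prefixes.
#' @export
feature_category <- function(features) sub("\\..*$", "", features)

# value extraction from a symmetric gene-by-gene matrix for pair indices;
# indices may be NA (gene absent from the evidence subset)
pairval <- function(M, genes_sub, from, to) {
  i <- match(from, genes_sub)
  j <- match(to, genes_sub)
  out <- rep(NA_real_, length(from))
  ok <- !is.na(i) & !is.na(j)
  out[ok] <- M[cbind(i[ok], j[ok])]
  out
}

#' Build the pair-by-feature matrix
#'
#' Computes all configured features for a list of gene pairs, vectorized
#' over gene-by-gene evidence matrices. Feature values are `NA` where the
#' underlying evidence is absent (missing category, or absent/constant
#' profiles for the phylogenetic and coexpression categories); the
#' domain/colocalization/annotation/interolog features use 0 for genes not
#' listed in an available evidence table, matching their per-pair
#' definitions. Pairs whose genes appear in no evidence source at all get an
#' all-`NA` row (count reported via `message()`).
#'
#' @param pairs canonical pair data.frame (`from`, `to`).
#' @param bundle an `evidence_bundle`.
#' @return data.frame of class `feature_matrix`: columns `from`, `to`, then
#'   the features of [feature_names()].
#' @export
build_feature_matrix <- function(pairs, bundle) {
  stopifnot(inherits(bundle, "evidence_bundle"))
  np <- nrow(pairs)
  out <- data.frame(from = pairs$from, to = pairs$to,
                    stringsAsFactors = FALSE)
  for (f in feature_names()) out[[f]] <- rep(NA_real_, np)
  if (np == 0) {
    class(out) <- c("feature_matrix", "data.frame")
    return(out)
  }
  genes <- sort(unique(c(pairs$from, pairs$to)))
  from <- pairs$from
  to <- pairs$to

  # --- interologs -----------------------------------------------------------
  if (!is.null(bundle$orthologs) && !is.null(bundle$foreign_interactions)) {
    count <- rep(0, np)
    keys <- pair_key(pairs)
    for (s in unique(bundle$orthologs$species)) {
      om <- bundle$orthologs[bundle$orthologs$species == s,
                             c("mouse_gene", "foreign_gene")]
      fi <- bundle$foreign_interactions[
        bundle$foreign_interactions$species == s, c("gene_a", "gene_b")]
      if (nrow(om) == 0 || nrow(fi) == 0) next
      m1 <- merge(fi, om, by.x = "gene_a", by.y = "foreign_gene")
      m2 <- merge(m1, om, by.x = "gene_b", by.y = "foreign_gene",
                  suffixes = c("_a", "_b"))
      if (nrow(m2) == 0) next
      sup <- unique(pair_key(canonical_pairs(m2$mouse_gene_a,
                                             m2$mouse_gene_b)))
      count <- count + as.numeric(keys %in% sup)
    }
    out$interolog.n_species <- count
  }

  # --- phylogenetic profiles ------------------------------------------------
  if (!is.null(bundle$phylo)) {
    P <- bundle$phylo[intersect(genes, rownames(bundle$phylo)), ,
                      drop = FALSE]
    if (nrow(P) > 0) {
      gsub_ <- rownames(P)
      n11 <- P %*% t(P)
      ones <- rowSums(P)
      un <- outer(ones, ones, `+`) - n11
      jac <- ifelse(un == 0, 0, n11 / un)
      sds <- apply(P, 1, sd)
      pea <- suppressWarnings(cor(t(P)))
      pea[sds == 0, ] <- NA
      pea[, sds == 0] <- NA
      ns <- ncol(P)
      n10 <- outer(ones, rep(1, nrow(P))) - n11  # x=1, y=0
      n01 <- t(n10)
      n00 <- ns - n11 - n10 - n01
      px1 <- ones / ns
      mi <- matrix(0, nrow(P), nrow(P))
      addterm <- function(nxy, px, py) {
        p <- nxy / ns
        t <- p * log2(p / outer(px, py))
        t[p == 0] <- 0
        t
      }
      mi <- addterm(n11, px1, px1) + addterm(n10, px1, 1 - px1) +
        addterm(n01, 1 - px1, px1) + addterm(n00, 1 - px1, 1 - px1)
      out$phylo.jaccard <- pairval(jac, gsub_, from, to)
      out$phylo.pearson <- pairval(pea, gsub_, from, to)
      out$phylo.mi <- pairval(mi, gsub_, from, to)
    }
  }

  # --- domains --------------------------------------------------------------
  if (!is.null(bundle$domains) && !is.null(bundle$domain_scores)) {
    d <- bundle$domains[bundle$domains$gene %in% genes, , drop = FALSE]
    doms <- sort(unique(c(d$domain, bundle$domain_scores$domain_a,
                          bundle$domain_scores$domain_b)))
    G <- matrix(0, length(genes), length(doms),
                dimnames = list(genes, doms))
    if (nrow(d) > 0) G[cbind(d$gene, d$domain)] <- 1
    S <- matrix(0, length(doms), length(doms),
                dimnames = list(doms, doms))
    ds <- bundle$domain_scores
    S[cbind(ds$domain_a, ds$domain_b)] <- ds$score
    S[cbind(ds$domain_b, ds$domain_a)] <- ds$score
    cnt <- G %*% (S > 0) %*% t(G)
    ssum <- G %*% S %*% t(G)
    sizes <- rowSums(G)
    denom <- outer(sizes, sizes)
    dens <- ifelse(denom == 0, 0, cnt / denom)
    mx <- matrix(0, length(genes), length(genes))
    for (r in seq_len(nrow(ds))) {
      a <- which(G[, ds$domain_a[r]] > 0)
      b <- which(G[, ds$domain_b[r]] > 0)
      if (length(a) && length(b)) {
        mx[a, b] <- pmax(mx[a, b], ds$score[r])
        mx[b, a] <- pmax(mx[b, a], ds$score[r])
      }
    }
    out$domain.n_scored <- pairval(cnt, genes, from, to)
    out$domain.max_score <- pairval(mx, genes, from, to)
    out$domain.sum_score <- pairval(ssum, genes, from, to)
    out$domain.density <- pairval(dens, genes, from, to)
  }

  # --- colocalization -------------------------------------------------------
  if (!is.null(bundle$compartments)) {
    cp <- bundle$compartments[bundle$compartments$gene %in% genes, ,
                              drop = FALSE]
    comps <- sort(unique(bundle$compartments$compartment))
    A <- matrix(0, length(genes), length(comps),
                dimnames = list(genes, comps))
    if (nrow(cp) > 0) {
      agg <- stats::aggregate(confidence ~ gene + compartment, cp, max)
      A[cbind(agg$gene, agg$compartment)] <- agg$confidence
    }
    A01 <- (A > 0) * 1
    nsh <- A01 %*% t(A01)
    sizes <- rowSums(A01)
    un <- outer(sizes, sizes, `+`) - nsh
    jac <- ifelse(un == 0, 0, nsh / un)
    mx <- matrix(0, length(genes), length(genes))
    for (c_ in seq_along(comps)) {
      v <- A[, c_]
      m <- which(v > 0)
      if (length(m)) mx[m, m] <- pmax(mx[m, m], outer(v[m], v[m], pmin))
    }
    out$coloc.n_shared <- pairval(nsh, genes, from, to)
    out$coloc.jaccard <- pairval(jac, genes, from, to)
    out$coloc.max_conf <- pairval(mx, genes, from, to)
    out$coloc.any <- as.numeric(out$coloc.n_shared >= 1)
  }

  # --- coexpression ---------------------------------------------------------
  if (!is.null(bundle$expression)) {
    # ranks are taken within the full profiled gene universe, so keep all
    # profiled genes when computing the correlation matrix
    E <- bundle$expression
    sds <- apply(E, 1, sd)
    C <- suppressWarnings(cor(t(E)))
    C[sds == 0, ] <- NA
    C[, sds == 0] <- NA
    gE <- rownames(E)
    nE <- length(gE)
    R <- matrix(NA_real_, nE, nE, dimnames = list(gE, gE))
    for (i in seq_len(nE)) {
      idx <- setdiff(seq_len(nE), i)
      ord <- idx[order(-abs(C[i, idx]), gE[idx], na.last = TRUE)]
      R[i, ord] <- seq_along(ord)
    }
    mr <- sqrt(R * t(R))
    pcc <- C
    diag(pcc) <- 1
    mr[is.na(pcc)] <- NA
    out$coexpr.pcc <- pairval(pcc, gE, from, to)
    out$coexpr.mutual_rank <- pairval(mr, gE, from, to)
  }

  # --- shared annotation ----------------------------------------------------
  if (!is.null(bundle$annotations) && !is.null(bundle$term_freq)) {
    an <- bundle$annotations[bundle$annotations$gene %in% genes, ,
                             drop = FALSE]
    terms <- sort(unique(bundle$annotations$term))
    f <- bundle$term_freq[terms]
    if (anyNA(f) || any(f <= 0)) {
      stop("annotated term with zero/missing background frequency")
    }
    Tm <- matrix(0, length(genes), length(terms),
                 dimnames = list(genes, terms))
    if (nrow(an) > 0) Tm[cbind(an$gene, an$term)] <- 1
    nsh <- Tm %*% t(Tm)
    sizes <- rowSums(Tm)
    un <- outer(sizes, sizes, `+`) - nsh
    jac <- ifelse(un == 0, 0, nsh / un)
    mx <- matrix(0, length(genes), length(genes))
    ic <- -log2(f)
    for (t_ in order(ic)) {  # ascending, so pmax ends at the right value
      m <- which(Tm[, t_] > 0)
      if (length(m)) mx[m, m] <- pmax(mx[m, m], ic[t_])
    }
    out$annot.n_shared <- pairval(nsh, genes, from, to)
    out$annot.jaccard <- pairval(jac, genes, from, to)
    out$annot.max_ic <- pairval(mx, genes, from, to)
  }

  # genes absent from every available evidence source -> all-NA row, logged
  known <- character(0)
  if (!is.null(bundle$orthologs)) {
    known <- c(known, bundle$orthologs$mouse_gene)
  }
  if (!is.null(bundle$phylo)) known <- c(known, rownames(bundle$phylo))
  if (!is.null(bundle$domains)) known <- c(known, bundle$domains$gene)
  if (!is.null(bundle$compartments)) {
    known <- c(known, bundle$compartments$gene)
  }
  if (!is.null(bundle$expression)) known <- c(known, rownames(bundle$expression))
  if (!is.null(bundle$annotations)) known <- c(known, bundle$annotations$gene)
  orphan <- from %in% setdiff(genes, known) | to %in% setdiff(genes, known)
  if (any(orphan)) {
    message(sum(orphan), " pair(s) contain a gene absent from every ",
            "evidence source; rows set to NA")
    out[orphan, feature_names()] <- NA_real_
  }
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Write a feature matrix as TSV (`NA` for missing)
#'
#' @param fm a `feature_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  write.table(fm, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a feature matrix TSV
#'
#' @param path path written by [write_feature_matrix()].
#' @return a `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  fm <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}
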