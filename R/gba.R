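# Guilt-by-association network-quality benchmark: predict each gene's
# annotations as the terms enriched (hypergeometric) among its first-degree
# network neighbours, then sweep the enrichment p-value cutoff to trace a
# precision-recall curve against a temporal annotation split. Precision is
# measured against all annotations, recall against the newly added ones
# only.

#' Temporal annotation split
#'
#' @param old data.frame `gene`, `term`: annotations known before the
#'   cutoff date.
#' @param new data.frame `gene`, `term`: annotations added after the
#'   cutoff; must be disjoint from `old` per gene.
#' @return object of class `annotation_split` with `old`, `new`, `all`.
#' @export
annotation_split <- function(old, new) {
  old <- unique(old[, c("gene", "term")])
  new <- unique(new[, c("gene", "term")])
  ko <- paste(old$gene, old$term)
  kn <- paste(new$gene, new$term)
  if (length(intersect(ko, kn)) > 0) {
    stop("new annotations overlap old annotations")
  }
  structure(list(old = old, new = new, all = rbind(old, new)),
            class = "annotation_split")
}

#' Predict a gene's annotations from its network neighbours
#'
#' For each term annotated to at least one first-degree neighbour, the
#' hypergeometric upper-tail p-value of the term's frequency among the
#' neighbours relative to the annotated background. The query gene's own
#' annotations are excluded from the evidence (the gene is removed from the
#' background and neighbour counts).
#'
#' @param gene a gene ID present in the network.
#' @param net an `fa_network`.
#' @param annotations data.frame `gene`, `term` (the pre-cutoff
#'   annotations).
#' @param p_cutoff return terms with `p <= p_cutoff` (default 0.05).
#' @return data.frame `term`, `p` (possibly empty; a gene without
#'   neighbours yields an empty result).
#' @export
neighbor_enrichment_predict <- function(gene, net, annotations,
                                        p_cutoff = 0.05) {
  stopifnot(gene %in% net$nodes)
  e <- net$edges
  nb <- unique(c(e$to[e$from == gene], e$from[e$to == gene]))
  nb <- setdiff(nb, gene)
  empty <- data.frame(term = character(), p = numeric(),
                      stringsAsFactors = FALSE)
  if (length(nb) == 0) return(empty)
  ann <- annotations[annotations$gene != gene, , drop = FALSE]
  bg_genes <- unique(ann$gene)
  N <- length(bg_genes)
  nb_ann <- intersect(nb, bg_genes)
  n <- length(nb_ann)
  if (n == 0) return(empty)
  nb_terms <- ann[ann$gene %in% nb_ann, , drop = FALSE]
  tt <- table(nb_terms$term)
  terms <- names(tt)
  K <- vapply(terms, function(t_) length(unique(ann$gene[ann$term == t_])), 0)
  k <- as.integer(tt)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, p = p, stringsAsFactors = FALSE)
  out <- out[out$p <= p_cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Neighbour-enrichment predictions for many genes
#'
#' @param net an `fa_network`.
#' @param annotations data.frame `gene`, `term` (pre-cutoff annotations).
#' @param genes genes to predict for (default: all network nodes).
#' @param p_cutoff keep predictions with `p <= p_cutoff` (default 1, i.e.
#'   every term present in at least one neighbour, for downstream cutoff
#'   sweeps).
#' @return data.frame `gene`, `term`, `p`.
#' @export
predict_annotations <- function(net, annotations, genes = net$nodes,
                                p_cutoff = 1) {
  res <- lapply(genes, function(g) {
    pr <- neighbor_enrichment_predict(g, net, annotations, p_cutoff)
    if (nrow(pr) == 0) return(NULL)
    cbind(gene = g, pr, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0) {
    return(data.frame(gene = character(), term = character(), p = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Precision-recall curve of annotation prediction
#'
#' Sweeps p-value cutoffs; at each cutoff, precision is the fraction of
#' predicted (gene, term) pairs found among all annotations, and recall is
#' the fraction of the newly added annotations that were predicted. The
#' area under the curve is the trapezoid over recall. Cutoffs with zero
#' predictions are skipped (with a note).
#'
#' @param predictions data.frame `gene`, `term`, `p` (from
#'   [predict_annotations()]).
#' @param split an `annotation_split`.
#' @param cutoffs p-value cutoffs to sweep (default: the distinct observed
#'   p-values).
#' @param recall_denominator `"new"` (default: all newly added
#'   annotations) or `"predicted"` (the predicted pairs at the cutoff).
#' @return object of class `pr_curve`: `points` (data.frame `cutoff`,
#'   `precision`, `recall`) and `pr_auc`.
#' @export
precision_recall_curve <- function(predictions, split, cutoffs = NULL,
                                   recall_denominator = c("new",
                                                          "predicted")) {
  recall_denominator <- match.arg(recall_denominator)
  stopifnot(inherits(split, "annotation_split"))
  if (is.null(cutoffs)) cutoffs <- sort(unique(predictions$p))
  key <- paste(predictions$gene, predictions$term)
  all_key <- paste(split$all$gene, split$all$term)
  new_key <- paste(split$new$gene, split$new$term)
  pts <- lapply(cutoffs, function(c_) {
    sel <- key[predictions$p <= c_]
    if (length(sel) == 0) return(NULL)
    prec <- mean(sel %in% all_key)
    hits_new <- sum(sel %in% new_key)
    rec <- if (recall_denominator == "new") hits_new / length(new_key)
    else hits_new / length(sel)
    data.frame(cutoff = c_, precision = prec, recall = rec)
  })
  skipped <- sum(vapply(pts, is.null, TRUE))
  if (skipped > 0) message(skipped, " cutoff(s) with zero predictions skipped")
  pts <- do.call(rbind, pts[!vapply(pts, is.null, TRUE)])
  if (is.null(pts) || nrow(pts) == 0) stop("no cutoff yields a prediction")
  ord <- order(pts$recall, pts$precision)
  r <- pts$recall[ord]
  p <- pts$precision[ord]
  auc <- if (length(r) < 2) 0 else
    sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  structure(list(points = pts, pr_auc = auc), class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("Precision-recall curve: %d points, PR-AUC = %.4f\n",
              nrow(x$points), x$pr_auc))
  invisible(x)
}

#' Benchmark a network by guilt-by-association annotation prediction
#'
#' Convenience wrapper: predicts annotations for every network gene from
#' the pre-cutoff annotations and traces the precision-recall curve against
#' the newly added ones.
#'
#' @param net an `fa_network`.
#' @param split an `annotation_split`.
#' @param ... passed to [precision_recall_curve()].
#' @return a `pr_curve`.
#' @export
gba_benchmark <- function(net, split, ...) {
  pred <- predict_annotations(net, split$old)
  precision_recall_curve(pred, split, ...)
}
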