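# On-disk representation of an evidence bundle: one TSV per category in a
# directory (wide gene-by-column tables for profiles and expression).

#' Write an evidence bundle to a directory of TSV files
#'
#' @param bundle an `evidence_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evidence_dir <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
  }
  if (!is.null(bundle$orthologs)) wt(bundle$orthologs, "orthologs.tsv")
  if (!is.null(bundle$foreign_interactions)) {
    wt(bundle$foreign_interactions, "foreign_interactions.tsv")
  }
  if (!is.null(bundle$phylo)) {
    wt(data.frame(gene = rownames(bundle$phylo), bundle$phylo,
                  check.names = FALSE), "phylo.tsv")
  }
  if (!is.null(bundle$domains)) wt(bundle$domains, "domains.tsv")
  if (!is.null(bundle$domain_scores)) {
    wt(bundle$domain_scores, "domain_scores.tsv")
  }
  if (!is.null(bundle$compartments)) wt(bundle$compartments,
                                        "compartments.tsv")
  if (!is.null(bundle$expression)) {
    wt(data.frame(gene = rownames(bundle$expression), bundle$expression,
                  check.names = FALSE), "expression.tsv")
  }
  if (!is.null(bundle$annotations)) wt(bundle$annotations, "annotations.tsv")
  if (!is.null(bundle$term_freq)) {
    wt(data.frame(term = names(bundle$term_freq),
                  freq = as.numeric(bundle$term_freq)), "term_freq.tsv")
  }
  invisible(dir)
}

#' Read an evidence bundle from a directory of TSV files
#'
#' Missing files yield `NULL` categories.
#'
#' @param dir directory written by [write_evidence_dir()].
#' @return an `evidence_bundle`.
#' @export
read_evidence_dir <- function(dir) {
  rd <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) return(NULL)
    read.delim(p, stringsAsFactors = FALSE, check.names = FALSE,
               comment.char = "#")
  }
  as_mat <- function(df) {
    if (is.null(df)) return(NULL)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene
    m
  }
  tfdf <- rd("term_freq.tsv")
  evidence_bundle(
    orthologs = rd("orthologs.tsv"),
    foreign_interactions = rd("foreign_interactions.tsv"),
    phylo = as_mat(rd("phylo.tsv")),
    domains = rd("domains.tsv"),
    domain_scores = rd("domain_scores.tsv"),
    compartments = rd("compartments.tsv"),
    expression = as_mat(rd("expression.tsv")),
    annotations = rd("annotations.tsv"),
    term_freq = if (is.null(tfdf)) NULL else
      stats::setNames(tfdf$freq, tfdf$term))
}
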