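# Gold-standard curation: high-confidence positives from curated interaction
# records, a temporal train/evaluation split, and random negative sampling at
# a declared class ratio.

#' Read curated interaction records
#'
#' TSV with columns `gene_a`, `gene_b`, `publication_id`, `method_class`
#' (`low_throughput` or `high_throughput`), `year` — one row per piece of
#' publication evidence for a pair. Pairs are canonicalized.
#'
#' @param path path to the TSV (header required).
#' @return data.frame of class `interaction_records` with columns `from`,
#'   `to`, `publication_id`, `method_class`, `year`.
#' @export
read_interaction_records <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                   fileEncoding = "UTF-8")
  req <- c("gene_a", "gene_b", "publication_id", "method_class", "year")
  if (!all(req %in% names(df))) {
    stop("interaction-record file must have columns: ",
         paste(req, collapse = ", "))
  }
  interaction_records(df$gene_a, df$gene_b, df$publication_id,
                      df$method_class, df$year)
}

#' Construct interaction records
#'
#' @param gene_a,gene_b gene IDs of the interacting pair.
#' @param publication_id publication identifier of the report.
#' @param method_class `"low_throughput"` or `"high_throughput"`.
#' @param year publication year (integer).
#' @return data.frame of class `interaction_records`.
#' @export
interaction_records <- function(gene_a, gene_b, publication_id, method_class,
                                year) {
  ok <- method_class %in% c("low_throughput", "high_throughput")
  if (!all(ok)) {
    stop("unknown method_class: ", paste(unique(method_class[!ok]),
                                         collapse = ", "))
  }
  pr <- canonical_pairs(gene_a, gene_b)
  rec <- data.frame(from = pr$from, to = pr$to,
                    publication_id = as.character(publication_id),
                    method_class = as.character(method_class),
                    year = suppressWarnings(as.integer(year)),
                    stringsAsFactors = FALSE)
  rec <- unique(rec)
  class(rec) <- c("interaction_records", "data.frame")
  rec
}

#' Filter interaction records to high-confidence pairs
#'
#' A pair is retained iff it was reported in at least `min_studies` distinct
#' publications AND (when `require_low_throughput`) at least one report used
#' a low-throughput method — removing pairs seen in fewer than two
#' independent studies or only in high-throughput screens.
#'
#' @param records an `interaction_records` data.frame.
#' @param min_studies minimum number of distinct publications (default 2).
#' @param require_low_throughput require at least one low-throughput report.
#' @return canonical pair data.frame (`from`, `to`).
#' @export
filter_high_confidence <- function(records, min_studies = 2,
                                   require_low_throughput = TRUE) {
  if (nrow(records) == 0) {
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  key <- pair_key(records)
  npub <- tapply(records$publication_id, key,
                 function(p) length(unique(p)))
  has_lt <- tapply(records$method_class, key,
                   function(m) any(m == "low_throughput"))
  ok <- npub >= min_studies
  if (require_low_throughput) ok <- ok & has_lt
  keys <- names(ok)[ok]
  out <- unique(records[key %in% keys, c("from", "to")])
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split pairs into training and evaluation sets by first-report year
#'
#' A pair belongs to training if its earliest publication year is at or
#' before the cutoff, and to evaluation otherwise, so evaluation pairs are
#' genuinely novel relative to the training evidence.
#'
#' @param records an `interaction_records` data.frame; every row must carry
#'   a year.
#' @param cutoff_year last year included in training (e.g. 2017 for evidence
#'   collected before 2018).
#' @return list with `train` and `eval` canonical pair data.frames.
#' @export
temporal_split <- function(records, cutoff_year) {
  if (anyNA(records$year)) {
    bad <- pair_key(records)[is.na(records$year)][1]
    stop("record without a year: ", bad)
  }
  key <- pair_key(records)
  first_year <- tapply(records$year, key, min)
  split_pairs <- function(keys) {
    if (length(keys) == 0) {
      return(data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE))
    }
    parts <- strsplit(keys, "|", fixed = TRUE)
    out <- data.frame(from = vapply(parts, `[[`, "", 1L),
                      to = vapply(parts, `[[`, "", 2L),
                      stringsAsFactors = FALSE)
    out <- out[order(out$from, out$to), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(train = split_pairs(names(first_year)[first_year <= cutoff_year]),
       eval = split_pairs(names(first_year)[first_year > cutoff_year]))
}

#' Sample random negative gene pairs
#'
#' Uniform sampling without replacement over all unordered pairs of the
#' universe, excluding the positive pairs, at `ratio` negatives per positive
#' (floored). Deterministic under a fixed seed.
#'
#' @param universe character vector of gene IDs.
#' @param positives canonical pair data.frame of positive pairs.
#' @param ratio negatives per positive (default 100, the class ratio used at
#'   training time).
#' @param seed integer RNG seed.
#' @param n_negatives optional explicit count, overriding `ratio`.
#' @return canonical pair data.frame of negatives, disjoint from positives.
#' @export
sample_negatives <- function(universe, positives, ratio = 100, seed = 1,
                             n_negatives = NULL) {
  universe <- sort(unique(as.character(universe)))
  n <- length(universe)
  npairs <- n * (n - 1) / 2
  m <- if (is.null(n_negatives)) floor(ratio * nrow(positives)) else n_negatives
  pos_key <- pair_key(positives)
  if (npairs - length(pos_key) < m) {
    stop("universe too small: ", npairs, " pairs minus ", length(pos_key),
         " positives cannot supply ", m, " negatives")
  }
  set.seed(seed)
  chosen <- numeric(0)
  while (length(chosen) < m) {
    k <- sample(npairs, min(npairs, ceiling((m - length(chosen)) * 1.2) + 10))
    ij <- pair_from_index(k, n)
    cand <- canonical_pairs(universe[ij[, 1]], universe[ij[, 2]])
    keys <- pair_key(cand)
    ok <- !(keys %in% pos_key) & !(k %in% chosen) & !duplicated(k)
    chosen <- c(chosen, k[ok])
  }
  chosen <- chosen[seq_len(m)]
  ij <- pair_from_index(chosen, n)
  out <- canonical_pairs(universe[ij[, 1]], universe[ij[, 2]])
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bundle positives and negatives into a labeled pair set
#'
#' @param positives,negatives canonical pair data.frames; must be disjoint.
#' @return object of class `labeled_pairs` with `positives`, `negatives`,
#'   `ratio`.
#' @export
labeled_pairs <- function(positives, negatives) {
  if (length(intersect(pair_key(positives), pair_key(negatives))) > 0) {
    stop("positives and negatives overlap")
  }
  structure(list(positives = positives, negatives = negatives,
                 ratio = nrow(negatives) / max(1, nrow(positives))),
            class = "labeled_pairs")
}

#' @export
print.labeled_pairs <- function(x, ...) {
  cat("Labeled pairs:", nrow(x$positives), "positives,", nrow(x$negatives),
      sprintf("negatives (1:%.1f)\n", x$ratio))
  invisible(x)
}
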