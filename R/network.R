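#' Construct an undirected gene association network
#'
#' A network is a simple undirected graph over gene IDs with an optional
#' per-edge score. Self-loops are dropped (with a warning) and duplicate
#' edges are merged keeping the maximum score.
#'
#' @param edges data.frame with columns `from`, `to` and optionally `score`.
#' @param nodes optional character vector of node IDs; the union with the
#'   edge endpoints is used, so isolated nodes can be declared.
#' @return object of class `fa_network` with elements `nodes` (sorted
#'   character vector) and `edges` (canonical pair data.frame with `score`).
#' @export
network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    ed <- data.frame(from = character(), to = character(), score = numeric(),
                     stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("from", "to") %in% names(edges)))
    score <- if ("score" %in% names(edges)) as.numeric(edges$score) else
      rep(NA_real_, nrow(edges))
    ed <- canonical_pairs(edges$from, edges$to)
    ed$score <- score
    self <- ed$from == ed$to
    if (any(self)) {
      warning(sum(self), " self-loop(s) dropped")
      ed <- ed[!self, , drop = FALSE]
    }
    if (nrow(ed) > 0) {
      key <- pair_key(ed)
      if (anyDuplicated(key)) {
        sc <- tapply(ed$score, key, function(s)
          if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE))
        keep <- !duplicated(key)
        ed <- ed[keep, , drop = FALSE]
        ed$score <- as.numeric(sc[pair_key(ed)])
      }
      ed <- ed[order(ed$from, ed$to), , drop = FALSE]
      rownames(ed) <- NULL
    }
  }
  nodes <- sort(unique(c(as.character(nodes), ed$from, ed$to)))
  structure(list(nodes = nodes, edges = ed), class = "fa_network")
}

#' @export
print.fa_network <- function(x, ...) {
  cat("Functional association network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Node degrees of a network
#'
#' @param net an `fa_network`.
#' @return named integer vector, one entry per node (isolated nodes have 0).
#' @export
network_degree <- function(net) {
  stopifnot(inherits(net, "fa_network"))
  deg <- table(factor(c(net$edges$from, net$edges$to), levels = net$nodes))
  stats::setNames(as.integer(deg), net$nodes)
}

#' Read a network from a tab-separated edge list
#'
#' Expects 2 or 3 tab-separated columns per row (gene, gene, optional numeric
#' score). Lines starting with `#` are skipped. Self-loops are dropped with a
#' warning; duplicate edges are merged keeping the maximum score.
#'
#' @param path path to a TSV edge list.
#' @return an `fa_network`.
#' @export
read_network <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2)) {
    stop("malformed edge-list row at line ", lineno[which(nf < 2)[1]],
         ": fewer than 2 columns")
  }
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  score <- rep(NA_real_, length(parts))
  has3 <- nf >= 3
  if (any(has3)) {
    raw <- vapply(parts[has3], `[[`, "", 3L)
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      bad <- which(has3)[which(is.na(val))[1]]
      stop("malformed edge-list row at line ", lineno[bad],
           ": non-numeric score")
    }
    score[has3] <- val
  }
  network(data.frame(from = from, to = to, score = score,
                     stringsAsFactors = FALSE))
}

#' Write a network as a tab-separated edge list
#'
#' @param net an `fa_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "fa_network"))
  ed <- net$edges
  if (all(is.na(ed$score))) ed$score <- NULL
  write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, na = "NA")
  invisible(path)
}
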