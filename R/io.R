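# ID mapping, GMT gene-set collections, and input validation.
# All tabular inputs are UTF-8 TSV; lines starting with "#" are comments.

read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE), lineno = which(keep))
}

#' Read an alias-to-canonical gene ID map
#'
#' Two-column TSV: alias, canonical ID. Aliases from any namespace (symbol,
#' UniProt, Ensembl gene/protein, Entrez, canonical) are unified to one
#' canonical namespace (e.g. MGI accessions). An alias mapped to two distinct
#' canonical IDs in the source table is a load-time error, since a silent
#' choice would corrupt downstream pair identities. Canonical IDs always map
#' to themselves.
#'
#' @param path path to the two-column TSV.
#' @return named character vector (`names` = aliases, values = canonical IDs)
#'   of class `id_map`.
#' @export
read_id_map <- function(path) {
  tl <- read_tsv_lines(path)
  nf <- lengths(tl$fields)
  if (length(nf) == 0) stop("empty ID map: ", path)
  if (any(nf < 2)) {
    stop("malformed ID-map row at line ", tl$lineno[which(nf < 2)[1]])
  }
  alias <- vapply(tl$fields, `[[`, "", 1L)
  canon <- vapply(tl$fields, `[[`, "", 2L)
  id_map(alias, canon)
}

#' Build an ID map from alias/canonical vectors
#'
#' @param alias,canonical parallel character vectors.
#' @return named character vector of class `id_map`.
#' @export
id_map <- function(alias, canonical) {
  stopifnot(length(alias) == length(canonical))
  df <- unique(data.frame(alias = as.character(alias),
                          canonical = as.character(canonical),
                          stringsAsFactors = FALSE))
  bad <- df$alias[duplicated(df$alias)]
  if (length(bad) > 0) {
    stop("alias collision(s) in ID map (alias mapped to >1 canonical ID): ",
         paste(unique(bad), collapse = ", "))
  }
  # canonical IDs map to themselves
  extra <- setdiff(df$canonical, df$alias)
  map <- c(stats::setNames(df$canonical, df$alias),
           stats::setNames(extra, extra))
  structure(map, class = "id_map")
}

#' Map gene aliases to canonical IDs
#'
#' Order is preserved; duplicate aliases resolving to the same canonical ID
#' collapse to one occurrence (count reported via `message()`). The mapped
#' and unmapped outputs partition the input.
#'
#' @param aliases non-empty character vector of query IDs.
#' @param idmap an `id_map`.
#' @return list with `mapped` (canonical IDs, input order, deduplicated) and
#'   `unmapped` (aliases not present in the map).
#' @export
map_ids <- function(aliases, idmap) {
  if (length(aliases) == 0) stop("empty query: no aliases given")
  stopifnot(inherits(idmap, "id_map"))
  aliases <- as.character(aliases)
  hit <- aliases %in% names(idmap)
  mapped <- unname(unclass(idmap)[aliases[hit]])
  ndup <- sum(duplicated(mapped))
  if (ndup > 0) {
    message(ndup, " duplicate quer", if (ndup == 1) "y" else "ies",
            " collapsed to already-mapped canonical IDs")
  }
  list(mapped = unique(mapped), unmapped = aliases[!hit])
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT: `set_id TAB description TAB member TAB member ...`. Members
#' are deduplicated; sets left empty are dropped with a warning.
#'
#' @param path path to the GMT file.
#' @return a `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  tl <- read_tsv_lines(path)
  nf <- lengths(tl$fields)
  if (any(nf < 3)) {
    drop <- nf < 3
    # a row with only id+description is an empty set -> warn and drop;
    # fewer than 2 fields is malformed
    if (any(nf < 2)) {
      stop("malformed GMT row at line ", tl$lineno[which(nf < 2)[1]])
    }
    warning(sum(drop), " empty gene set(s) dropped")
    tl$fields <- tl$fields[!drop]
  }
  if (length(tl$fields) == 0) {
    return(gene_set_collection(character(), character(), list()))
  }
  ids <- vapply(tl$fields, `[[`, "", 1L)
  desc <- vapply(tl$fields, `[[`, "", 2L)
  members <- lapply(tl$fields, function(f) unique(f[-(1:2)]))
  gene_set_collection(ids, desc, members)
}

#' Construct a gene-set collection
#'
#' @param set_id unique set identifiers.
#' @param name human-readable set names/descriptions.
#' @param members list of character vectors of member gene IDs.
#' @return object of class `gene_set_collection`: list with `sets`
#'   (data.frame `set_id`, `name`) and `members` (named list).
#' @export
gene_set_collection <- function(set_id, name = set_id, members) {
  set_id <- as.character(set_id)
  if (anyDuplicated(set_id)) stop("duplicate set_ids in collection")
  stopifnot(length(members) == length(set_id))
  members <- lapply(members, function(m) unique(as.character(m)))
  names(members) <- set_id
  structure(list(sets = data.frame(set_id = set_id, name = as.character(name),
                                   stringsAsFactors = FALSE),
                 members = members),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene set collection:", nrow(x$sets), "sets; median size",
      stats::median(lengths(x$members)), "\n")
  invisible(x)
}

#' Write a gene-set collection in GMT format
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(seq_len(nrow(collection$sets)), function(i) {
    paste(c(collection$sets$set_id[i], collection$sets$name[i],
            collection$members[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Validate an input file against its expected schema
#'
#' Runs the corresponding reader and reports success or the parse error.
#'
#' @param path path to the file.
#' @param kind one of `"network"`, `"gmt"`, `"idmap"`, `"interactions"`.
#' @return `TRUE` invisibly on success; otherwise stops with the reader's
#'   error message.
#' @export
validate_file <- function(path, kind = c("network", "gmt", "idmap",
                                         "interactions")) {
  kind <- match.arg(kind)
  reader <- switch(kind,
    network = read_network,
    gmt = read_gmt,
    idmap = read_id_map,
    interactions = read_interaction_records
  )
  suppressWarnings(reader(path))
  invisible(TRUE)
}
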