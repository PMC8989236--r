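# Unordered gene pairs are stored canonically: two character columns `from`,
# `to` with from < to (lexicographic). A pair key is "from|to".

#' Canonicalize unordered gene pairs
#'
#' Sorts each pair lexicographically so that an unordered pair has a single
#' representation (`from < to`).
#'
#' @param a,b character vectors of gene IDs (recycled to common length).
#' @return data.frame with columns `from`, `to`.
#' @export
canonical_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  stopifnot(length(a) == length(b))
  swap <- a > b
  from <- ifelse(swap, b, a)
  to <- ifelse(swap, a, b)
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' Pair keys for canonical pairs
#'
#' @param pairs data.frame with `from`, `to` columns (canonical order).
#' @return character vector of `"from|to"` keys.
#' @export
pair_key <- function(pairs) {
  paste(pairs$from, pairs$to, sep = "|")
}

# Map linear indices k in 1..choose(n,2) to pair (i, j), i < j, using the
# row-major enumeration (1,2),(1,3),...,(1,n),(2,3),...  Vectorized; used for
# uniform sampling over all unordered pairs without materializing them.
pair_from_index <- function(k, n) {
  stopifnot(all(k >= 1), all(k <= n * (n - 1) / 2))
  # cumulative pairs after row i: S(i) = i*n - i*(i+1)/2
  i <- ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * k))
  i <- pmax(i, 1L)
  S <- function(i) i * n - i * (i + 1) / 2
  # guard against floating-point boundary errors
  adj <- S(i - 1) >= k
  while (any(adj)) {
    i[adj] <- i[adj] - 1L
    adj <- S(i - 1) >= k
  }
  adj <- S(i) < k
  while (any(adj)) {
    i[adj] <- i[adj] + 1L
    adj <- S(i) < k
  }
  j <- k - S(i - 1) + i
  cbind(i = as.integer(i), j = as.integer(j))
}
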