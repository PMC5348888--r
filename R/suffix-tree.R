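#' Build the annotated suffix tree of a sequence
#'
#' Constructs the suffix tree of `x` over `x` plus a unique terminal sentinel,
#' then annotates every node with its word-depth `D(v)`, the number of
#' (sentinel-free) terminal nodes `C(v)` in its subtree -- which equals the
#' observed frequency of the node's path-label -- the smallest suffix index in
#' its subtree, and suffix links for internal nodes. Letters are rank-mapped
#' to an integer alphabet consisting of the distinct letters of `x` in their
#' natural (C-locale) order; case is preserved as given.
#'
#' @param x A single character string (the sequence). Any single-byte letters
#'   are accepted; the alphabet is whatever occurs in `x`.
#' @param id Optional identifier carried along for reporting.
#' @return An object of class `suffix_tree` with elements `x`, `id`, `n`,
#'   `alphabet` and `sigma`.
#' @examples
#' st <- suffix_tree("AGCGCGACGTCTGTGT")
#' occurrence_count(st, "GCG")
#' st_locate(st, "TCT")$explicit
#' @export
suffix_tree <- function(x, id = NULL) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("`x` must be a single character string", call. = FALSE)
  }
  if (nchar(x) == 0L) stop("empty sequence", call. = FALSE)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  alphabet <- sort(unique(chars), method = "radix")
  ranks <- match(chars, alphabet) - 1L
  ptr <- st_build_cpp(ranks, length(alphabet))
  structure(
    list(ptr = ptr, x = x, id = id, n = nchar(x),
         alphabet = alphabet, sigma = length(alphabet)),
    class = "suffix_tree"
  )
}

as_suffix_tree <- function(x, id = NULL) {
  if (inherits(x, "suffix_tree")) x else suffix_tree(x, id = id)
}

#' @export
print.suffix_tree <- function(x, ...) {
  s <- st_stats(x)
  cat(sprintf(
    "Annotated suffix tree%s: n = %d, sigma = %d, %d nodes (%d leaves)\n",
    if (is.null(x$id)) "" else paste0(" of '", x$id, "'"),
    s$n, s$sigma, s$n_nodes, s$n_leaves
  ))
  invisible(x)
}

rank_map <- function(st, w) {
  match(strsplit(w, "", fixed = TRUE)[[1L]], st$alphabet) - 1L
}

#' Locate a word in a suffix tree
#'
#' Descends from the root comparing edge letters left to right. The locus of
#' an occurring word is either an explicit node (the word equals the full
#' path-label) or an implicit position inside an edge; in both cases the
#' occurrence count of the word equals `C` of the explicit node at or
#' immediately below the position. Absence is a value (`found = FALSE`), not
#' an error.
#'
#' @param st A [suffix_tree()].
#' @param w A single non-empty word.
#' @return A list with `found`, and when found: `node` (internal id), `depth`
#'   (letters of `w`), `explicit`, `node_depth` (`D` of the explicit node),
#'   `count` (observed frequency of `w`) and `label_start` (0-based start of
#'   one occurrence of the node's label).
#' @export
st_locate <- function(st, w) {
  stopifnot(inherits(st, "suffix_tree"), is.character(w), length(w) == 1L)
  if (nchar(w) == 0L) stop("`w` must be non-empty", call. = FALSE)
  r <- rank_map(st, w)
  r[is.na(r)] <- -1L  # letters outside the alphabet never match
  st_locate_cpp(st$ptr, r)
}

#' Observed frequency of words in a sequence
#'
#' Number of possibly overlapping occurrences, read off the suffix tree in
#' time proportional to the word length. Words containing letters absent from
#' the alphabet have count 0.
#'
#' @param st A [suffix_tree()].
#' @param w Character vector of non-empty words.
#' @return Integer vector of counts.
#' @examples
#' occurrence_count(suffix_tree("TTT"), "TT")  # 2: overlaps are distinct
#' @export
occurrence_count <- function(st, w) {
  stopifnot(inherits(st, "suffix_tree"), is.character(w))
  if (any(nchar(w) == 0L)) stop("words must be non-empty", call. = FALSE)
  vapply(w, function(wi) {
    r <- rank_map(st, wi)
    r[is.na(r)] <- -1L
    st_count_cpp(st$ptr, r)
  }, integer(1L), USE.NAMES = FALSE)
}

#' Suffix link of an explicit internal node
#'
#' For the node path-labelled `w`, returns the node path-labelled `w` minus
#' its first letter. Defined only for explicit, internal, non-root nodes;
#' anything else is a contract violation.
#'
#' @param st A [suffix_tree()].
#' @param w The path-label of an explicit internal node.
#' @return A list with `node`, `depth`, `label` and `count` of the target.
#' @export
st_suffix_link <- function(st, w) {
  stopifnot(inherits(st, "suffix_tree"), is.character(w), length(w) == 1L)
  r <- rank_map(st, w)
  if (anyNA(r)) stop("word does not occur in the sequence", call. = FALSE)
  res <- st_slink_cpp(st$ptr, r)
  res$label <- if (res$depth > 0L) {
    substr(st$x, res$label_start + 1L, res$label_start + res$depth)
  } else ""
  res
}

#' Node table of a suffix tree
#'
#' One row per node with parent, word-depth (sentinel-free), subtree terminal
#' count, leaf flag, suffix index (leaves), suffix link (internal non-root
#' nodes) and edge coordinates. Mainly useful for inspection and for testing
#' structural invariants on small trees.
#'
#' @param st A [suffix_tree()].
#' @return A data frame with 0-based node ids.
#' @export
st_nodes <- function(st) {
  stopifnot(inherits(st, "suffix_tree"))
  st_nodes_cpp(st$ptr)
}

#' Summary statistics of a suffix tree
#'
#' Node, leaf and edge counts, plus the length of the longest repeated factor
#' of `x` (the greatest word-depth of an internal node). `essential_edges` is
#' the edge count of the tree with the sentinel stripped (sentinel-only leaf
#' edges removed and resulting unary nodes merged), which is bounded by
#' `2n - 1`.
#'
#' @param st A [suffix_tree()].
#' @return A list of counts.
#' @export
st_stats <- function(st) {
  stopifnot(inherits(st, "suffix_tree"))
  st_stats_cpp(st$ptr)
}
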