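#' Minimal absent words of a sequence
#'
#' A word `w` is a minimal absent word (MAW) of `x` when `w` is absent from
#' `x` but every proper factor of `w` occurs in `x`. Each MAW of length at
#' least 2 is returned in the tuple representation `<(i, j), alpha>` meaning
#' `w = x[i..j] alpha` with `x[i..j]` the longest proper prefix of `w`; this
#' representation is unique (the smallest witness occurrence is used for
#' `(i, j)`). Enumeration runs in `O(sigma n)` on the annotated suffix tree.
#'
#' Deviation statistics are only defined for words longer than 2 letters, so
#' the avoided-word routines consume the tuples with `length >= 3`; the
#' length-2 MAWs (absent letter pairs) are reported here for completeness.
#'
#' @param x A character string or a [suffix_tree()].
#' @param id Optional sequence identifier (ignored when `x` is already a tree).
#' @return A data frame with columns `word`, `length`, `i`, `j` (0-based,
#'   inclusive) and `alpha`, sorted by length, then `i`, then letter rank.
#' @examples
#' minimal_absent_words("baaab")$word  # "bb" "aba" "bab" "aaaa" "baab"
#' @export
minimal_absent_words <- function(x, id = NULL) {
  st <- as_suffix_tree(x, id)
  mw <- maw_cpp(st$ptr)
  word <- paste0(substring(st$x, mw$i + 1L, mw$j + 1L),
                 st$alphabet[mw$alpha + 1L])
  len <- mw$j - mw$i + 2L
  ord <- order(len, mw$i, mw$alpha, method = "radix")
  out <- data.frame(word = word[ord], length = len[ord], i = mw$i[ord],
                    j = mw$j[ord], alpha = st$alphabet[mw$alpha + 1L][ord],
                    stringsAsFactors = FALSE)
  attr(out, "n") <- st$n
  attr(out, "sigma") <- st$sigma
  out
}

#' Filter minimal absent words by length
#'
#' @param maws A data frame from [minimal_absent_words()].
#' @param k Word length, must exceed 2 (the tuple stream consumed by the
#'   avoided-word routines starts at length 3).
#' @return The rows with `length == k`.
#' @export
maws_of_length <- function(maws, k) {
  stopifnot(is.data.frame(maws), "length" %in% names(maws))
  if (!is.numeric(k) || length(k) != 1L || k <= 2) {
    stop("`k` must be a single integer greater than 2", call. = FALSE)
  }
  maws[maws$length == as.integer(k), , drop = FALSE]
}

#' Export minimal absent words as plain text
#'
#' One word per line, for interoperability with published MAW tools.
#'
#' @param maws A data frame from [minimal_absent_words()].
#' @param path Output file path.
#' @export
write_maws <- function(maws, path) {
  stopifnot(is.data.frame(maws), "word" %in% names(maws))
  writeLines(maws$word, path)
  invisible(path)
}
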