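# Self-complementarity utility: type-II restriction endonucleases target
# self-complementary (palindromic) sites, and such sites are strongly avoided
# in prokaryotic genomes. This summariser makes that analysis re-runnable on
# any avoided-word result computed from DNA.

#' Is a DNA word self-complementary (palindromic)?
#'
#' A DNA word is self-complementary when it equals its own reverse
#' complement; this requires an even length (a middle base cannot pair with
#' itself). Only `A`, `C`, `G`, `T` (either case) are accepted -- this
#' utility alone rejects ambiguity codes, which the core computation treats
#' as ordinary letters.
#'
#' @param w Character vector of DNA words.
#' @return Logical vector.
#' @examples
#' is_self_complementary(c("GAATTC", "AAAAAA", "GAT"))  # TRUE FALSE FALSE
#' @export
is_self_complementary <- function(w) {
  stopifnot(is.character(w))
  if (length(w) == 0L) return(logical(0))
  if (any(nchar(w) == 0L) || any(grepl("[^ACGTacgt]", w))) {
    stop("self-complementarity is defined for non-empty words over {A,C,G,T}",
         call. = FALSE)
  }
  up <- toupper(w)
  vapply(up, function(x) {
    if (nchar(x) %% 2L == 1L) return(FALSE)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    identical(rc, x)
  }, logical(1L), USE.NAMES = FALSE)
}

#' Summarise self-complementary words in an avoided-word result
#'
#' Counts computed on the deviation-sorted list: the total number of avoided
#' words, how many are self-complementary, and the fraction of
#' self-complementary words among the `top_m` most avoided ones.
#'
#' @param result An `avoided_words` data frame (DNA).
#' @param top_m How many of the most avoided words to inspect (clamped to the
#'   result size).
#' @return A list with `total`, `self_complementary`, `top_m`,
#'   `top_self_complementary` and `top_fraction` (`NA` on an empty result).
#' @export
summarize_self_complementarity <- function(result, top_m = 10L) {
  stopifnot(inherits(result, "avoided_words"))
  n <- nrow(result)
  if (n == 0L) {
    return(list(total = 0L, self_complementary = 0L, top_m = 0L,
                top_self_complementary = 0L, top_fraction = NA_real_))
  }
  sc <- is_self_complementary(result$word)
  m <- min(as.integer(top_m), n)
  top_sc <- sum(sc[seq_len(m)])
  list(total = n,
       self_complementary = sum(sc),
       top_m = m,
       top_self_complementary = top_sc,
       top_fraction = top_sc / m)
}
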