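# Synthetic-sequence generators: seeded uniform random sequences and the two
# extremal constructions that realise the Omega(sigma n) lower bounds on the
# number of minimal absent words (overall, and at fixed length 3).

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random sequence with i.i.d. uniform letters
#'
#' Letters are drawn independently and uniformly from `alphabet` using R's
#' default Mersenne-Twister stream; the same `(alphabet, n, seed)` always
#' yields the same sequence, and the global RNG state is left untouched when
#' a seed is supplied.
#'
#' @param n Sequence length (at least 1).
#' @param alphabet Character vector of single letters (default DNA).
#' @param seed Optional integer seed, recorded in the `seed` attribute.
#' @return A single character string with attributes `alphabet` and `seed`.
#' @examples
#' random_sequence(20, seed = 1)
#' @export
random_sequence <- function(n, alphabet = c("A", "C", "G", "T"), seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1,
            is.character(alphabet), length(alphabet) >= 1L,
            all(nchar(alphabet) == 1L))
  n <- as.integer(n)
  draws <- with_seed(seed, sample(alphabet, n, replace = TRUE))
  structure(paste(draws, collapse = ""), alphabet = alphabet, seed = seed)
}

#' Extremal sequence with Omega(sigma n) minimal absent words
#'
#' For `sigma == 2` the word `b a^(n-2) b`, in which every `b a^t b` with
#' `0 <= t <= n - 3` is minimal absent (at least `n - 2` MAWs). For
#' `sigma >= 3` the word `b a^t c a^t d a^t ... a^m` with
#' `t = floor(n / (sigma - 1)) - 1`, which has at least
#' `(sigma - 1)(sigma - 2) floor(n / (sigma - 1)) - (sigma - 2)` minimal
#' absent words. Letters are `a`, `b`, `c`, ... so `sigma <= 26`.
#'
#' @param sigma Alphabet size, `2 <= sigma <= n`.
#' @param n Sequence length.
#' @return A character string of length exactly `n`.
#' @examples
#' maw_dense_sequence(2, 10)  # "baaaaaaaab"
#' maw_dense_sequence(3, 7)   # "baacaaa"
#' @export
maw_dense_sequence <- function(sigma, n) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L,
            is.numeric(n), length(n) == 1L)
  sigma <- as.integer(sigma)
  n <- as.integer(n)
  if (sigma < 2L) stop("`sigma` must be at least 2", call. = FALSE)
  if (sigma > n) stop("`sigma` must not exceed `n`", call. = FALSE)
  if (sigma > 26L) stop("letter rendering supports sigma <= 26", call. = FALSE)
  ab <- letters[seq_len(sigma)]
  if (sigma == 2L) {
    return(paste0("b", strrep("a", n - 2L), "b"))
  }
  t <- n %/% (sigma - 1L) - 1L
  m <- n - (sigma - 1L) * (t + 1L)
  paste0(paste0(ab[2:sigma], strrep("a", t), collapse = ""), strrep("a", m))
}

#' Extremal sequence with Omega(sigma n) minimal absent words of length 3
#'
#' The concatenation of blocks `B_i = a_{i+1} a_i a_{i+2} a_i ... a_sigma a_i`
#' for `i = 1 .. sigma - 1`, of total length `sigma (sigma - 1)`; each block
#' has length `2 (sigma - i)`. Every prefix `y` with `|y| > 2 (sigma - 1)`
#' has at least `((sigma - 2)^2 - sigma) * floor(|y| / (2 sigma))` minimal
#' absent words of length 3.
#'
#' @param sigma Alphabet size, at least 3 (letters `a`, `b`, ..., so at most
#'   26).
#' @param n Optional prefix length, at most `sigma * (sigma - 1)`; the full
#'   word when `NULL`.
#' @return A character string.
#' @examples
#' maw_dense_triplet_sequence(4)  # "bacadacbdbdc"
#' @export
maw_dense_triplet_sequence <- function(sigma, n = NULL) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L)
  sigma <- as.integer(sigma)
  if (sigma < 3L) stop("`sigma` must be at least 3", call. = FALSE)
  if (sigma > 26L) stop("letter rendering supports sigma <= 26", call. = FALSE)
  ab <- letters[seq_len(sigma)]
  blocks <- vapply(seq_len(sigma - 1L), function(i) {
    paste0(ab[(i + 1L):sigma], ab[i], collapse = "")
  }, character(1L))
  x <- paste(blocks, collapse = "")
  full <- sigma * (sigma - 1L)
  if (is.null(n)) return(x)
  n <- as.integer(n)
  if (n < 1L || n > full) {
    stop(sprintf("`n` must be between 1 and sigma * (sigma - 1) = %d", full),
         call. = FALSE)
  }
  substr(x, 1L, n)
}
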