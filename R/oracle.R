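# Brute-force reference implementations. These deliberately share no code
# with the suffix tree, the minimal-absent-word enumeration or the avoided
# routines: they use sliding-window scans and explicit enumeration only, so
# agreement between the two routes is meaningful evidence of correctness.

#' Naive occurrence count
#'
#' Sliding-window count of possibly overlapping occurrences of `w` in `x`.
#'
#' @param x,w Character strings; `w` non-empty.
#' @return Integer count.
#' @examples
#' naive_count("TTT", "TT")  # 2
#' @export
naive_count <- function(x, w) {
  stopifnot(is.character(x), length(x) == 1L,
            is.character(w), length(w) == 1L)
  n <- nchar(x)
  m <- nchar(w)
  if (m == 0L) stop("`w` must be non-empty", call. = FALSE)
  if (m > n) return(0L)
  starts <- seq_len(n - m + 1L)
  sum(substring(x, starts, starts + m - 1L) == w)
}

# counts of every factor of x of a given length, as a named integer vector
factor_counts <- function(x, len) {
  n <- nchar(x)
  if (len < 1L || len > n) return(setNames(integer(0), character(0)))
  f <- substring(x, seq_len(n - len + 1L), seq(len, n))
  tab <- table(f)
  setNames(as.integer(tab), names(tab))
}

lookup0 <- function(tab, w) {
  idx <- match(w, names(tab))
  out <- as.integer(tab[idx])
  out[is.na(idx)] <- 0L
  out
}

#' Brute-force enumeration of avoided words of length k
#'
#' Considers every one of the `sigma^k` words over the distinct letters of
#' `x`, computes `f`, `f_p`, `f_s` and `f_i` by naive sliding-window counting,
#' then `E` and `dev`. When `rho` is given, only words with `dev <= rho` are
#' returned; otherwise the full deviation table is returned (useful for
#' checking several thresholds against one enumeration).
#'
#' @param x A character string.
#' @param k Word length, greater than 2.
#' @param rho Optional negative threshold.
#' @param max_enum Refuse enumerations larger than this many words (test
#'   guard; default one million).
#' @return A data frame with `word`, `status`, `f`, `E`, `dev`, sorted by
#'   `dev` then word.
#' @export
brute_force_avoided <- function(x, k, rho = NULL, max_enum = 1e6) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!is.numeric(k) || k <= 2) {
    stop("`k` must be a single integer greater than 2", call. = FALSE)
  }
  k <- as.integer(k)
  alph <- sort(unique(strsplit(x, "", fixed = TRUE)[[1L]]), method = "radix")
  if (length(alph)^k > max_enum) {
    stop("enumeration too large: sigma^k exceeds `max_enum`", call. = FALSE)
  }
  grid <- expand.grid(rep(list(alph), k), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  words <- do.call(paste0, grid)
  tk <- factor_counts(x, k)
  tp <- factor_counts(x, k - 1L)
  ti <- factor_counts(x, k - 2L)
  f <- lookup0(tk, words)
  f_p <- lookup0(tp, substr(words, 1L, k - 1L))
  f_s <- lookup0(tp, substr(words, 2L, k))
  f_i <- lookup0(ti, substr(words, 2L, k - 1L))
  E <- ifelse(f_i > 0L, as.double(f_p) * f_s / f_i, 0)
  dev <- (f - E) / pmax(sqrt(E), 1)
  out <- data.frame(word = words,
                    status = ifelse(f > 0L, "occurring", "absent"),
                    f = f, E = E, dev = dev,
                    f_p = f_p, f_s = f_s, f_i = f_i,
                    stringsAsFactors = FALSE)
  if (!is.null(rho)) out <- out[out$dev <= rho, , drop = FALSE]
  out <- out[order(out$dev, out$word, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Brute-force enumeration of minimal absent words
#'
#' Direct application of the definition: a word of length 2 to `max_len` over
#' the distinct letters of `x` is a minimal absent word when it is absent
#' while its two maximal proper factors (longest proper prefix and suffix)
#' occur -- every shorter proper factor is then a factor of one of those two.
#' Candidates are single-letter left extensions of occurring factors, so the
#' enumeration needs no `sigma^k` sweep.
#'
#' @param x A character string.
#' @param max_len Longest length to consider; at most `nchar(x) + 1` is ever
#'   productive.
#' @return Character vector of minimal absent words, sorted by length then
#'   lexicographically.
#' @examples
#' brute_force_maws("baaab", 6)  # bb, aba, bab, aaaa, baab
#' @export
brute_force_maws <- function(x, max_len) {
  stopifnot(is.character(x), length(x) == 1L, is.numeric(max_len))
  max_len <- as.integer(max_len)
  alph <- sort(unique(strsplit(x, "", fixed = TRUE)[[1L]]), method = "radix")
  out <- character(0)
  for (l in 2:max_len) {
    prev <- names(factor_counts(x, l - 1L))
    if (length(prev) == 0L) break
    cur <- names(factor_counts(x, l))
    cand <- as.vector(outer(alph, prev, paste0))
    keep <- !(cand %in% cur) & (substr(cand, 1L, l - 1L) %in% prev)
    out <- c(out, sort(cand[keep], method = "radix"))
  }
  out
}
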