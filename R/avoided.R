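#' Expected frequency of a word from its maximal proper factor counts
#'
#' `E(w) = f(w_p) * f(w_s) / f(w_i)` when the longest proper infix occurs,
#' else 0. The intuition: of the `f(w_i)` occurrences of the infix, a fraction
#' `f(w_p) / f(w_i)` is preceded by the first letter of `w` and a fraction
#' `f(w_s) / f(w_i)` is followed by its last letter; treating the two events
#' as independent gives the expected count of `w`. No independence correction
#' is applied -- the estimator is used verbatim.
#'
#' @param f_p,f_s,f_i Observed frequencies of the longest proper prefix,
#'   suffix and infix of `w`. Non-negative; vectors recycle.
#' @return `E(w)` as a double vector.
#' @examples
#' expected_frequency(3, 3, 6)  # 1.5
#' @export
expected_frequency <- function(f_p, f_s, f_i) {
  if (any(f_p < 0) || any(f_s < 0) || any(f_i < 0)) {
    stop("factor counts must be non-negative", call. = FALSE)
  }
  ifelse(f_i > 0, as.double(f_p) * f_s / f_i, 0)
}

#' Deviation of observed from expected frequency
#'
#' The chi-square-style standardized difference
#' `dev(w) = (f(w) - E(w)) / max(sqrt(E(w)), 1)`. A word is rho-avoided when
#' `dev(w) <= rho` for a chosen threshold `rho < 0`; the boundary case
#' `dev(w) == rho` counts as avoided.
#'
#' @param f Observed frequency (non-negative).
#' @param E Expected frequency (non-negative), e.g. from
#'   [expected_frequency()].
#' @return `dev(w)` as a double vector.
#' @examples
#' deviation(1, 1.5)  # -0.408248...
#' deviation(0, 0.5)  # -0.5
#' @export
deviation <- function(f, E) {
  if (any(f < 0) || any(E < 0)) {
    stop("frequencies must be non-negative", call. = FALSE)
  }
  (f - E) / pmax(sqrt(E), 1)
}

check_rho <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho >= 0) {
    stop("`rho` must be a single negative number", call. = FALSE)
  }
  as.double(rho)
}

# Shared driver for the fixed-length and all-lengths algorithms: enumerate
# minimal absent words, run the absent and occurring routines on the annotated
# tree, and assemble the deviation-ranked result set.
aw_compute <- function(st, k, all_lengths, rho) {
  mw <- maw_cpp(st$ptr)
  ab <- absent_avoided_cpp(st$ptr, mw$i, mw$j, mw$alpha,
                           if (all_lengths) 0L else k, all_lengths, rho)
  oc <- occurring_avoided_cpp(st$ptr, if (all_lengths) 0L else k,
                              all_lengths, rho)
  mk_words <- function(z) {
    if (length(z$start) == 0L) return(character(0))
    paste0(substring(st$x, z$start + 1L, z$start + z$plen),
           st$alphabet[z$alpha + 1L])
  }
  out <- data.frame(
    word = c(mk_words(ab), mk_words(oc)),
    length = c(ab$plen + 1L, oc$plen + 1L),
    status = rep(c("absent", "occurring"),
                 c(length(ab$start), length(oc$start))),
    f = c(rep(0L, length(ab$start)), oc$f),
    E = c(ab$E, oc$E),
    dev = c(ab$dev, oc$dev),
    f_p = c(ab$f_p, oc$f_p),
    f_s = c(ab$f_s, oc$f_s),
    f_i = c(ab$f_i, oc$f_i),
    stringsAsFactors = FALSE
  )
  # dev ascending; ties broken lexicographically on the rank-mapped word
  ord <- order(out$dev, out$word, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            id = st$id, n = st$n, sigma = st$sigma, rho = rho,
            k = if (all_lengths) NA_integer_ else as.integer(k),
            mode = if (all_lengths) "all-lengths" else "fixed-k",
            n_maws = sum(mw$j - mw$i + 2L >= 3L),
            n_candidates = ab$candidates + oc$candidates,
            class = c("avoided_words", "data.frame"))
}

#' Compute all rho-avoided words of a fixed length
#'
#' A word `w` of length `k > 2` is rho-avoided in `x` when
#' `dev(w) <= rho < 0`. Avoided words are either *occurring* -- then the
#' longest proper prefix of `w` labels an explicit internal node of the
#' suffix tree, so only the first-letter children of nodes at word-depth
#' `k - 1` need checking -- or *absent*, in which case `w` is necessarily a
#' minimal absent word. The two routines together examine at most
#' `(sigma + 1) n - k + 1` candidates and run in time linear in `n` for a
#' fixed alphabet.
#'
#' @param x A character string or a prebuilt [suffix_tree()].
#' @param k Word length, an integer greater than 2. A `k` exceeding `n + 1`
#'   yields an empty result (no word of that length occurs and no minimal
#'   absent word is that long), not an error.
#' @param rho Threshold, a single negative number. `dev(w) == rho` counts as
#'   avoided.
#' @param id Optional sequence identifier for reporting.
#' @return A data frame of class `avoided_words` with columns `word`,
#'   `length`, `status` (`occurring` or `absent`), `f`, `E`, `dev` and the
#'   exact integer factor counts `f_p`, `f_s`, `f_i` from which `E` is
#'   reproducible as a rational. Rows are sorted by `dev` ascending, ties
#'   broken lexicographically.
#' @examples
#' avoided_words("AGCGCGACGTCTGTGT", k = 3, rho = -0.4)
#' @export
avoided_words <- function(x, k, rho, id = NULL) {
  st <- as_suffix_tree(x, id)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 2 ||
      k != round(k)) {
    stop("`k` must be a single integer greater than 2", call. = FALSE)
  }
  rho <- check_rho(rho)
  aw_compute(st, as.integer(k), FALSE, rho)
}

#' Compute all rho-avoided words of every length
#'
#' Equivalent to the union of [avoided_words()] over every `k > 2`: the
#' absent route drops the length condition on the minimal absent word tuples,
#' and the occurring route checks the first-letter child of every explicit
#' internal node of word-depth at least 2 (at most `2n - 1` candidates, the
#' bound on the number of suffix tree edges). The longest reported word never
#' exceeds the longest repeated factor of `x` plus 2.
#'
#' @inheritParams avoided_words
#' @return A data frame of class `avoided_words`; see [avoided_words()].
#' @examples
#' all_avoided_words("AGCGCGACGTCTGTGT", rho = -0.4)
#' @export
all_avoided_words <- function(x, rho, id = NULL) {
  st <- as_suffix_tree(x, id)
  rho <- check_rho(rho)
  aw_compute(st, 0L, TRUE, rho)
}

#' @export
print.avoided_words <- function(x, ...) {
  k <- attr(x, "k")
  cat(sprintf("rho-avoided words (%s%s, rho = %g): %d word%s\n",
              attr(x, "mode"),
              if (is.na(k)) "" else paste0(", k = ", k),
              attr(x, "rho"), nrow(x), if (nrow(x) == 1L) "" else "s"))
  if (nrow(x) > 0L) {
    print.data.frame(x, digits = 7, row.names = FALSE)
  }
  invisible(x)
}
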