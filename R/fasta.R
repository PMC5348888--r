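# FASTA input/output and the tab-separated result format. Parsing goes
# through Biostrings; a light preliminary line scan produces the
# line-numbered diagnostics for malformed input that the parser itself does
# not report.

validate_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L) {
    stop(sprintf("empty FASTA file: '%s'", path), call. = FALSE)
  }
  is_header <- startsWith(trimws(lines), ">")
  first <- nonblank[1L]
  if (!is_header[first]) {
    stop(sprintf("malformed FASTA '%s': sequence data before any header at line %d",
                 path, first), call. = FALSE)
  }
  headers <- which(is_header)
  for (h in headers) {
    after <- nonblank[nonblank > h & !is_header[nonblank]]
    next_header <- headers[headers > h]
    limit <- if (length(next_header)) next_header[1L] else length(lines) + 1L
    if (!any(after < limit)) {
      stop(sprintf("malformed FASTA '%s': empty record for header at line %d",
                   path, h), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read sequences from a (Multi)FASTA file
#'
#' One entry per record; wrapped sequence lines are joined and the identifier
#' is the header text up to the first whitespace. Each record is processed
#' independently downstream. Malformed input (sequence before any header, or
#' an empty record) is an error reporting the offending line number.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("no such file: '%s'", path), call. = FALSE)
  }
  validate_fasta_lines(path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  setNames(as.character(set), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs))
  if (is.null(names(seqs))) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              width = width)
  invisible(path)
}

#' Write avoided-word results as a tab-separated file
#'
#' Plain text: comment lines recording the query (`k`, `rho`, mode, and the
#' generator seed when the input was synthetic), a column header, then one
#' row per avoided word with sequence id, word, status, `f`, `E` (6 decimal
#' places) and `dev` (6 decimal places), in each result's deviation order.
#' `dev` is compared against `rho` unrounded; rounding applies to the text
#' rendering only. The file is written atomically: on error nothing is left
#' behind at `path`.
#'
#' @param results A single `avoided_words` data frame or a list of them (one
#'   per input sequence).
#' @param path Output path, or `NULL` to write to standard output.
#' @param seed Optional generator seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_avoided_words <- function(results, path, seed = NULL) {
  if (inherits(results, "avoided_words")) results <- list(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1L), "avoided_words")))
  r1 <- results[[1L]]
  k <- attr(r1, "k")
  header <- c(
    sprintf("# mode=%s", attr(r1, "mode")),
    if (!is.na(k)) sprintf("# k=%d", k),
    sprintf("# rho=%g", attr(r1, "rho")),
    if (!is.null(seed)) sprintf("# seed=%d", as.integer(seed)),
    "sequence\tword\tstatus\tf\tE\tdev"
  )
  rows <- unlist(lapply(results, function(r) {
    if (nrow(r) == 0L) return(character(0))
    id <- attr(r, "id")
    if (is.null(id)) id <- "seq"
    sprintf("%s\t%s\t%s\t%d\t%.6f\t%.6f",
            id, r$word, r$status, r$f, r$E, r$dev)
  }), use.names = FALSE)
  lines <- c(header, rows)
  if (is.null(path)) {
    writeLines(lines)
    return(invisible(NULL))
  }
  tmp <- tempfile(tmpdir = dirname(path))
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
  }
  invisible(path)
}

#' Read back a tab-separated avoided-word file
#'
#' Inverse of [write_avoided_words()] up to the 6-decimal rounding of `E` and
#' `dev` in the text rendering.
#'
#' @param path Path written by [write_avoided_words()].
#' @return A data frame with columns `sequence`, `word`, `status`, `f`, `E`,
#'   `dev`.
#' @export
read_avoided_words <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  read.delim(text = paste(body, collapse = "\n"),
             stringsAsFactors = FALSE,
             colClasses = c("character", "character", "character",
                            "integer", "numeric", "numeric"))
}
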