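# Shared fixtures, all built in code.

# the worked 16-letter example sequence used throughout the documentation
EX <- "AGCGCGACGTCTGTGT"

# all words of length n over {a, b}
binary_words <- function(n) {
  if (n == 0L) return("")
  vapply(0:(2^n - 1L), function(v) {
    bits <- as.integer(intToBits(v))[seq_len(n)]
    paste(c("a", "b")[bits + 1L], collapse = "")
  }, character(1L))
}

# every distinct factor of x (all lengths), for count cross-checks
all_factors <- function(x) {
  n <- nchar(x)
  unique(unlist(lapply(seq_len(n), function(l) {
    substring(x, seq_len(n - l + 1L), seq(l, n))
  })))
}

expect_same_word_set <- function(got, want) {
  expect_setequal(got, want)
  expect_equal(anyDuplicated(got), 0L)
}

PROTEIN20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1L]]
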