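test_that("expected frequency and deviation implement the defining formulas", {
  expect_equal(expected_frequency(3, 3, 6), 1.5)
  expect_equal(expected_frequency(1, 3, 6), 0.5)
  expect_equal(expected_frequency(5, 7, 0), 0)  # absent infix
  expect_error(expected_frequency(-1, 3, 6), "non-negative")

  expect_equal(round(deviation(1, 1.5), 6), -0.408248)
  expect_equal(deviation(0, 0.5), -0.5)  # denominator clamps at 1
  expect_equal(deviation(2, 2), 0)
  expect_error(deviation(-1, 1), "non-negative")
})

test_that("the worked example reports its two avoided trinucleotides", {
  res <- avoided_words(EX, k = 3, rho = -0.4)
  expect_s3_class(res, "avoided_words")

  cgt <- res[res$word == "CGT", ]
  expect_equal(cgt$status, "occurring")
  expect_equal(cgt$f, 1L)
  expect_equal(cgt$E, 1.5)
  expect_equal(round(cgt$dev, 6), -0.408248)

  agt <- res[res$word == "AGT", ]
  expect_equal(agt$status, "absent")
  expect_equal(agt$f, 0L)
  expect_equal(agt$E, 0.5)
  expect_equal(agt$dev, -0.5)

  # ranked by deviation: AGT is more avoided than CGT
  expect_lt(which(res$word == "AGT"), which(res$word == "CGT"))
})

test_that("input contracts are enforced and boundary cases are values", {
  expect_error(avoided_words(EX, k = 2, rho = -0.4), "greater than 2")
  expect_error(avoided_words(EX, k = 3, rho = 0), "negative")
  expect_error(all_avoided_words(EX, rho = 0.5), "negative")
  # k beyond any possible word length: empty result, not an error
  expect_equal(nrow(avoided_words("ACGT", k = 10, rho = -0.1)), 0L)
  # dev == rho counts as avoided
  res <- avoided_words(EX, k = 3, rho = -0.5)
  expect_true("AGT" %in% res$word)
})

test_that("absent route: every minimal absent word is emitted when rho allows", {
  # for a minimal absent word E(w) >= 1/n, so dev <= -1/n: at rho = -1/n all
  # length >= 3 minimal absent words of this construction are avoided
  x <- maw_dense_sequence(2, 12)
  m <- minimal_absent_words(x)
  m3 <- m[m$length >= 3L, ]
  res <- avoided_words_all <- all_avoided_words(x, rho = -1 / 12)
  ab <- res[res$status == "absent", ]
  expect_same_word_set(ab$word, m3$word)

  # an absurdly low threshold excludes everything: |dev| <= sqrt(n)
  expect_equal(nrow(all_avoided_words(x, rho = -1e6)), 0L)
})

test_that("fixed-length results equal the brute-force oracle", {
  # exhaustive binary sweep (small here; the full sweep runs in acceptance)
  for (n in 3:7) {
    for (x in binary_words(n)) {
      st <- suffix_tree(x)
      for (k in 3:(n + 1L)) {
        tab <- brute_force_avoided(x, k)
        for (rho in c(-0.01, -0.5, -2)) {
          got <- avoided_words(st, k, rho)
          want <- tab[tab$dev <= rho, ]
          expect_same_word_set(got$word, want$word)
          if (nrow(got) > 0L) {
            o <- order(got$word)
            w <- order(want$word)
            expect_equal(got$dev[o], want$dev[w], tolerance = 1e-12)
            expect_equal(got$E[o], want$E[w], tolerance = 1e-12)
          }
        }
      }
    }
  }
  # random DNA
  x <- as.character(random_sequence(500, seed = 11))
  got <- avoided_words(x, 4, -0.1)
  want <- brute_force_avoided(x, 4, rho = -0.1)
  expect_same_word_set(got$word, want$word)
  expect_equal(got$word, want$word)  # same dev-then-word order
})

test_that("results are monotone in rho and deterministic", {
  x <- as.character(random_sequence(300, seed = 21))
  st <- suffix_tree(x)
  r1 <- avoided_words(st, 4, -1)
  r2 <- avoided_words(st, 4, -0.2)
  r3 <- avoided_words(st, 4, -0.01)
  expect_true(all(r1$word %in% r2$word))
  expect_true(all(r2$word %in% r3$word))
  expect_identical(avoided_words(x, 4, -0.2), r2)
})

test_that("all-lengths mode equals the union over k and obeys length bounds", {
  for (s in 1:10) {
    x <- as.character(random_sequence(100, seed = 400 + s))
    st <- suffix_tree(x)
    aw <- all_avoided_words(st, rho = -0.3)
    lrf <- st_stats(st)$longest_repeated_factor
    expect_lte(max(c(0L, aw$length)), lrf + 2L)
    un <- unlist(lapply(3:(lrf + 2L), function(k) {
      avoided_words(st, k, -0.3)$word
    }))
    expect_same_word_set(aw$word, un)
  }
  expect_true(all(c("CGT", "AGT") %in% all_avoided_words(EX, -0.4)$word))
})

test_that("emitted records satisfy the factor-count chain and size bounds", {
  for (s in 1:5) {
    x <- as.character(random_sequence(250, seed = 500 + s))
    n <- nchar(x)
    sigma <- length(unique(strsplit(x, "")[[1]]))
    for (k in 3:5) {
      res <- avoided_words(x, k, -0.05)
      expect_true(all(res$f <= res$f_p))
      expect_true(all(res$f <= res$f_s))
      expect_true(all(res$f_p <= res$f_i))
      expect_true(all(res$f_s <= res$f_i))
      expect_equal(res$E, res$f_p * res$f_s / res$f_i)
      expect_lte(nrow(res), (sigma + 1L) * n - k + 1L)
      expect_equal(anyDuplicated(res$word), 0L)
      # absent records are minimal absent words
      maws <- brute_force_maws(x, k)
      expect_true(all(res$word[res$status == "absent"] %in% maws))
    }
  }
})
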