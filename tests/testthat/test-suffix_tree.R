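test_that("worked example tree has the expected explicit and implicit loci", {
  st <- suffix_tree(EX)

  gcg <- st_locate(st, "GCG")
  expect_true(gcg$found)
  expect_true(gcg$explicit)
  expect_equal(gcg$node_depth, 3L)
  expect_equal(gcg$count, 2L)

  tct <- st_locate(st, "TCT")
  expect_true(tct$found)
  expect_false(tct$explicit)
  expect_equal(tct$count, 1L)

  expect_false(st_locate(st, "AGT")$found)

  # the whole word occurs exactly once, at a terminal position
  whole <- st_locate(st, EX)
  expect_true(whole$found)
  expect_equal(whole$count, 1L)
  expect_true(whole$explicit)

  nodes <- st_nodes(st)
  expect_equal(nodes$count[nodes$id == 0L], 16L)  # root: every suffix below
  leaf0 <- nodes[!is.na(nodes$suffix_index) & nodes$suffix_index == 0L, ]
  expect_equal(leaf0$depth, 16L)
  expect_equal(leaf0$count, 1L)
})

test_that("occurrence counts use overlapping occurrences", {
  expect_equal(occurrence_count(suffix_tree("TTT"), "TT"), 2L)
  expect_equal(occurrence_count(suffix_tree("A"), "A"), 1L)
  st <- suffix_tree(EX)
  expect_equal(occurrence_count(st, c("GCG", "AAA", "G")), c(2L, 0L, 6L))
})

test_that("counts agree with naive scanning for every factor, and are monotone", {
  words <- c(binary_words(6), binary_words(8),
             vapply(1:10, function(s) as.character(
               random_sequence(30, c("a", "b", "c", "d"), seed = s)),
               character(1L)))
  for (x in words) {
    st <- suffix_tree(x)
    for (f in all_factors(x)) {
      expect_identical(occurrence_count(st, f), naive_count(x, f))
      if (nchar(f) > 1L) {
        # every proper factor occurs at least as often
        expect_gte(naive_count(x, substr(f, 1L, nchar(f) - 1L)),
                   occurrence_count(st, f))
        expect_gte(naive_count(x, substr(f, 2L, nchar(f))),
                   occurrence_count(st, f))
      }
    }
    # some absent words
    expect_equal(occurrence_count(st, paste0(x, "z")), 0L)
  }
})

test_that("structural invariants: edge bound, branching counts, suffix links", {
  words <- c("TTT", EX, binary_words(7),
             vapply(1:8, function(s) as.character(
               random_sequence(80, seed = 50 + s)), character(1L)))
  for (x in words) {
    st <- suffix_tree(x)
    s <- st_stats(st)
    expect_lte(s$essential_edges, 2L * st$n - 1L)
    nodes <- st_nodes(st)
    internal <- nodes[!nodes$leaf & nodes$id != 0L, ]
    expect_true(all(internal$count >= 2L))
    # suffix link drops exactly one letter of depth
    expect_true(all(nodes$depth[match(internal$slink, nodes$id)] ==
                      internal$depth - 1L))
    # word-depth accumulates edge lengths
    child <- nodes[nodes$id != 0L & !nodes$sentinel_only, ]
    expect_true(all(child$depth ==
                      nodes$depth[match(child$parent, nodes$id)] +
                      child$edge_length))
    # a suffix-link chain reaches the root in exactly D(v) steps
    if (nrow(internal) > 0L) {
      v <- internal[which.max(internal$depth), ]
      steps <- 0L
      cur <- v$id
      while (cur != 0L) {
        cur <- nodes$slink[nodes$id == cur]
        steps <- steps + 1L
      }
      expect_equal(steps, v$depth)
    }
  }
})

test_that("suffix links resolve by path label and reject invalid nodes", {
  st <- suffix_tree(EX)
  sl <- st_suffix_link(st, "GCG")
  expect_equal(sl$label, "CG")
  expect_equal(sl$depth, 2L)
  # one-letter labels link to the root
  expect_equal(st_suffix_link(st, "C")$depth, 0L)
  # implicit loci and terminal nodes have no suffix link
  expect_error(st_suffix_link(st, "TCT"), "internal")
  expect_error(st_suffix_link(st, EX), "internal")
})

test_that("degenerate inputs are handled", {
  expect_error(suffix_tree(""), "empty")
  expect_error(st_locate(suffix_tree("A"), ""), "non-empty")
  st <- suffix_tree("A")
  expect_equal(occurrence_count(st, "AA"), 0L)
})
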