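quartet <- function() ape::unroot(ape::read.tree(text = "((A,B),(C,D));"))

test_that("Fitch scoring handles informative, constant and conflicting sites", {
  tr <- quartet()
  expect_equal(fitch_score(tr, aligned_matrix(LETTERS[1:4], c("a", "a", "t", "t"))), 1L)
  expect_equal(fitch_score(tr, aligned_matrix(LETTERS[1:4], rep("ccc", 4))), 0L)
  expect_equal(fitch_score(tr, aligned_matrix(LETTERS[1:4], c("a", "t", "a", "t"))), 2L)
  # gaps and N are missing data: never force a change
  expect_equal(fitch_score(tr, aligned_matrix(LETTERS[1:4], c("a", "-", "n", "t"))), 1L)
  expect_error(fitch_score(tr, aligned_matrix(c("A", "B", "C", "X"), rep("a", 4))),
               "do not match")
})

test_that("Fitch score is invariant to rooting and taxon order", {
  m <- random_alignment(LETTERS[1:6], 20, seed = 9)
  trees <- all_topologies(LETTERS[1:6])
  for (tr in trees[c(1, 40, 105)]) {
    s0 <- fitch_score(tr, m)
    for (og in c("A", "D", "F")) {
      rooted <- ape::root(tr, outgroup = og, resolve.root = TRUE)
      expect_equal(fitch_score(rooted, m), s0)
    }
  }
  # permuting matrix rows changes nothing
  m2 <- aligned_matrix(rev(m$taxa), rev(apply(m$chars, 1, paste, collapse = "")))
  expect_equal(fitch_score(trees[[40]], m2), fitch_score(trees[[40]], m))
})

test_that("Fitch equals the brute-force labelling minimum on small trees", {
  for (n in 4:5) {
    m <- random_alignment(LETTERS[1:n], 10, seed = 100 + n)
    for (tr in all_topologies(LETTERS[1:n])) {
      expect_equal(fitch_score(tr, m), brute_fitch(tr, m))
    }
  }
  # 6 taxa: seeded random topologies, including sites with gaps/ambiguity
  karyophy:::with_seed(77, {
    seqs <- vapply(LETTERS[1:6], function(t)
      paste(sample(c("a", "c", "g", "t", "-", "r"), 8, replace = TRUE,
                   prob = c(.22, .22, .22, .22, .06, .06)), collapse = ""),
      character(1))
    m6 <- aligned_matrix(LETTERS[1:6], seqs)
    topo <- all_topologies(LETTERS[1:6])
    picks <- sample(length(topo), 10)
    for (tr in topo[picks]) expect_equal(fitch_score(tr, m6), brute_fitch(tr, m6))
  })
})

test_that("Fitch agrees with an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  for (seed in 1:5) {
    m <- random_alignment(paste0("t", 1:7), 40, seed = seed)
    pd <- phangorn::phyDat(m$chars, type = "DNA")
    res <- heuristic_parsimony(m, n_starts = 2, seed = seed)
    for (tr in res$trees) {
      expect_equal(res$score, as.integer(phangorn::parsimony(tr, pd)))
    }
  }
})
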