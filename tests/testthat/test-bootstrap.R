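test_that("retention is inclusive at the threshold", {
  tab <- data.frame(split = c("a,b", "c,d", "e,f"),
                    support_count = c(700, 699, 1000),
                    support_percent = c(70.0, 69.9, 100.0))
  kept <- retain_bipartitions(tab, 70)
  expect_setequal(kept$split, c("a,b", "e,f"))
  # retained set shrinks monotonically as the threshold rises
  sizes <- vapply(c(0, 50, 69.9, 70, 99, 100, 101),
                  function(th) nrow(retain_bipartitions(tab, th)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[length(sizes)], 0)
})

test_that("a split supported by every column reaches 100 percent", {
  m <- aligned_matrix(c("A", "B", "C", "D", "E"),
                      c(strrep("a", 15), strrep("a", 15),
                        strrep("c", 15), strrep("c", 15), strrep("c", 15)))
  bs <- bootstrap_support(m, replicates = 50, seed = 2)
  expect_true("C,D,E" %in% bs$split)
  expect_equal(bs$support_percent[bs$split == "C,D,E"], 100)
  all_splits <- attr(bs, "all_splits")
  expect_true(all(all_splits$support_percent >= 0 & all_splits$support_percent <= 100))
})

test_that("bootstrap retains the true split of a long-internal-branch quintet", {
  t5 <- ape::read.tree(
    text = "((A:0.02,B:0.02):0.15,C:0.02,(D:0.02,E:0.02):0.15);")
  true_splits <- tree_splits(t5)
  for (seed in c(11, 23)) {
    al <- simulate_jc69_alignment(seq_sim_spec(t5, 300, seed = seed))
    bs <- bootstrap_support(al, replicates = 200, retention_percent = 70,
                            seed = seed)
    expect_true(all(true_splits %in% bs$split))
  }
})

test_that("outgroup rooting places the outgroup basally and annotates supports", {
  m <- random_alignment(c("out", "p", "q", "r", "s", "t"), 40, seed = 31)
  res <- heuristic_parsimony(m, n_starts = 2, seed = 3)
  tr <- res$trees[[1]]
  supports <- data.frame(split = tree_splits(tr),
                         support_percent = 85,
                         stringsAsFactors = FALSE)
  rooted <- annotate_and_root(tr, supports, outgroup = "out")
  expect_true(ape::is.rooted(rooted))
  # the outgroup is sister to everything else
  og_edge <- rooted$edge[rooted$edge[, 2] == which(rooted$tip.label == "out"), 1]
  expect_equal(og_edge, length(rooted$tip.label) + 1L)
  # every retained split's node carries its label
  expect_equal(sum(rooted$node.label == "85"), length(supports$split))
  # root, then unroot: the unrooted topology is unchanged
  expect_equal(karyophy:::topology_key(ape::unroot(rooted)),
               karyophy:::topology_key(tr))
  expect_error(annotate_and_root(tr, supports, outgroup = "absent"), "outgroup")
})

test_that("an empty retained table yields an unlabelled rooted tree", {
  m <- random_alignment(c("out", "x", "y", "z"), 20, seed = 8)
  res <- heuristic_parsimony(m, n_starts = 1, seed = 1)
  none <- data.frame(split = character(0), support_percent = numeric(0))
  rooted <- annotate_and_root(res$trees[[1]], none, outgroup = "out")
  expect_true(all(rooted$node.label == ""))
})
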