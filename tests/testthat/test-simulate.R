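test_that("the fixture carries the printed complement and its annotations", {
  fx <- table1_fixture()
  expect_equal(nrow(fx$measurements), 24L)
  expect_equal(length(unique(fx$measurements$pair_label)), 12L)
  sat <- fx$measurements[fx$measurements$has_satellite, ]
  expect_equal(unique(sat$pair_label), "P02")
  expect_equal(unique(sat$satellite_arm), "short")
  expect_equal(fx$expected_total, 70.57)
  expect_equal(fx$expected_formula, "2n = 2x = 24 = 2m + 2m(sat) + 2sm + 8st + 10t")
  expect_equal(fx$expected$full_length,
               sort(fx$expected$full_length, decreasing = TRUE))
})

test_that("metaphase simulation is exact at zero noise and deterministic", {
  truth <- fixture_truth()
  m0 <- simulate_metaphase(metaphase_sim_spec(truth, 1, 1, 0, seed = 3))
  expect_setequal(round(m0$short_arm, 6), round(truth$short_arm, 6))
  expect_setequal(round(m0$long_arm, 6), round(truth$long_arm, 6))
  expect_true(all(is.na(m0$pair_label)))   # labels withheld

  a <- simulate_metaphase(metaphase_sim_spec(truth, 2, 2, 0.02, seed = 17))
  b <- simulate_metaphase(metaphase_sim_spec(truth, 2, 2, 0.02, seed = 17))
  expect_equal(a, b)
  c <- simulate_metaphase(metaphase_sim_spec(truth, 2, 2, 0.02, seed = 18))
  expect_false(isTRUE(all.equal(a$short_arm, c$short_arm)))
})

test_that("sequence simulation reduces to identity at zero branch length", {
  tr <- recovery_tree6()
  tr0 <- tr
  tr0$edge.length[] <- 0
  al <- simulate_jc69_alignment(seq_sim_spec(tr0, 50, seed = 5))
  expect_true(all(apply(al$chars, 2, function(col) length(unique(col)) == 1L)))

  a <- simulate_jc69_alignment(seq_sim_spec(tr, 100, seed = 9))
  b <- simulate_jc69_alignment(seq_sim_spec(tr, 100, seed = 9))
  expect_equal(a$chars, b$chars)
})

test_that("pairwise identity matches the Jukes-Cantor closed form", {
  # two leaves at total distance d: P(same) = 1/4 + 3/4 exp(-4d/3)
  nsite <- 10000
  for (d in c(0.1, 0.75, 8)) {     # d = 8 probes the 1/4 saturation limit
    tr <- ape::read.tree(text = sprintf("(A:%f,B:%f,C:0.01);", d / 2, d / 2))
    al <- simulate_jc69_alignment(seq_sim_spec(tr, nsite, seed = round(100 * d)))
    p_same <- mean(al$chars["A", ] == al$chars["B", ])
    p_exp <- 0.25 + 0.75 * exp(-4 * d / 3)
    se <- sqrt(p_exp * (1 - p_exp) / nsite)
    expect_lt(abs(p_same - p_exp), 3 * se + 1e-12)
  }
})

test_that("derived stream seeds stay within 32-bit integer range and vary", {
  s <- vapply(0:2000, function(r) derive_seed(123456, r), integer(1))
  expect_true(all(s >= 0 & s < 2^31))
  expect_gt(length(unique(s)), 1990)
})
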