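test_that("the published fixture reproduces every derived column", {
  fx <- table1_fixture()
  k <- karyotype_from_measurements(fx$measurements)
  p <- k$pairs
  exp <- fx$expected

  expect_equal(nrow(p), 12L)
  expect_equal(p$full_length_mean, exp$full_length)
  expect_equal(range(p$full_length_mean), c(4.81, 8.49))
  expect_equal(p$arm_ratio, exp$arm_ratio)
  expect_equal(as.character(p$centromere_class), exp$centromere_class)
  expect_equal(k$total_haploid_length, 70.57, tolerance = 1e-9)
  expect_equal(format_formula(k), fx$expected_formula)
  expect_true(p$has_satellite[2] && !any(p$has_satellite[-2]))

  # relative lengths: exact except the three cells whose printed values
  # carry rounding provenance from unrounded raw means
  fuzzy <- c(2, 6, 12)
  expect_equal(p$relative_length[-fuzzy], exp$relative_length[-fuzzy])
  expect_true(all(abs(p$relative_length[fuzzy] - exp$relative_length[fuzzy]) <= 0.015))
})

test_that("pair summaries average per chromosome and respect rank ordering", {
  # one cell, two identical pairs of distinct sizes: zero sds, clean ranks
  m <- arm_measurements("i", "c", short_arm = c(2, 2, 1, 1),
                        long_arm = c(4, 4, 2, 2),
                        pair_label = c("a", "a", "b", "b"))
  s <- summarize_pairs(pair_homologs(m))
  expect_equal(s$rank, 1:2)
  expect_equal(s$full_length_mean, c(6, 3))
  expect_equal(s$short_arm_sd, c(0, 0))
  expect_equal(s$n_cells, c(1L, 1L))

  # inconsistent pair counts across cells are refused
  m2 <- rbind(m, arm_measurements("i", "c2", short_arm = c(2, 2),
                                  long_arm = c(4, 4), pair_label = c("a", "a")))
  expect_error(summarize_pairs(pair_homologs(m2)), "inconsistent pair counts")
})

test_that("pair averaging equals direct averaging of labelled replicate cells", {
  truth <- fixture_truth()
  cv <- 0.02
  nrep <- 18L  # 3 individuals x 3 cells x 2 homologs
  m <- karyophy:::with_seed(424, {
    rows <- expand.grid(ind = 1:3, cell = 1:3, pair = 1:12, hom = 1:2)
    arm_measurements(
      individual_id = paste0("I", rows$ind),
      cell_id = paste0("C", rows$cell),
      short_arm = truth$short_arm[rows$pair] * (1 + stats::rnorm(nrow(rows), 0, cv)),
      long_arm = truth$long_arm[rows$pair] * (1 + stats::rnorm(nrow(rows), 0, cv)),
      pair_label = sprintf("P%02d", rows$pair))
  })
  s <- summarize_pairs(pair_homologs(m))
  # oracle: direct per-label averaging of the same records
  oracle_s <- tapply(m$short_arm, m$pair_label, mean)
  oracle_l <- tapply(m$long_arm, m$pair_label, mean)
  oracle_f <- tapply(m$short_arm + m$long_arm, m$pair_label, mean)
  # match each summary row to its label via the full-length oracle
  for (i in seq_len(nrow(s))) {
    lab <- names(oracle_f)[which.min(abs(oracle_f - s$full_length_mean[i]))]
    expect_equal(s$short_arm_mean[i], unname(oracle_s[lab]), tolerance = 1e-12)
    expect_equal(s$long_arm_mean[i], unname(oracle_l[lab]), tolerance = 1e-12)
    expect_equal(s$full_length_mean[i], unname(oracle_f[lab]), tolerance = 1e-12)
    # and the averages sit near the simulation truth
    p <- as.integer(sub("P", "", lab))
    expect_lt(abs(s$short_arm_mean[i] - truth$short_arm[p]),
              4 * truth$short_arm[p] * cv / sqrt(nrep))
    expect_lt(abs(s$long_arm_mean[i] - truth$long_arm[p]),
              4 * truth$long_arm[p] * cv / sqrt(nrep))
  }
})

test_that("pair summaries are invariant to record and cell permutation", {
  truth <- fixture_truth()
  m <- simulate_metaphase(metaphase_sim_spec(truth, 2, 2, 0.02, seed = 7))
  s1 <- summarize_pairs(pair_homologs(m))
  perm <- karyophy:::with_seed(11, sample(nrow(m)))
  m2 <- m[perm, , drop = FALSE]
  rownames(m2) <- NULL
  s2 <- summarize_pairs(pair_homologs(m2))
  expect_equal(s1$short_arm_mean, s2$short_arm_mean, tolerance = 1e-12)
  expect_equal(s1$full_length_mean, s2$full_length_mean, tolerance = 1e-12)
})

test_that("arm ratios follow the published L/S convention", {
  expect_equal(arm_ratio(4.82, 3.68), 1.31)
  expect_equal(arm_ratio(4.40, 0.42), 10.48)
  expect_equal(arm_ratio(2, 2), 1.00)
  expect_equal(arm_ratio(4.56, 3.20), 1.43)   # 1.425 rounds half-up
  expect_error(arm_ratio(4, 0), "positive")
})

test_that("centromere classification matches the class bounds and is monotone", {
  expect_equal(as.character(classify_centromere(c(1.43, 2.10, 7.16, 3.81))),
               c("m", "sm", "t", "st"))
  # boundary closure by rounding-first semantics
  expect_equal(as.character(classify_centromere(c(1.70, 1.705, 1.71))),
               c("m", "sm", "sm"))
  expect_equal(as.character(classify_centromere(c(7.00, 7.004, 7.01))),
               c("st", "st", "t"))
  expect_error(classify_centromere(0.8), "orientation")

  ratios <- sort(karyophy:::with_seed(3, stats::runif(200, 1, 12)))
  cls <- classify_centromere(ratios)
  expect_true(!is.unsorted(cls))   # ordered factor: m < sm < st < t
})

test_that("relative lengths normalise to 100 within rounding", {
  expect_equal(relative_lengths(5), 100)
  for (seed in 1:20) {
    fl <- karyophy:::with_seed(seed, stats::runif(sample(2:15, 1), 1, 12))
    rl <- relative_lengths(fl)
    expect_true(abs(sum(rl) - 100) <= 0.1)
  }
  expect_error(relative_lengths(numeric(0)), "no pairs")
})

test_that("karyotype assembly counts satellited pairs in their class", {
  fx <- table1_fixture()
  k <- karyotype_from_measurements(fx$measurements)
  expect_equal(k$two_n, 24L)
  expect_equal(unname(k$formula$base_counts),  c(2L, 2L, 8L, 10L))
  expect_equal(unname(k$formula$satellite_counts), c(2L, 0L, 0L, 0L))

  # same measurements without the satellite: both m pairs become base
  m2 <- fx$measurements
  m2$has_satellite <- FALSE
  m2$satellite_arm <- "none"
  k2 <- karyotype_from_measurements(m2)
  expect_equal(unname(k2$formula$base_counts), c(4L, 2L, 8L, 10L))
  expect_equal(sum(k2$formula$satellite_counts), 0L)

  # a single metacentric pair
  m1 <- arm_measurements("i", "c", short_arm = c(2, 2), long_arm = c(2.1, 2.1),
                         pair_label = c("a", "a"))
  k1 <- assemble_karyotype(summarize_pairs(pair_homologs(m1)))
  expect_equal(k1$two_n, 2L)
  expect_equal(format_formula(k1), "2n = 2x = 2 = 2m")

  s <- summarize_pairs(pair_homologs(m1))
  s2 <- rbind(s, s)
  expect_error(assemble_karyotype(s2), "duplicate")
})
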