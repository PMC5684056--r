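test_that("canonicalization keeps, swaps or rejects arm records appropriately", {
  m <- arm_measurements("i", "c", short_arm = 3.68, long_arm = 4.82)
  expect_silent(out <- canonicalize_measurements(m))
  expect_equal(out$short_arm, 3.68)
  expect_equal(out$long_arm, 4.82)

  rev <- arm_measurements("i", "c", short_arm = 4.82, long_arm = 3.68,
                          has_satellite = TRUE, satellite_arm = "short")
  expect_warning(out <- canonicalize_measurements(rev), "swapped")
  expect_equal(out$short_arm, 3.68)
  expect_equal(out$long_arm, 4.82)
  expect_equal(out$satellite_arm, "long")   # annotation follows the arm

  expect_error(arm_measurements("i", "c", short_arm = 0, long_arm = 4),
               "non-positive arm length")
  expect_error(arm_measurements("i", "c", short_arm = 2, long_arm = 4,
                                has_satellite = TRUE, satellite_arm = "none"),
               "disagree")
})

test_that("measured full length must agree with the arm sum within rounding", {
  expect_silent(arm_measurements("i", "c", 0.56, 4.39, full_length = 4.96))
  expect_error(arm_measurements("i", "c", 0.56, 4.39, full_length = 5.4),
               "inconsistent")
})

test_that("labelled pairing groups by label and checks group sizes", {
  idx <- rep(1:12, each = 2)
  m <- arm_measurements("i", "c", short_arm = idx, long_arm = idx * 2,
                        pair_label = sprintf("P%02d", idx))
  p <- pair_homologs(m)
  expect_equal(length(unique(p$pair_id)), 12L)
  expect_true(all(table(p$pair_id) == 2L))
  # longest pair gets rank 1
  expect_equal(unique(p$pair_rank[p$pair_label == "P12"]), 1L)

  m$pair_label[1] <- "P12"
  expect_error(pair_homologs(m), "exactly twice")
})

test_that("unlabelled rank pairing joins consecutive size ranks and rejects odd counts", {
  m <- arm_measurements("i", "c", short_arm = c(4, 3.9, 2, 1.9),
                        long_arm = c(6, 5.9, 4, 4))
  p <- pair_homologs(m, method = "rank")
  fl <- p$short_arm + p$long_arm
  expect_equal(sort(tapply(fl, p$pair_id, paste, collapse = "+")),
               sort(c("10+9.8", "6+5.9")), ignore_attr = TRUE)

  odd <- arm_measurements("i", "c", short_arm = rep(1, 23), long_arm = rep(2, 23))
  expect_error(pair_homologs(odd), "even count")
})

test_that("arm-geometry pairing separates equal-length chromosomes with different ratios", {
  # two pairs with identical full length 6 but opposite centromere position
  m <- arm_measurements("i", "c",
                        short_arm = c(2.95, 3.05, 0.55, 0.45),
                        long_arm  = c(3.05, 2.95, 5.45, 5.55))
  p <- pair_homologs(m, method = "arms")
  grp <- split(p$short_arm, p$pair_id)
  spans <- vapply(grp, function(s) abs(diff(s)), numeric(1))
  expect_true(all(spans < 0.2))   # metacentrics together, telocentrics together
})

test_that("measurement CSV round-trips through read and write", {
  fx <- table1_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(fx$measurements, path)
  back <- read_measurements(path)
  expect_equal(back$short_arm, fx$measurements$short_arm)
  expect_equal(back$full_length, fx$measurements$full_length)
  expect_equal(back$has_satellite, fx$measurements$has_satellite)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("individual_id,cell_id,short_arm_um,long_arm_um", empty)
  expect_error(read_measurements(empty), "no records")
})
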