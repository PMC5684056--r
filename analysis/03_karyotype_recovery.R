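#!/usr/bin/env Rscript

# Stage 3 — can the karyotype be recovered from noisy replicate slides?
#
# Simulates the measurement survey: 3 individuals x 3 metaphase cells,
# each chromosome's arms measured with 2% multiplicative noise, records
# shuffled and unlabelled so homolog pairing has to be inferred. Per
# seed, the full pipeline runs and the recovered formula is compared to
# the truth.
#
# Finding (seeds 1-100): the published formula is recovered in 99/100
# replicates with morphology-aware pairing; the size-rank pairing rule
# fails almost always because neighbouring pairs differ by less than the
# measurement noise in total length while differing strongly in arm
# ratio.

suppressPackageStartupMessages(library(karyophy))

dir.create("results", showWarnings = FALSE)

fx <- table1_fixture()
truth <- data.frame(short_arm = fx$expected$short_arm,
                    long_arm = fx$expected$long_arm,
                    has_satellite = fx$expected$has_satellite)

run <- function(seed, method) {
  m <- simulate_metaphase(metaphase_sim_spec(truth, 3, 3, 0.02, seed = seed))
  paired <- pair_homologs(canonicalize_measurements(m), method = method)
  k <- assemble_karyotype(summarize_pairs(paired, match = method))
  format_formula(k)
}

seeds <- 1:100
res <- data.frame(
  seed = seeds,
  formula_arms = vapply(seeds, run, character(1), method = "arms"),
  formula_rank = vapply(seeds, run, character(1), method = "rank"))
res$arms_ok <- res$formula_arms == fx$expected_formula
res$rank_ok <- res$formula_rank == fx$expected_formula

write.table(res, "results/karyotype_recovery.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("formula recovery, arm-geometry pairing: %d/%d seeds\n",
            sum(res$arms_ok), length(seeds)))
cat(sprintf("formula recovery, size-rank pairing:    %d/%d seeds\n",
            sum(res$rank_ok), length(seeds)))
cat("wrote results/karyotype_recovery.tsv\n")
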