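# Independent oracles and generators shared across the test files.

# Brute-force Fitch oracle: minimum over all internal-node state
# assignments of the number of edges whose endpoint states differ (a tip
# matches when the internal state lies in its observed IUPAC set).
# Exponential in internal nodes; for use on small trees only.
brute_fitch <- function(tree, matrix) {
  enc <- karyophy:::encode_alignment(matrix)
  po <- ape::reorder.phylo(tree, "postorder")
  n <- length(po$tip.label)
  E <- po$edge
  internals <- sort(unique(E[, 1]))
  bits <- c(1L, 2L, 4L, 8L)
  asg <- as.matrix(expand.grid(rep(list(bits), length(internals))))
  colnames(asg) <- as.character(internals)
  enc <- enc[po$tip.label, , drop = FALSE]
  total <- 0L
  for (site in seq_len(ncol(enc))) {
    cost <- integer(nrow(asg))
    for (j in seq_len(nrow(E))) {
      p <- as.character(E[j, 1]); ch <- E[j, 2]
      cost <- cost + if (ch <= n) {
        as.integer(bitwAnd(asg[, p], enc[ch, site]) == 0L)
      } else {
        as.integer(asg[, p] != asg[, as.character(ch)])
      }
    }
    total <- total + min(cost)
  }
  total
}

# Uniform random nucleotide alignment.
random_alignment <- function(taxa, nsites, seed) {
  karyophy:::with_seed(seed, {
    seqs <- vapply(taxa, function(t)
      paste(sample(c("a", "c", "g", "t"), nsites, replace = TRUE), collapse = ""),
      character(1))
    aligned_matrix(taxa, seqs)
  })
}

# Random valid karyotype formula counts summing to 2n.
random_formula_counts <- function(seed) {
  karyophy:::with_seed(seed, {
    classes <- c("m", "sm", "st", "t")
    npairs <- sample(1:15, 1)
    base <- sat <- stats::setNames(integer(4), classes)
    for (i in seq_len(npairs)) {
      cc <- sample(classes, 1)
      if (stats::runif(1) < 0.2) sat[cc] <- sat[cc] + 2L else base[cc] <- base[cc] + 2L
    }
    karyotype_formula_counts(base, sat, b_chromosomes = sample(0:2, 1) * 2L,
                             two_n = 2L * npairs,
                             ploidy_x = sample(c(NA_integer_, 2L), 1))
  })
}

# The study's complement as simulation truth.
fixture_truth <- function() {
  fx <- table1_fixture()
  data.frame(short_arm = fx$expected$short_arm,
             long_arm = fx$expected$long_arm,
             has_satellite = fx$expected$has_satellite)
}

# Balanced 6-taxon tree with an internal branch 5x the terminal lengths.
recovery_tree6 <- function() {
  ape::read.tree(
    text = "((A:0.02,B:0.02):0.10,(C:0.02,D:0.02):0.10,(E:0.02,F:0.02):0.10);")
}
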