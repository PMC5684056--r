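# Synthetic data: the published measurement fixture, noisy metaphase
# simulation, and Jukes-Cantor sequence evolution on a known tree.

#' Published chromosome-measurement fixture
#'
#' The twelve homolog-pair mean arm lengths of the Taiwanese Lilium
#' callosum complement, with the satellite (secondary constriction) on the
#' short arm of pair 2, expressed as a single pseudo-cell of 24 labelled
#' measurements (the study's raw per-cell measurements are unpublished, so
#' the printed means stand in for one cell). Alongside the measurements
#' the published derived columns are returned for assertion: full lengths,
#' relative lengths, arm ratios, centromere classes, the formula string
#' and the 70.57 µm haploid total.
#'
#' @return List with `measurements` (an [arm_measurements()] table),
#'   `expected` (data.frame of the printed per-pair columns),
#'   `expected_formula` and `expected_total`.
#' @export
table1_fixture <- function() {
  short <- c(3.68, 3.20, 0.77, 0.60, 1.86, 0.52, 0.76, 0.93, 0.95, 0.56, 1.01, 0.42)
  long  <- c(4.82, 4.56, 5.51, 5.42, 3.90, 5.09, 4.71, 4.45, 4.25, 4.39, 3.85, 4.40)
  sat <- seq_along(short) == 2L
  expected <- data.frame(
    rank = 1:12,
    short_arm = short,
    short_arm_sd = c(0.16, 0.19, 0.06, 0.12, 0.16, 0.10, 0.07, 0.14, 0.13, 0.09, 0.21, 0.06),
    long_arm = long,
    long_arm_sd = c(0.29, 0.09, 0.07, 0.08, 0.26, 0.29, 0.18, 0.07, 0.22, 0.26, 0.25, 0.24),
    full_length = c(8.49, 7.76, 6.28, 6.01, 5.75, 5.60, 5.47, 5.38, 5.20, 4.96, 4.86, 4.81),
    full_length_sd = c(0.43, 0.28, 0.10, 0.17, 0.35, 0.28, 0.11, 0.08, 0.08, 0.18, 0.33, 0.29),
    relative_length = c(12.03, 10.99, 8.90, 8.52, 8.15, 7.93, 7.75, 7.62, 7.37, 7.03, 6.89, 6.81),
    arm_ratio = c(1.31, 1.43, 7.16, 9.03, 2.10, 9.79, 6.20, 4.78, 4.47, 7.84, 3.81, 10.48),
    centromere_class = c("m", "m", "t", "t", "sm", "t", "st", "st", "st", "t", "st", "t"),
    has_satellite = sat,
    stringsAsFactors = FALSE
  )
  idx <- rep(1:12, each = 2L)
  meas <- arm_measurements(
    individual_id = "T1",
    cell_id = "C1",
    short_arm = short[idx],
    long_arm = long[idx],
    full_length = expected$full_length[idx],
    pair_label = sprintf("P%02d", idx),
    has_satellite = sat[idx],
    satellite_arm = ifelse(sat[idx], "short", "none")
  )
  list(measurements = meas,
       expected = expected,
       expected_formula = "2n = 2x = 24 = 2m + 2m(sat) + 2sm + 8st + 10t",
       expected_total = 70.57)
}

#' Metaphase simulation specification
#'
#' @param true_pairs Data frame with columns `short_arm`, `long_arm` (µm)
#'   and `has_satellite` — the true homolog-pair geometry.
#' @param n_individuals Number of plants sampled (default 3, matching a
#'   typical root-tip survey).
#' @param n_cells_per_individual Metaphase cells scored per plant.
#' @param arm_noise_cv Coefficient of variation of the multiplicative
#'   measurement noise on each arm, in `[0, 0.5)`. Multiplicative noise
#'   keeps short arms (down to 0.42 µm here) positive at realistic error
#'   levels where additive noise would not.
#' @param seed Simulation seed.
#' @return An object of class `metaphase_sim_spec`.
#' @export
metaphase_sim_spec <- function(true_pairs, n_individuals = 3L,
                               n_cells_per_individual = 1L,
                               arm_noise_cv = 0.02, seed = 1L) {
  stopifnot(is.data.frame(true_pairs),
            all(c("short_arm", "long_arm") %in% names(true_pairs)))
  if (!"has_satellite" %in% names(true_pairs)) true_pairs$has_satellite <- FALSE
  if (any(true_pairs$short_arm <= 0 | true_pairs$long_arm <= 0))
    abort_validation("true arm lengths must be positive")
  if (arm_noise_cv < 0 || arm_noise_cv >= 0.5)
    abort_validation("arm_noise_cv must lie in [0, 0.5)")
  structure(list(true_pairs = true_pairs,
                 n_individuals = as.integer(n_individuals),
                 n_cells_per_individual = as.integer(n_cells_per_individual),
                 arm_noise_cv = arm_noise_cv, seed = as.integer(seed)),
            class = "metaphase_sim_spec")
}

#' Simulate replicate metaphase measurements
#'
#' For every individual, cell and homolog pair, two chromosome records are
#' drawn with each arm equal to truth x (1 + Normal(0, cv)), redrawn in
#' the (practically never triggered) event of a non-positive value.
#' Records are emitted in shuffled order with pair labels withheld, so the
#' pipeline's auto-pairing is exercised. Deterministic given the spec's
#' seed.
#'
#' @param spec A [metaphase_sim_spec()].
#' @return An [arm_measurements()] table.
#' @export
simulate_metaphase <- function(spec) {
  stopifnot(inherits(spec, "metaphase_sim_spec"))
  tp <- spec$true_pairs
  with_seed(spec$seed, {
    rows <- list()
    for (ind in seq_len(spec$n_individuals)) {
      for (cell in seq_len(spec$n_cells_per_individual)) {
        for (p in seq_len(nrow(tp))) {
          for (h in 1:2) {
            noisy <- function(mu) {
              repeat {
                v <- mu * (1 + stats::rnorm(1, 0, spec$arm_noise_cv))
                if (v > 0) return(v)
              }
            }
            rows[[length(rows) + 1L]] <- data.frame(
              individual_id = sprintf("I%d", ind),
              cell_id = sprintf("C%d", cell),
              short_arm = noisy(tp$short_arm[p]),
              long_arm = noisy(tp$long_arm[p]),
              has_satellite = tp$has_satellite[p])
          }
        }
      }
    }
    df <- do.call(rbind, rows)
    df <- df[sample.int(nrow(df)), , drop = FALSE]
    arm_measurements(df$individual_id, df$cell_id, df$short_arm, df$long_arm,
                     pair_label = NA_character_,
                     has_satellite = df$has_satellite,
                     satellite_arm = ifelse(df$has_satellite, "short", "none"))
  })
}

#' Sequence simulation specification
#'
#' @param tree A `phylo` with branch lengths in expected substitutions
#'   per site (all >= 0).
#' @param length Number of sites (>= 1).
#' @param seed Simulation seed.
#' @return An object of class `seq_sim_spec`.
#' @export
seq_sim_spec <- function(tree, length, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    abort_validation("tree must carry non-negative branch lengths")
  if (length < 1L) abort_validation("alignment length must be >= 1")
  structure(list(tree = tree, length = as.integer(length),
                 seed = as.integer(seed)),
            class = "seq_sim_spec")
}

#' Simulate a Jukes-Cantor alignment on a tree
#'
#' Sites evolve i.i.d.: the root state is uniform on {A,C,G,T}; along a
#' branch of length b (expected substitutions/site) a site changes with
#' probability (3/4)(1 - exp(-4b/3)) to one of the three other states,
#' uniformly. Equal rates and no indels — the simplest model sufficient
#' to test parsimony topology recovery. Deterministic given the seed.
#'
#' @param spec A [seq_sim_spec()].
#' @return An [aligned_matrix()] over the tree's tip labels.
#' @export
simulate_jc69_alignment <- function(spec) {
  stopifnot(inherits(spec, "seq_sim_spec"))
  tr <- ape::reorder.phylo(spec$tree, "postorder")
  n <- length(tr$tip.label)
  nn <- n + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  bases <- c("a", "c", "g", "t")
  with_seed(spec$seed, {
    states <- matrix(NA_integer_, nn, spec$length)
    states[root, ] <- sample.int(4L, spec$length, replace = TRUE)
    # preorder = reversed postorder edge list
    for (j in rev(seq_len(nrow(tr$edge)))) {
      p <- tr$edge[j, 1]; ch <- tr$edge[j, 2]
      b <- tr$edge.length[j]
      pchange <- 0.75 * (1 - exp(-4 * b / 3))
      s <- states[p, ]
      flip <- stats::runif(spec$length) < pchange
      if (any(flip)) {
        # uniform among the three other states
        shift <- sample.int(3L, sum(flip), replace = TRUE)
        s[flip] <- ((s[flip] - 1L + shift) %% 4L) + 1L
      }
      states[ch, ] <- s
    }
    seqs <- apply(states[seq_len(n), , drop = FALSE], 1, function(z)
      paste(bases[z], collapse = ""))
    aligned_matrix(tr$tip.label, seqs)
  })
}
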