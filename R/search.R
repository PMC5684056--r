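# Maximum-parsimony tree search: exhaustive enumeration for small taxon
# sets (the oracle) and random-addition stepwise insertion with
# nearest-neighbour-interchange hill climbing (the workhorse).

#' Exhaustive parsimony search
#'
#' Scores every unrooted binary topology — (2n-5)!! of them — and returns
#' the minimum and all trees attaining it. The guaranteed optimum against
#' which the heuristic is validated; refused above 8 taxa.
#'
#' @param matrix An [aligned_matrix()] with 3 to 8 taxa.
#' @param site_weights Optional per-site weights.
#' @return List with `score` and `trees` (all optima).
#' @export
exhaustive_parsimony <- function(matrix, site_weights = NULL) {
  n <- length(matrix$taxa)
  if (n > 8L)
    abort_validation("exhaustive search limited to 8 taxa; use heuristic_parsimony")
  enc <- encode_alignment(matrix)
  trees <- all_topologies(matrix$taxa)
  scores <- vapply(trees, fitch_score_enc, numeric(1), enc = enc,
                   site_weights = site_weights)
  best <- min(scores)
  list(score = best, trees = trees[scores == best])
}

# Deterministic stepwise addition in the given taxon order: each next
# taxon is inserted on the edge minimising the Fitch score (first minimum
# on ties).
stepwise_addition <- function(taxa_in_order, enc, site_weights = NULL) {
  tr <- star_tree(taxa_in_order[1:3])
  for (k in seq_along(taxa_in_order)[-(1:3)]) {
    cands <- lapply(seq_len(nrow(tr$edge)), insert_tip, tr = tr,
                    label = taxa_in_order[k])
    scores <- vapply(cands, fitch_score_enc, numeric(1), enc = enc,
                     site_weights = site_weights)
    tr <- cands[[which.min(scores)]]
  }
  tr
}

# NNI hill climbing to a local optimum; accepts the first strictly
# improving neighbour each round, so the trajectory is deterministic.
nni_hill_climb <- function(tr, enc, site_weights = NULL) {
  score <- fitch_score_enc(tr, enc, site_weights)
  repeat {
    nb <- nni_neighbors(tr)
    scores <- vapply(nb, fitch_score_enc, numeric(1), enc = enc,
                     site_weights = site_weights)
    if (!length(scores) || min(scores) >= score) break
    i <- which.min(scores)
    tr <- nb[[i]]
    score <- scores[i]
  }
  list(tree = tr, score = score)
}

#' Heuristic parsimony search
#'
#' Per start: a random taxon-addition order (derived deterministically
#' from `seed` and the start index), stepwise insertion of each taxon at
#' the Fitch-score-minimising branch, then nearest-neighbour-interchange
#' hill climbing to a local optimum. Across starts, the best score and
#' all distinct topologies attaining it are returned. Identical seeds
#' give identical results; replicate streams are derived per start so the
#' outcome does not depend on evaluation order.
#'
#' @param matrix An [aligned_matrix()] with >= 4 taxa.
#' @param n_starts Number of random-addition starts (>= 1).
#' @param seed Master seed.
#' @param site_weights Optional per-site weights.
#' @return List with `score` and `trees` (distinct optimal topologies, in
#'   canonical key order).
#' @export
heuristic_parsimony <- function(matrix, n_starts = 10L, seed = 1L,
                                site_weights = NULL) {
  if (n_starts < 1L) abort_validation("n_starts must be >= 1")
  n <- length(matrix$taxa)
  if (n < 4L) abort_validation("heuristic search needs at least 4 taxa")
  enc <- encode_alignment(matrix)
  best_score <- Inf
  best_trees <- list()
  best_keys <- character(0)
  for (s in seq_len(n_starts)) {
    ord <- with_seed(derive_seed(seed, s), sample.int(n))
    res <- nni_hill_climb(stepwise_addition(matrix$taxa[ord], enc, site_weights),
                          enc, site_weights)
    if (res$score < best_score - 1e-9) {
      best_score <- res$score
      best_trees <- list(res$tree)
      best_keys <- topology_key(res$tree)
    } else if (abs(res$score - best_score) < 1e-9) {
      k <- topology_key(res$tree)
      if (!k %in% best_keys) {
        best_trees <- c(best_trees, list(res$tree))
        best_keys <- c(best_keys, k)
      }
    }
  }
  ord <- order(best_keys)
  list(score = best_score, trees = best_trees[ord])
}
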