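# Fitch parsimony scoring: minimum number of unordered state changes on a
# tree, summed over sites.

#' Fitch parsimony score
#'
#' Classic two-pass-free downpass count: at each internal node the state
#' sets of the children are intersected; an empty intersection costs one
#' change and the union is propagated. States are nucleotide bitmasks, so
#' IUPAC ambiguity codes contribute their state set and gaps/N are
#' missing data (the full set, never forcing a change). The tree is
#' scored as unrooted — the score is invariant to where the basal
#' (trifurcating or rooted) node sits.
#'
#' @param tree A `phylo` whose tip labels equal the matrix taxa.
#' @param matrix An [aligned_matrix()].
#' @param site_weights Optional non-negative integer weight per site
#'   (used by the bootstrap, where resampled columns become counts).
#' @return The parsimony score (integer-valued numeric).
#' @export
fitch_score <- function(tree, matrix, site_weights = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(matrix, "aligned_matrix"))
  if (!setequal(tree$tip.label, matrix$taxa) ||
      length(tree$tip.label) != length(matrix$taxa))
    abort_validation("tree tip labels do not match alignment taxa")
  enc <- encode_alignment(matrix)
  fitch_score_enc(tree, enc, site_weights)
}

# Scoring core on a pre-encoded bitmask matrix (rownames = taxa).
# Multifurcations are folded pairwise in child order; for the single basal
# trifurcation of an unrooted tree this equals the unrooted Fitch score.
fitch_score_enc <- function(tree, enc, site_weights = NULL) {
  po <- ape::reorder.phylo(tree, "postorder")
  n <- length(po$tip.label)
  nsite <- ncol(enc)
  S <- matrix(0L, n + po$Nnode, nsite)
  S[seq_len(n), ] <- enc[po$tip.label, , drop = FALSE]
  seen <- logical(n + po$Nnode)
  seen[seq_len(n)] <- TRUE
  changes <- integer(nsite)
  E <- po$edge
  for (j in seq_len(nrow(E))) {
    p <- E[j, 1]; ch <- E[j, 2]
    if (!seen[p]) {
      S[p, ] <- S[ch, ]
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(S[p, ], S[ch, ])
      zero <- inter == 0L
      changes <- changes + zero
      S[p, ] <- bitwOr(S[p, ], S[ch, ]) * zero + inter * !zero
    }
  }
  if (is.null(site_weights)) sum(changes) else sum(changes * site_weights)
}
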