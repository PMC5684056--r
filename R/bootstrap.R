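# Nonparametric bootstrap support for bipartitions, retention filtering,
# and outgroup rooting with support annotation.

#' Bootstrap bipartition support
#'
#' Felsenstein's nonparametric bootstrap: per replicate the alignment
#' columns are resampled with replacement to the original length
#' (realised as integer site weights), the heuristic search is run (one
#' random-addition start per replicate), and the bipartitions of that
#' replicate's single best tree are recorded — score ties are broken by
#' canonical topology order so each replicate contributes exactly one
#' tree. Support is 100 x count / replicates; only splits at or above the
#' retention threshold are returned (the full table is kept in the
#' `"all_splits"` attribute).
#'
#' @param matrix An [aligned_matrix()].
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param retention_percent Minimum support retained, in percent
#'   (default 70).
#' @param seed Master seed; replicate r uses a derived stream seed, so
#'   supports do not depend on replicate order.
#' @param n_starts Addition starts per replicate (default 1).
#' @return A `data.frame` with columns `split` (canonical taxon set),
#'   `support_count`, `support_percent`, sorted by decreasing support.
#' @export
bootstrap_support <- function(matrix, replicates = 1000L,
                              retention_percent = 70, seed = 1L,
                              n_starts = 1L) {
  if (replicates < 1L) abort_validation("replicates must be >= 1")
  nsite <- matrix$length
  counts <- new.env(parent = emptyenv())
  for (r in seq_len(replicates)) {
    rep_seed <- derive_seed(seed, r)
    w <- with_seed(rep_seed, tabulate(sample.int(nsite, replace = TRUE), nsite))
    res <- heuristic_parsimony(matrix, n_starts = n_starts,
                               seed = derive_seed(rep_seed, 1L),
                               site_weights = w)
    best <- res$trees[[1L]]               # canonical-order tie-break
    for (sp in tree_splits(best)) {
      counts[[sp]] <- (if (is.null(counts[[sp]])) 0L else counts[[sp]]) + 1L
    }
  }
  splits <- ls(counts)
  tab <- data.frame(
    split = splits,
    support_count = vapply(splits, function(s) counts[[s]], integer(1)),
    support_percent = NA_real_,
    stringsAsFactors = FALSE
  )
  tab$support_percent <- 100 * tab$support_count / replicates
  tab <- tab[order(-tab$support_percent, tab$split), , drop = FALSE]
  rownames(tab) <- NULL
  retained <- retain_bipartitions(tab, retention_percent)
  attr(retained, "all_splits") <- tab
  retained
}

#' Filter bipartitions by retention threshold
#'
#' Keeps splits whose support is greater than or equal to the threshold:
#' 70.0 percent is retained at a threshold of 70, 69.9 is not.
#'
#' @param supports Data frame with a `support_percent` column.
#' @param retention_percent Threshold in percent.
#' @return The retained rows.
#' @export
retain_bipartitions <- function(supports, retention_percent = 70) {
  out <- supports[supports$support_percent >= retention_percent - 1e-9, ,
                  drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Root a tree on an outgroup and annotate bootstrap support
#'
#' Roots the tree on the branch leading to the outgroup taxon and writes
#' each retained bipartition's support (integer percent) on the internal
#' node whose descendant set realises that split; internal nodes without
#' a retained split carry an empty label.
#'
#' @param tree An unrooted `phylo`.
#' @param supports Retained bipartition table from [bootstrap_support()]
#'   (or any data frame with `split` and `support_percent`).
#' @param outgroup Name of the outgroup taxon.
#' @return A rooted `phylo` with `node.label` set.
#' @export
annotate_and_root <- function(tree, supports, outgroup) {
  if (!outgroup %in% tree$tip.label)
    abort_validation(sprintf("outgroup '%s' is not among the taxa", outgroup))
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  n <- length(rooted$tip.label)
  sets <- node_tipsets(rooted)
  labels <- character(rooted$Nnode)
  lut <- stats::setNames(supports$support_percent, supports$split)
  for (v in seq_len(rooted$Nnode)) {
    node <- n + v
    side <- rooted$tip.label[sets[[node]]]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    key <- canonical_split(side, rooted$tip.label)
    if (key %in% names(lut)) labels[v] <- as.character(round(lut[[key]]))
  }
  rooted$node.label <- labels
  rooted
}
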