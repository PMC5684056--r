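# Minimal unrooted-tree toolkit on the ape edge matrix: construction by
# tip insertion, topology enumeration, NNI neighbours, and canonical
# bipartition keys. Unrooted binary trees are held as "phylo" objects
# whose basal node trifurcates (the usual unrooted convention).

#' Three-taxon star tree
#'
#' The unique unrooted topology on three taxa; the seed of stepwise
#' addition and of topology enumeration.
#'
#' @param labels Three tip labels.
#' @return A `phylo` object.
#' @export
star_tree <- function(labels) {
  stopifnot(length(labels) == 3L)
  structure(list(edge = matrix(c(4L, 4L, 4L, 1L, 2L, 3L), ncol = 2),
                 Nnode = 1L, tip.label = as.character(labels)),
            class = "phylo")
}

#' Insert a tip on an edge
#'
#' Subdivides edge `edge_i` with a new internal node and attaches a new
#' tip there; the fundamental move of both stepwise addition and topology
#' enumeration. Node numbering is kept in ape's convention (tips first,
#' basal node at `ntips + 1`).
#'
#' @param tr A `phylo` in the unrooted convention.
#' @param edge_i Row index into `tr$edge`.
#' @param label New tip label.
#' @return A `phylo` with one more tip.
#' @export
insert_tip <- function(tr, edge_i, label) {
  n <- length(tr$tip.label)
  e <- tr$edge
  e[e > n] <- e[e > n] + 1L            # shift internals; new tip takes id n+1
  newtip <- n + 1L
  newnode <- n + 1L + tr$Nnode + 1L    # one past the highest internal id
  parent <- e[edge_i, 1]; child <- e[edge_i, 2]
  e[edge_i, ] <- c(parent, newnode)
  e <- rbind(e, c(newnode, child), c(newnode, newtip))
  structure(list(edge = e, Nnode = tr$Nnode + 1L,
                 tip.label = c(tr$tip.label, label)),
            class = "phylo")
}

#' Enumerate all unrooted binary topologies
#'
#' Recursive tip insertion: every topology on n taxa arises exactly once
#' by inserting the n-th taxon into every edge of every topology on the
#' first n-1, giving (2n-5)!! trees. Feasible up to 8 taxa (10395 trees);
#' larger inputs are refused in favour of the heuristic search.
#'
#' @param labels Taxon names (3 to 8).
#' @return List of `phylo` objects.
#' @export
all_topologies <- function(labels) {
  n <- length(labels)
  if (n < 3L) abort_validation("need at least 3 taxa")
  if (n > 8L)
    abort_validation("exhaustive enumeration limited to 8 taxa; use heuristic_parsimony")
  trees <- list(star_tree(labels[1:3]))
  for (k in seq_len(n)[-(1:3)]) {
    trees <- unlist(lapply(trees, function(tr) {
      lapply(seq_len(nrow(tr$edge)), function(i) insert_tip(tr, i, labels[k]))
    }), recursive = FALSE)
  }
  trees
}

# Tip-index sets below every node (tips themselves included), via one
# postorder sweep.
node_tipsets <- function(tr) {
  po <- ape::reorder.phylo(tr, "postorder")
  n <- length(tr$tip.label)
  sets <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  for (j in seq_len(nrow(po$edge))) {
    p <- po$edge[j, 1]; ch <- po$edge[j, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# Canonical string for one side of a split: the side not containing the
# reference taxon, tips sorted, comma-joined.
canonical_split <- function(side_labels, all_labels, reference = min(all_labels)) {
  if (reference %in% side_labels)
    side_labels <- setdiff(all_labels, side_labels)
  paste(sort(side_labels), collapse = ",")
}

#' Non-trivial bipartitions of a tree
#'
#' Each internal edge splits the taxa in two; the split is stored as the
#' sorted, comma-joined side that excludes the reference taxon (default:
#' the alphabetically first), so identical splits from different trees
#' compare equal as strings. Trivial splits (single tips) are omitted.
#'
#' @param tr A `phylo`.
#' @param reference Taxon whose side is dropped from the representation.
#' @return Character vector of canonical split strings (possibly empty).
#' @export
tree_splits <- function(tr, reference = min(tr$tip.label)) {
  n <- length(tr$tip.label)
  sets <- node_tipsets(tr)
  internal_children <- tr$edge[tr$edge[, 2] > n, 2]
  out <- character(0)
  for (v in internal_children) {
    side <- tr$tip.label[sets[[v]]]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    out <- c(out, canonical_split(side, tr$tip.label, reference))
  }
  unique(out)
}

# Order-independent identity key for an unrooted topology.
topology_key <- function(tr) {
  paste(c(sort(tree_splits(tr)), "~", sort(tr$tip.label)), collapse = ";")
}

#' Nearest-neighbour-interchange neighbours
#'
#' For each internal edge the two alternative arrangements of the four
#' incident subtrees, i.e. 2(n-3) neighbouring topologies of an unrooted
#' binary tree.
#'
#' @param tr A `phylo` in the unrooted convention.
#' @return List of `phylo` objects.
#' @export
nni_neighbors <- function(tr) {
  n <- length(tr$tip.label)
  e <- tr$edge
  internal <- which(e[, 1] > n & e[, 2] > n)
  out <- vector("list", 2L * length(internal))
  k <- 0L
  for (i in internal) {
    u <- e[i, 1]; v <- e[i, 2]
    ia <- which(e[, 1] == u & e[, 2] != v)[1]   # one other subtree at u
    for (ib in which(e[, 1] == v)) {            # the two subtrees at v
      t2 <- tr
      t2$edge[ia, 2] <- e[ib, 2]
      t2$edge[ib, 2] <- e[ia, 2]
      k <- k + 1L
      out[[k]] <- t2
    }
  }
  out[seq_len(k)]
}
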