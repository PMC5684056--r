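# Homolog-pair summaries, relative lengths, and karyotype assembly.

#' Average homolog pairs across cells
#'
#' Takes the paired measurement table from [pair_homologs()] and produces
#' one summary row per chromosome pair: mean and sd of short arm, long
#' arm, and full length. Full length is taken per chromosome *before*
#' averaging — the directly measured length where recorded, the arm sum
#' otherwise — which is why the full-length column (and the haploid total
#' derived from it) can differ from the sum of the averaged arm columns
#' by measurement rounding, exactly as in published karyotype tables.
#' Also carried: the number of cells and the satellite annotation
#' (a pair is satellited if any of its measurements are). Pairs are
#' matched across cells by `pair_label` when labels are present;
#' otherwise by arm geometry (`match = "arms"`, the default: each cell's
#' pairs are assigned greedily to running (S, L) centroids seeded from
#' the first cell) or by within-cell size rank (`match = "rank"`). Final
#' ranks are assigned by descending full-length mean, ties broken by
#' larger short-arm mean, then first appearance.
#'
#' @param paired Output of [pair_homologs()] (all cells together).
#' @param match Cross-cell pair matching rule, `"arms"` or `"rank"`;
#'   ignored when labels are present.
#' @return A `data.frame` of class `pair_summaries` with columns `rank`,
#'   `short_arm_mean`, `short_arm_sd`, `long_arm_mean`, `long_arm_sd`,
#'   `full_length_mean`, `full_length_sd`, `has_satellite`,
#'   `satellite_arm`, `n_cells`.
#' @export
summarize_pairs <- function(paired, match = c("arms", "rank")) {
  match <- match.arg(match)
  stopifnot(is.data.frame(paired), "pair_rank" %in% names(paired))
  cell_key <- paste(paired$individual_id, paired$cell_id, sep = "\r")
  counts <- tapply(paired$pair_rank, cell_key, function(r) length(r) / 2L)
  if (length(unique(counts)) != 1L)
    abort_validation(sprintf(
      "inconsistent pair counts across cells: %s",
      paste(unique(counts), collapse = ", ")))
  labelled <- !is.na(paired$pair_label) & paired$pair_label != ""
  key <- if (all(labelled)) paired$pair_label
         else if (match == "arms") match_pairs_across_cells(paired, cell_key)
         else paired$pair_rank
  fl <- effective_full_length(paired)
  grp <- split(seq_len(nrow(paired)), key)
  rows <- lapply(grp, function(idx) {
    sat_any <- any(paired$has_satellite[idx])
    sat_arm <- if (sat_any) {
      arms <- paired$satellite_arm[idx][paired$has_satellite[idx]]
      names(sort(table(arms), decreasing = TRUE))[1]
    } else "none"
    data.frame(
      short_arm_mean   = mean(paired$short_arm[idx]),
      short_arm_sd     = stats::sd(paired$short_arm[idx]),
      long_arm_mean    = mean(paired$long_arm[idx]),
      long_arm_sd      = stats::sd(paired$long_arm[idx]),
      full_length_mean = mean(fl[idx]),
      full_length_sd   = stats::sd(fl[idx]),
      has_satellite    = sat_any,
      satellite_arm    = sat_arm,
      n_cells          = length(unique(cell_key[idx]))
    )
  })
  out <- do.call(rbind, rows)
  # single observation per pair -> sd undefined; report 0 (one pseudo-cell)
  out$short_arm_sd[is.na(out$short_arm_sd)] <- 0
  out$long_arm_sd[is.na(out$long_arm_sd)] <- 0
  out$full_length_sd[is.na(out$full_length_sd)] <- 0
  first_seen <- vapply(grp, min, numeric(1))
  ord <- order(-out$full_length_mean, -out$short_arm_mean, first_seen)
  out <- out[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("pair_summaries", "data.frame")
  out
}

# Match unlabelled pairs across cells by arm geometry: centroids are
# seeded from the first cell (longest pair first) and each later cell's
# pairs are assigned greedily by smallest (S, L) distance, the centroids
# tracking the running means. Returns a group id per record.
match_pairs_across_cells <- function(paired, cell_key) {
  pid <- paired$pair_id
  s_mean <- tapply(paired$short_arm, pid, mean)
  l_mean <- tapply(paired$long_arm, pid, mean)
  pid_cell <- tapply(cell_key, pid, `[`, 1)
  cells <- unique(cell_key)
  group <- stats::setNames(integer(length(s_mean)), names(s_mean))
  first <- names(s_mean)[pid_cell == cells[1]]
  first <- first[order(-(s_mean[first] + l_mean[first]))]
  npairs <- length(first)
  cent <- cbind(s_mean[first], l_mean[first])
  w <- rep(1, npairs)
  group[first] <- seq_len(npairs)
  for (ck in cells[-1]) {
    ids <- names(s_mean)[pid_cell == ck]
    D <- outer(seq_along(ids), seq_len(npairs), function(i, j)
      sqrt((s_mean[ids][i] - cent[j, 1])^2 + (l_mean[ids][i] - cent[j, 2])^2))
    for (step in seq_len(npairs)) {
      hit <- which(D == min(D, na.rm = TRUE), arr.ind = TRUE)[1, ]
      i <- hit[1]; j <- hit[2]
      group[ids[i]] <- j
      cent[j, ] <- (cent[j, ] * w[j] + c(s_mean[ids[i]], l_mean[ids[i]])) / (w[j] + 1)
      w[j] <- w[j] + 1
      D[i, ] <- NA; D[, j] <- NA
    }
  }
  unname(group[pid])
}

#' Relative chromosome lengths
#'
#' Relative length (%) = chromosome length / total haploid length x 100,
#' computed from full-length means and rounded half-up to 2 decimals. The
#' rounded values sum to 100 within +/- 0.1 by construction.
#'
#' @param full_length_mean Numeric vector of pair full-length means (µm).
#' @return Percent relative lengths, rounded to 2 dp.
#' @export
relative_lengths <- function(full_length_mean) {
  if (length(full_length_mean) == 0L)
    abort_validation("no pairs: cannot compute relative lengths")
  total <- sum(full_length_mean)
  if (total <= 0) abort_validation("total haploid length must be positive")
  round_half_up(full_length_mean / total * 100, 2L)
}

#' Assemble a karyotype from pair summaries
#'
#' Classifies each pair by its arm ratio, computes relative lengths, and
#' builds the karyotype object: the ordered pair table, ploidy metadata,
#' total haploid length (sum of full-length means), and the formula counts
#' in which each satellited pair contributes two chromosomes to the
#' satellite count of its class and every other pair two to the base
#' count.
#'
#' @param summaries A `pair_summaries` table.
#' @param scheme A [classification_scheme()].
#' @param ploidy_x Base-number multiplier (2 for a diploid); `NA` to leave
#'   ploidy unstated in the formula.
#' @return An object of class `karyotype`: list with `pairs` (the summary
#'   table extended with `relative_length`, `arm_ratio`,
#'   `centromere_class`), `ploidy_x`, `two_n`, `total_haploid_length`,
#'   `formula` (a [karyotype_formula_counts()]).
#' @export
assemble_karyotype <- function(summaries, scheme = classification_scheme(),
                               ploidy_x = 2L) {
  stopifnot(inherits(summaries, "pair_summaries") || is.data.frame(summaries))
  if (nrow(summaries) == 0L) abort_validation("no pair summaries")
  if (anyDuplicated(summaries$rank))
    abort_validation("duplicate pair ranks")
  p <- summaries[order(summaries$rank), , drop = FALSE]
  p$relative_length <- relative_lengths(p$full_length_mean)
  p$arm_ratio <- arm_ratio(p$long_arm_mean, p$short_arm_mean, scheme)
  p$centromere_class <- classify_centromere(p$arm_ratio, scheme)
  two_n <- 2L * nrow(p)
  cls <- scheme$class_bounds$class_code
  base_counts <- satellite_counts <- stats::setNames(integer(length(cls)), cls)
  for (i in seq_len(nrow(p))) {
    cc <- as.character(p$centromere_class[i])
    if (p$has_satellite[i]) satellite_counts[cc] <- satellite_counts[cc] + 2L
    else base_counts[cc] <- base_counts[cc] + 2L
  }
  k <- structure(list(
    pairs = p,
    ploidy_x = ploidy_x,
    two_n = two_n,
    total_haploid_length = sum(p$full_length_mean),
    formula = karyotype_formula_counts(base_counts, satellite_counts,
                                       b_chromosomes = 0L, two_n = two_n,
                                       ploidy_x = ploidy_x,
                                       class_order = cls)
  ), class = "karyotype")
  k
}

#' @export
print.karyotype <- function(x, ...) {
  cat(format_formula(x$formula), "\n", sep = "")
  cat(sprintf("total haploid length: %.2f um over %d pairs\n",
              x$total_haploid_length, nrow(x$pairs)))
  tab <- x$pairs[, c("rank", "short_arm_mean", "long_arm_mean",
                     "full_length_mean", "relative_length", "arm_ratio",
                     "centromere_class", "has_satellite")]
  print(format(tab, digits = 4), ...)
  invisible(x)
}
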