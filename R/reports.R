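# End-to-end drivers and report writers (Table-1-style TSV, JSON
# karyotype report, bipartition TSV, Newick, run logs).

#' Full karyotype pipeline
#'
#' Canonicalizes arm orientation, pairs homologs, averages pairs across
#' cells, and assembles the classified karyotype — the whole measurement
#' to formula path in one call.
#'
#' @param m An [arm_measurements()] table.
#' @param scheme A [classification_scheme()].
#' @param ploidy_x Ploidy clause for the formula (default 2, diploid).
#' @return A `karyotype`.
#' @export
karyotype_from_measurements <- function(m, scheme = classification_scheme(),
                                        ploidy_x = 2L) {
  assemble_karyotype(summarize_pairs(pair_homologs(canonicalize_measurements(m))),
                     scheme = scheme, ploidy_x = ploidy_x)
}

#' Write the karyotype summary table as TSV
#'
#' Mirrors the layout of a published karyotype table: per pair the
#' short-arm, long-arm and full-length means with sds, relative length,
#' arm ratio and centromere class, all numeric cells at 2 decimals.
#'
#' @param k A `karyotype`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_karyotype_tsv <- function(k, path) {
  p <- k$pairs
  fmt <- function(x) sprintf("%.2f", x)
  out <- data.frame(
    chromosome = p$rank,
    short_arm_um = sprintf("%s ± %s", fmt(p$short_arm_mean), fmt(p$short_arm_sd)),
    long_arm_um = sprintf("%s ± %s", fmt(p$long_arm_mean), fmt(p$long_arm_sd)),
    full_length_um = sprintf("%s ± %s", fmt(p$full_length_mean), fmt(p$full_length_sd)),
    relative_length_pct = fmt(p$relative_length),
    arm_ratio = fmt(p$arm_ratio),
    type = paste0(as.character(p$centromere_class),
                  ifelse(p$has_satellite, " (sat)", "")))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON karyotype report
#'
#' @param k A `karyotype`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_karyotype_json <- function(k, path) {
  rep <- list(
    formula = format_formula(k$formula),
    two_n = k$two_n,
    ploidy_x = k$ploidy_x,
    total_haploid_length_um = round_half_up(k$total_haploid_length, 2L),
    pairs = data.frame(
      rank = k$pairs$rank,
      short_arm_um = k$pairs$short_arm_mean,
      long_arm_um = k$pairs$long_arm_mean,
      full_length_um = k$pairs$full_length_mean,
      relative_length_pct = k$pairs$relative_length,
      arm_ratio = k$pairs$arm_ratio,
      centromere_class = as.character(k$pairs$centromere_class),
      has_satellite = k$pairs$has_satellite))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a tree as Newick
#'
#' Internal node labels (bootstrap percentages) are carried through as
#' written by [annotate_and_root()].
#'
#' @param tree A `phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a bipartition support table as TSV
#'
#' @param supports Data frame from [bootstrap_support()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bipartition_tsv <- function(supports, path) {
  utils::write.table(supports, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run log
#'
#' Records the package version, the seed and the run parameters so a
#' deterministic run can be reproduced from the log alone.
#'
#' @param path Output path.
#' @param params Named list of run parameters (seed included).
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, params) {
  lines <- c(
    sprintf("karyophy %s", as.character(utils::packageVersion("karyophy"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    vapply(names(params), function(nm)
      sprintf("%s: %s", nm, paste(format(params[[nm]]), collapse = " ")),
      character(1)))
  writeLines(lines, path)
  invisible(path)
}
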