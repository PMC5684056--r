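# Per-cell chromosome arm measurements: construction, validation,
# canonical orientation, file I/O, and homolog pairing.

#' Construct an arm-measurement table
#'
#' One row per chromosome observed in one metaphase cell: short- and
#' long-arm lengths in micrometres plus an optional satellite (secondary
#' constriction) annotation. This is the raw input of the karyotype
#' pipeline.
#'
#' @param individual_id Character, the plant/individual each cell came from.
#' @param cell_id Character, the metaphase cell within the individual.
#' @param short_arm,long_arm Arm lengths in µm; must be strictly positive.
#' @param pair_label Optional character homolog-pair labels (`NA` when
#'   unknown; then [pair_homologs()] falls back to size-rank pairing).
#' @param full_length Optional directly measured chromosome length (µm).
#'   Karyotype surveys usually measure total length on the slide as well
#'   as the arms; when given it is used as the chromosome's length and
#'   must agree with S + L within measurement rounding. `NA` (the
#'   default) falls back to S + L.
#' @param has_satellite Logical, whether the chromosome carries a satellite.
#' @param satellite_arm `"short"`, `"long"` or `"none"`; must be `"none"`
#'   exactly when `has_satellite` is `FALSE`.
#' @return A `data.frame` of class `arm_measurements`.
#' @export
arm_measurements <- function(individual_id, cell_id, short_arm, long_arm,
                             pair_label = NA_character_,
                             full_length = NA_real_,
                             has_satellite = FALSE,
                             satellite_arm = ifelse(has_satellite, "short", "none")) {
  df <- data.frame(
    individual_id = as.character(individual_id),
    cell_id       = as.character(cell_id),
    pair_label    = as.character(pair_label),
    short_arm     = as.numeric(short_arm),
    long_arm      = as.numeric(long_arm),
    full_length   = as.numeric(full_length),
    has_satellite = as.logical(has_satellite),
    satellite_arm = as.character(satellite_arm),
    stringsAsFactors = FALSE
  )
  validate_arm_measurements(df)
  class(df) <- c("arm_measurements", "data.frame")
  df
}

validate_arm_measurements <- function(df) {
  bad <- which(!is.finite(df$short_arm) | !is.finite(df$long_arm) |
                 df$short_arm <= 0 | df$long_arm <= 0)
  if (length(bad))
    abort_validation(sprintf(
      "non-positive arm length in record(s) %s (individual %s, cell %s)",
      paste(bad, collapse = ", "),
      paste(unique(df$individual_id[bad]), collapse = "/"),
      paste(unique(df$cell_id[bad]), collapse = "/")))
  if ("full_length" %in% names(df)) {
    given <- !is.na(df$full_length)
    armsum <- df$short_arm + df$long_arm
    off <- which(given & (df$full_length <= 0 |
                            abs(df$full_length - armsum) >
                              pmax(0.02, 0.005 * armsum)))
    if (length(off))
      abort_validation(sprintf(
        "measured full length inconsistent with arm sum in record(s) %s",
        paste(off, collapse = ", ")))
  }
  ok_arm <- df$satellite_arm %in% c("short", "long", "none")
  if (any(!ok_arm))
    abort_validation(sprintf("unknown satellite_arm value(s): %s",
                             paste(unique(df$satellite_arm[!ok_arm]), collapse = ", ")))
  mism <- which(xor(df$has_satellite, df$satellite_arm != "none"))
  if (length(mism))
    abort_validation(sprintf(
      "satellite flag and satellite_arm disagree in record(s) %s",
      paste(mism, collapse = ", ")))
  invisible(df)
}

# Chromosome length per record: the directly measured full length where
# given, the arm sum otherwise.
effective_full_length <- function(df) {
  if (!"full_length" %in% names(df)) return(df$short_arm + df$long_arm)
  ifelse(is.na(df$full_length), df$short_arm + df$long_arm, df$full_length)
}

#' Canonicalize arm orientation
#'
#' Enforces the convention behind the arm ratio L/S: the long arm is the
#' longer of the two. Records measured in the opposite order are swapped
#' (together with their satellite-arm annotation) with a warning rather
#' than rejected, since slide measurements may record arms either way.
#'
#' @param m An `arm_measurements` table.
#' @return The table with `long_arm >= short_arm` in every row.
#' @export
canonicalize_measurements <- function(m) {
  validate_arm_measurements(m)
  swap <- m$short_arm > m$long_arm
  if (any(swap)) {
    warning(sprintf("swapped arms in %d record(s) measured short > long: %s",
                    sum(swap), paste(which(swap), collapse = ", ")))
    s <- m$short_arm[swap]
    m$short_arm[swap] <- m$long_arm[swap]
    m$long_arm[swap] <- s
    sat <- m$satellite_arm[swap]
    m$satellite_arm[swap] <- ifelse(sat == "short", "long",
                                    ifelse(sat == "long", "short", "none"))
  }
  m
}

#' Read an arm-measurement table from a delimited file
#'
#' Accepts comma- or tab-delimited text with a header. Required columns:
#' `individual_id`, `cell_id`, `short_arm_um`, `long_arm_um`; optional:
#' `pair_label`, `satellite` (logical/0-1), `satellite_arm`.
#'
#' @param path File path.
#' @return An `arm_measurements` table.
#' @export
read_measurements <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) abort_validation(sprintf("no records in '%s'", path))
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  if (nrow(raw) == 0L) abort_validation(sprintf("no records in '%s'", path))
  need <- c("individual_id", "cell_id", "short_arm_um", "long_arm_um")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    abort_validation(sprintf("'%s' lacks required column(s): %s",
                             path, paste(miss, collapse = ", ")))
  has_sat <- if ("satellite" %in% names(raw)) as.logical(raw$satellite) else FALSE
  arm_measurements(
    individual_id = raw$individual_id,
    cell_id       = raw$cell_id,
    short_arm     = raw$short_arm_um,
    long_arm      = raw$long_arm_um,
    full_length   = if ("full_length_um" %in% names(raw)) raw$full_length_um else NA_real_,
    pair_label    = if ("pair_label" %in% names(raw)) raw$pair_label else NA_character_,
    has_satellite = has_sat,
    satellite_arm = if ("satellite_arm" %in% names(raw)) raw$satellite_arm
                    else ifelse(has_sat, "short", "none")
  )
}

#' Write an arm-measurement table as CSV
#'
#' @param m An `arm_measurements` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(m, path) {
  out <- data.frame(individual_id = m$individual_id, cell_id = m$cell_id,
                    pair_label = m$pair_label,
                    short_arm_um = m$short_arm, long_arm_um = m$long_arm,
                    full_length_um = m$full_length,
                    satellite = as.integer(m$has_satellite),
                    satellite_arm = m$satellite_arm)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pair homologous chromosomes within each cell
#'
#' With `pair_label` present on every record, records are grouped by label
#' (each label must occur exactly twice per cell) — the authoritative
#' path. Without labels, each cell must contain an even number of records
#' and homologs are paired automatically:
#'
#' * `method = "arms"` (default) pairs by morphology, the way homologs
#'   are matched on a slide: the longest unpaired chromosome is paired
#'   with its nearest neighbour in (short-arm, long-arm) space,
#'   repeatedly. Because short arms carry little absolute measurement
#'   noise, this keeps chromosomes of similar total length but different
#'   centromere position apart.
#' * `method = "rank"` sorts by full length descending and pairs
#'   consecutive ranks (1,2), (3,4), ... — the naive size-rank rule. It
#'   is reliable only when between-pair length gaps exceed the
#'   measurement noise.
#'
#' Aneuploid or B-chromosome counts must be labelled.
#'
#' @param m A canonical `arm_measurements` table.
#' @param method Auto-pairing rule, `"arms"` or `"rank"`.
#' @return A `data.frame` like `m` with columns `pair_rank` (1 = longest
#'   pair within its cell) and `pair_id` added.
#' @export
pair_homologs <- function(m, method = c("arms", "rank")) {
  method <- match.arg(method)
  validate_arm_measurements(m)
  labelled <- !is.na(m$pair_label) & m$pair_label != ""
  if (any(labelled) && !all(labelled))
    abort_validation("pair_label must be present on all records or none")
  cells <- split(seq_len(nrow(m)), paste(m$individual_id, m$cell_id, sep = "\r"))
  out <- vector("list", length(cells))
  for (k in seq_along(cells)) {
    idx <- cells[[k]]
    sub <- m[idx, , drop = FALSE]
    fl <- effective_full_length(sub)
    if (all(labelled)) {
      counts <- table(sub$pair_label)
      bad <- names(counts)[counts != 2L]
      if (length(bad))
        abort_validation(sprintf(
          "cell %s/%s: pair label(s) not seen exactly twice: %s",
          sub$individual_id[1], sub$cell_id[1], paste(bad, collapse = ", ")))
      # rank labels by mean full length, longest pair first
      lab_len <- tapply(fl, sub$pair_label, mean)
      ranks <- rank(-lab_len, ties.method = "first")
      sub$pair_rank <- as.integer(ranks[sub$pair_label])
    } else {
      if (nrow(sub) %% 2L != 0L)
        abort_validation(sprintf(
          "cell %s/%s has %d unlabelled records; auto-pairing needs an even count",
          sub$individual_id[1], sub$cell_id[1], nrow(sub)))
      part <- if (method == "arms") {
        pair_by_arm_geometry(sub$short_arm, sub$long_arm, fl)
      } else {
        ord <- order(-fl, -sub$short_arm)
        split(ord, rep(seq_len(nrow(sub) / 2L), each = 2L))
      }
      pr <- integer(nrow(sub))
      pair_len <- vapply(part, function(ii) mean(fl[ii]), numeric(1))
      for (r in seq_along(part)) pr[part[[order(-pair_len)[r]]]] <- r
      sub$pair_rank <- pr
    }
    sub$pair_id <- paste(sub$individual_id, sub$cell_id, sub$pair_rank, sep = ":")
    out[[k]] <- sub
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Greedy morphology pairing: repeatedly take the longest unpaired
# chromosome and pair it with the nearest remaining one in (S, L) space.
pair_by_arm_geometry <- function(s, l, fl) {
  left <- seq_along(s)
  part <- list()
  while (length(left)) {
    i <- left[which.max(fl[left])]
    left <- setdiff(left, i)
    d <- sqrt((s[left] - s[i])^2 + (l[left] - l[i])^2)
    j <- left[which.min(d)]
    left <- setdiff(left, j)
    part[[length(part) + 1L]] <- c(i, j)
  }
  part
}
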