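# Aligned nucleotide matrices: container, FASTA I/O, bitmask encoding for
# Fitch scoring, and ITS partitioning.

IUPAC_BITS <- c(
  a = 1L, c = 2L, g = 4L, t = 8L, u = 8L,
  r = 5L, y = 10L, s = 6L, w = 9L, k = 12L, m = 3L,
  b = 14L, d = 13L, h = 11L, v = 7L,
  n = 15L, "-" = 15L, "?" = 15L, "." = 15L, x = 15L
)

#' Construct an aligned nucleotide matrix
#'
#' @param taxa Character vector of unique taxon names.
#' @param sequences Character vector (one string per taxon) of equal
#'   length over the nucleotide alphabet plus gaps and IUPAC ambiguity
#'   codes.
#' @return An object of class `aligned_matrix` with elements `taxa`,
#'   `chars` (character matrix, taxa x sites, lowercase) and `length`.
#' @export
aligned_matrix <- function(taxa, sequences) {
  taxa <- as.character(taxa)
  if (length(taxa) < 3L)
    abort_validation("an aligned matrix needs at least 3 taxa")
  if (anyDuplicated(taxa))
    abort_validation("taxon names must be unique")
  if (length(sequences) != length(taxa))
    abort_validation("one sequence per taxon required")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    abort_validation(sprintf("sequences are not aligned: lengths %s",
                             paste(unique(lens), collapse = ", ")))
  chars <- do.call(rbind, strsplit(tolower(sequences), ""))
  rownames(chars) <- taxa
  bad <- setdiff(unique(as.vector(chars)), names(IUPAC_BITS))
  if (length(bad))
    abort_validation(sprintf("unknown residue character(s): %s",
                             paste(bad, collapse = ", ")))
  structure(list(taxa = taxa, chars = chars, length = ncol(chars)),
            class = "aligned_matrix")
}

#' Read an aligned FASTA file
#'
#' @param path FASTA path; all records must have equal length.
#' @return An `aligned_matrix`.
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), paste, character(1), collapse = "")
  aligned_matrix(names(dna), seqs)
}

#' Write an aligned matrix as FASTA
#'
#' @param m An `aligned_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(m, path) {
  lines <- as.vector(rbind(paste0(">", m$taxa),
                           apply(m$chars, 1, paste, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}

# taxa x sites integer matrix of IUPAC bitmasks (A=1, C=2, G=4, T=8;
# ambiguity = union; gap/N/? = full set, i.e. missing data).
encode_alignment <- function(m) {
  stopifnot(inherits(m, "aligned_matrix"))
  enc <- matrix(IUPAC_BITS[as.vector(m$chars)], nrow = length(m$taxa))
  rownames(enc) <- m$taxa
  enc
}

#' Subsequence extraction for one taxon
#'
#' @param m An `aligned_matrix`.
#' @param taxon Taxon name.
#' @return The taxon's sequence as a single string.
#' @export
get_sequence <- function(m, taxon) {
  if (!taxon %in% m$taxa) abort_validation(sprintf("taxon '%s' not in matrix", taxon))
  paste(m$chars[taxon, ], collapse = "")
}

#' ITS partition specification
#'
#' 1-based inclusive coordinates of the ITS1, 5.8S and ITS2 regions of a
#' ribosomal transcript. Defaults are the coordinates of the 590-bp
#' Taiwanese Lilium callosum ITS region: ITS1 1-229, 5.8S 230-393,
#' ITS2 394-590. Regions must be contiguous, non-overlapping, ascending.
#'
#' @param its1,r5_8s,its2 Length-2 integer vectors `(start, end)`.
#' @return An object of class `its_partition_spec`.
#' @export
its_partition_spec <- function(its1 = c(1L, 229L), r5_8s = c(230L, 393L),
                               its2 = c(394L, 590L)) {
  regs <- list(its1 = as.integer(its1), r5_8s = as.integer(r5_8s),
               its2 = as.integer(its2))
  for (nm in names(regs)) {
    r <- regs[[nm]]
    if (length(r) != 2L || r[1] < 1L || r[2] < r[1])
      abort_validation(sprintf("invalid %s region (%s)", nm, paste(r, collapse = ", ")))
  }
  if (regs$r5_8s[1] != regs$its1[2] + 1L || regs$its2[1] != regs$r5_8s[2] + 1L)
    abort_validation("ITS regions must be contiguous and ascending")
  structure(regs, class = "its_partition_spec")
}

#' Partition a sequence into ITS1 / 5.8S / ITS2
#'
#' 1-based inclusive slicing; with the default spec on a 590-base
#' sequence the pieces have lengths 229, 164 and 197 and concatenate back
#' to the input.
#'
#' @param sequence A single nucleotide string.
#' @param spec An [its_partition_spec()].
#' @return Named list of the three subsequences.
#' @export
partition_its <- function(sequence, spec = its_partition_spec()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  need <- spec$its2[2]
  if (n < need)
    abort_validation(sprintf(
      "sequence has %d bases but the partition needs %d (%d short)",
      n, need, need - n))
  list(its1  = substr(sequence, spec$its1[1], spec$its1[2]),
       r5_8s = substr(sequence, spec$r5_8s[1], spec$r5_8s[2]),
       its2  = substr(sequence, spec$its2[1], spec$its2[2]))
}
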