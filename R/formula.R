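# Karyotype formulas: the count object, canonical formatting, and a parser
# for the dialects found in the cytotaxonomy literature.

#' Karyotype formula counts
#'
#' A multiset of centromere-class chromosome counts, split into plain and
#' satellited (secondary-constriction) chromosomes, plus optional B
#' chromosomes. Satellited chromosomes are counted once, in
#' `satellite_counts`; base and satellite counts together must sum to the
#' diploid number (B chromosomes are supernumerary and excluded from 2n,
#' as in "2n = 24 + 2B").
#'
#' @param base_counts Named integer vector, class code -> plain count.
#' @param satellite_counts Named integer vector, class code -> satellited
#'   count (default all zero).
#' @param b_chromosomes Integer >= 0 supernumerary B chromosomes.
#' @param two_n The diploid chromosome number the counts must sum to.
#' @param ploidy_x Base-number multiplier (`NA` when unstated).
#' @param class_order Class codes in display order (default m, sm, st, t).
#' @return An object of class `karyotype_formula_counts`.
#' @export
karyotype_formula_counts <- function(base_counts,
                                     satellite_counts = NULL,
                                     b_chromosomes = 0L,
                                     two_n = NULL,
                                     ploidy_x = NA_integer_,
                                     class_order = c("m", "sm", "st", "t")) {
  full <- stats::setNames(integer(length(class_order)), class_order)
  bc <- sc <- full
  bc[names(base_counts)] <- as.integer(base_counts)
  if (!is.null(satellite_counts))
    sc[names(satellite_counts)] <- as.integer(satellite_counts)
  unknown <- setdiff(c(names(base_counts), names(satellite_counts)), class_order)
  if (length(unknown))
    abort_validation(sprintf("unknown centromere class code(s): %s",
                             paste(unknown, collapse = ", ")))
  if (any(bc < 0L) || any(sc < 0L) || b_chromosomes < 0L)
    abort_validation("chromosome counts must be non-negative")
  total <- sum(bc) + sum(sc)
  if (is.null(two_n)) two_n <- total
  if (total != two_n)
    abort_validation(sprintf(
      "formula counts sum to %d but 2n = %d", total, two_n))
  structure(list(base_counts = bc, satellite_counts = sc,
                 b_chromosomes = as.integer(b_chromosomes),
                 two_n = as.integer(two_n),
                 ploidy_x = ploidy_x,
                 class_order = class_order),
            class = "karyotype_formula_counts")
}

#' Format a karyotype formula string
#'
#' Canonical rendering: `2n = 2x = 24 = 2m + 2m(sat) + 2sm + 8st + 10t`.
#' Terms appear in class order with the plain term before the satellited
#' term of the same class; zero counts are omitted; the satellite
#' annotation is rendered lowercase `(sat)`; B chromosomes are appended to
#' the 2n clause (`24 + 2B`); the ploidy clause is suppressed when
#' `ploidy_x` is `NA`.
#'
#' @param counts A [karyotype_formula_counts()] or a `karyotype` (its
#'   `formula` element is used).
#' @return The formula as a single string.
#' @export
format_formula <- function(counts) {
  if (inherits(counts, "karyotype")) counts <- counts$formula
  stopifnot(inherits(counts, "karyotype_formula_counts"))
  terms <- character(0)
  for (cc in counts$class_order) {
    if (counts$base_counts[cc] > 0L)
      terms <- c(terms, sprintf("%d%s", counts$base_counts[cc], cc))
    if (counts$satellite_counts[cc] > 0L)
      terms <- c(terms, sprintf("%d%s(sat)", counts$satellite_counts[cc], cc))
  }
  nclause <- as.character(counts$two_n)
  if (counts$b_chromosomes > 0L)
    nclause <- sprintf("%d + %dB", counts$two_n, counts$b_chromosomes)
  xclause <- if (is.na(counts$ploidy_x)) "" else sprintf("%dx = ", counts$ploidy_x)
  sprintf("2n = %s%s = %s", xclause, nclause, paste(terms, collapse = " + "))
}

#' Parse a karyotype formula string
#'
#' Understands the dialects used across the Lilium karyotype literature:
#' an optional `2n =` and optional ploidy clause (`2x =`), the diploid
#' number optionally carrying a B-chromosome term (`24 + 2B`), then
#' `+`-separated class terms. A term is a count followed by a class code
#' (m, sm, st, t) and an optional parenthesized satellite annotation —
#' `(sat)`/`(SAT)` marks the whole term as satellited, while a counted
#' secondary-constriction note like `(2sc)` moves that many chromosomes of
#' the term's class into the satellite count. Whitespace is optional
#' everywhere. Parsing validates that the counts sum to 2n.
#'
#' @param s The formula string.
#' @return A [karyotype_formula_counts()].
#' @export
parse_formula <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  compact <- gsub("[[:space:]]+", "", s)
  parts <- strsplit(compact, "=", fixed = TRUE)[[1]]
  if (length(parts) < 2L)
    abort_validation(sprintf("cannot parse formula '%s': no '=' separating 2n from terms", s))
  term_str <- parts[length(parts)]
  n_str <- parts[length(parts) - 1L]
  ploidy_x <- NA_integer_
  if (length(parts) > 2L) {
    for (head in parts[1:(length(parts) - 2L)]) {
      if (head == "2n") next
      mx <- regmatches(head, regexec("^([0-9]+)x$", head))[[1]]
      if (length(mx)) ploidy_x <- as.integer(mx[2])
      else abort_validation(sprintf("unrecognized clause '%s' in formula '%s'", head, s))
    }
  }
  mn <- regmatches(n_str, regexec("^([0-9]+)(\\+([0-9]*)B)?$", n_str))[[1]]
  if (!length(mn))
    abort_validation(sprintf("cannot parse chromosome-number clause '%s'", n_str))
  two_n <- as.integer(mn[2])
  b <- if (nzchar(mn[3])) {
    if (nzchar(mn[4])) as.integer(mn[4]) else 1L
  } else 0L

  classes <- c("m", "sm", "st", "t")
  base <- sat <- stats::setNames(integer(4), classes)
  for (tok in strsplit(term_str, "+", fixed = TRUE)[[1]]) {
    if (!nzchar(tok)) next
    mt <- regmatches(tok, regexec(
      "^([0-9]+)(sm|st|m|t)(\\(([0-9]*)(sat|sc)\\))?$", tok, ignore.case = TRUE))[[1]]
    if (!length(mt))
      abort_validation(sprintf("cannot parse term '%s' in formula '%s'", tok, s))
    count <- as.integer(mt[2])
    cc <- tolower(mt[3])
    if (nzchar(mt[4])) {                       # satellite/sc annotation present
      n_sat <- if (nzchar(mt[5])) as.integer(mt[5]) else count
      if (n_sat > count)
        abort_validation(sprintf(
          "term '%s': %d satellited exceeds term count %d", tok, n_sat, count))
      sat[cc] <- sat[cc] + n_sat
      base[cc] <- base[cc] + (count - n_sat)
    } else {
      base[cc] <- base[cc] + count
    }
  }
  total <- sum(base) + sum(sat)
  if (total != two_n)
    abort_validation(sprintf(
      "formula terms sum to %d but 2n clause says %d", total, two_n))
  karyotype_formula_counts(base, sat, b_chromosomes = b, two_n = two_n,
                           ploidy_x = ploidy_x)
}

#' @export
print.karyotype_formula_counts <- function(x, ...) {
  cat(format_formula(x), "\n", sep = "")
  invisible(x)
}
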