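# Arm ratios and Levan-style centromere-position classification.

#' Centromere classification scheme
#'
#' Arm-ratio intervals mapping a chromosome to a centromere-position class.
#' The default follows the Levan-derived convention used in Lilium
#' cytotaxonomy: median (m) 1.00-1.70, submedian (sm) 1.71-3.00,
#' subterminal (st) 3.01-7.00, terminal (t) >= 7.01. The printed bounds
#' leave gaps (1.70 vs 1.71 etc.); these are closed by rounding the ratio
#' to `rounding_decimals` first and then testing inclusive bounds, which
#' makes the intervals exhaustive on the rounded grid.
#'
#' @param class_bounds Data frame with columns `class_code`, `lower`,
#'   `upper` (inclusive after rounding), ordered by increasing `lower`.
#' @param rounding_decimals Decimals the ratio is rounded (half-up) to
#'   before classification; default 2, matching published tables.
#' @return An object of class `classification_scheme`.
#' @export
classification_scheme <- function(class_bounds = NULL, rounding_decimals = 2L) {
  if (is.null(class_bounds)) {
    class_bounds <- data.frame(
      class_code = c("m", "sm", "st", "t"),
      lower = c(1.00, 1.71, 3.01, 7.01),
      upper = c(1.70, 3.00, 7.00, Inf),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(class_bounds),
            all(c("class_code", "lower", "upper") %in% names(class_bounds)))
  if (is.unsorted(class_bounds$lower, strictly = TRUE))
    abort_validation("class bounds must be ordered by strictly increasing lower bound")
  if (any(class_bounds$upper < class_bounds$lower))
    abort_validation("class bound upper < lower")
  # adjacent intervals must not overlap on the rounded grid
  step <- 10^(-rounding_decimals)
  n <- nrow(class_bounds)
  if (n > 1L && any(class_bounds$lower[-1] < class_bounds$upper[-n] + step / 2))
    abort_validation("class intervals overlap after rounding")
  structure(list(class_bounds = class_bounds,
                 rounding_decimals = as.integer(rounding_decimals)),
            class = "classification_scheme")
}

#' Arm ratio L/S
#'
#' Long-arm mean divided by short-arm mean, rounded half-up to the scheme's
#' decimals (default 2). Requires canonical orientation (L >= S).
#'
#' @param long_arm,short_arm Arm lengths (means), µm.
#' @param scheme A [classification_scheme()]; only its rounding is used.
#' @return Rounded ratio(s), dimensionless.
#' @export
arm_ratio <- function(long_arm, short_arm, scheme = classification_scheme()) {
  if (any(short_arm <= 0))
    abort_validation("short arm length must be positive to form the arm ratio")
  round_half_up(long_arm / short_arm, scheme$rounding_decimals)
}

#' Classify centromere position from an arm ratio
#'
#' Rounds the ratio to the scheme's decimals (half-up), then returns the
#' unique class whose inclusive interval contains it. Ratios below 1 after
#' rounding indicate non-canonical arm orientation and are rejected.
#'
#' @param ratio Arm ratio(s), L/S.
#' @param scheme A [classification_scheme()].
#' @return Factor of class codes ordered m < sm < st < t (or the scheme's
#'   own order), same length as `ratio`.
#' @export
classify_centromere <- function(ratio, scheme = classification_scheme()) {
  r <- round_half_up(ratio, scheme$rounding_decimals)
  if (any(r < scheme$class_bounds$lower[1]))
    abort_validation(sprintf(
      "arm ratio %s below %.2f after rounding: arms not in canonical L >= S orientation",
      paste(r[r < scheme$class_bounds$lower[1]], collapse = ", "),
      scheme$class_bounds$lower[1]))
  b <- scheme$class_bounds
  out <- character(length(r))
  for (i in seq_len(nrow(b))) {
    hit <- r >= b$lower[i] - 1e-9 & r <= b$upper[i] + 1e-9
    out[hit] <- b$class_code[i]
  }
  if (any(out == ""))
    abort_validation(sprintf("arm ratio(s) %s fall in no class interval",
                             paste(r[out == ""], collapse = ", ")))
  factor(out, levels = b$class_code, ordered = TRUE)
}
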