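# Haploid idiogram construction and a light SVG rendering.

#' Build idiogram rows from a karyotype
#'
#' One row per homolog pair, in descending relative length (the rank
#' ordering of the karyotype): relative length, the short-arm fraction of
#' pair length (<= 0.5 in canonical orientation; the centromere position),
#' and the satellite mark. This is the data a drawn idiogram encodes.
#'
#' @param k A `karyotype`.
#' @return A `data.frame` with columns `rank`, `relative_length`,
#'   `short_fraction`, `satellite_mark`, sorted by rank.
#' @export
build_idiogram <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  p <- k$pairs[order(k$pairs$rank), , drop = FALSE]
  data.frame(
    rank = p$rank,
    relative_length = p$relative_length,
    short_fraction = p$short_arm_mean / p$full_length_mean,
    satellite_mark = p$has_satellite
  )
}

#' Write an idiogram as SVG
#'
#' Schematic haploid idiogram: one vertical bar per pair in rank order,
#' height proportional to relative length, split at the centromere, with a
#' detached satellite block above the short arm where marked. Cosmetic
#' output; the contract-bearing numbers live in [build_idiogram()].
#'
#' @param k A `karyotype`.
#' @param path Output path (`.svg`).
#' @param bar_width,gap,scale Pixel geometry of the drawing.
#' @return `path`, invisibly.
#' @export
write_idiogram_svg <- function(k, path, bar_width = 22, gap = 14, scale = 18) {
  rows <- build_idiogram(k)
  n <- nrow(rows)
  maxh <- max(rows$relative_length) * scale
  top <- 40; left <- 30
  width <- left * 2 + n * bar_width + (n - 1) * gap
  height <- top + maxh + 40
  el <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    ceiling(width), ceiling(height)))
  for (i in seq_len(n)) {
    x <- left + (i - 1) * (bar_width + gap)
    h <- rows$relative_length[i] * scale
    hs <- h * rows$short_fraction[i]
    # short arm above a fixed centromere line, long arm below
    cy <- top + maxh * 0.45
    el <- c(el,
      sprintf('<rect x="%.1f" y="%.1f" width="%d" height="%.1f" fill="#777" stroke="black"/>',
              x, cy - hs, bar_width, hs),
      sprintf('<rect x="%.1f" y="%.1f" width="%d" height="%.1f" fill="#bbb" stroke="black"/>',
              x, cy + 2, bar_width, h - hs),
      sprintf('<text x="%.1f" y="%.1f" font-size="10" text-anchor="middle">%d</text>',
              x + bar_width / 2, cy + (h - hs) + 16, rows$rank[i]),
      sprintf('<text x="%.1f" y="%.1f" font-size="8" text-anchor="middle">%.2f</text>',
              x + bar_width / 2, cy - hs - (if (rows$satellite_mark[i]) 14 else 4),
              rows$relative_length[i]))
    if (rows$satellite_mark[i])
      el <- c(el, sprintf(
        '<rect x="%.1f" y="%.1f" width="%d" height="6" fill="#777" stroke="black"/>',
        x, cy - hs - 10, bar_width))
  }
  el <- c(el, "</svg>")
  writeLines(el, path)
  invisible(path)
}
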