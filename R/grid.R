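# Test-point grids for the Humphrey 24-2 and 30-2 patterns.
#
# Coordinates are degrees of visual angle in right-eye (OD) orientation:
# positive x is nasal, positive y is superior. Points are ordered as on the
# instrument printout: rows from superior to inferior, left to right within
# each row. The two blind-spot locations (15, 3) and (15, -3) are excluded,
# leaving 52 points for 24-2 and 74 for 30-2.

.make_grid <- function(rows) {
  xs <- lapply(rows$n, function(n) seq(-3 * (n - 1), 3 * (n - 1), by = 6))
  x <- unlist(xs)
  y <- rep(rows$y, rows$n)
  keep <- !(x == 15 & abs(y) == 3)
  data.frame(index = seq_len(sum(keep)), x = x[keep], y = y[keep])
}

#' Humphrey 24-2 test-point grid
#'
#' Returns the 52 total-deviation test locations of the 24-2 pattern (54
#' locations minus the two blind-spot points), in printout order: superior
#' to inferior rows, left to right within a row, right-eye orientation
#' (nasal = positive x). This ordering is the canonical layout for every
#' 52-length total-deviation vector in the package.
#'
#' @return A data frame with columns `index` (1..52), `x` and `y`
#'   (degrees of visual angle).
#' @examples
#' g <- vf_grid24()
#' nrow(g)  # 52
#' @export
vf_grid24 <- function() {
  # 54 locations: centred rows of 4/6/8, and y = +/-3 rows running from
  # -21 (24 deg temporal limit) to +27 (30 deg nasal extension, OD)
  xs <- list(seq(-9, 9, 6), seq(-15, 15, 6), seq(-21, 21, 6),
             seq(-21, 27, 6), seq(-21, 27, 6),
             seq(-21, 21, 6), seq(-15, 15, 6), seq(-9, 9, 6))
  ys <- c(21, 15, 9, 3, -3, -9, -15, -21)
  x <- unlist(xs)
  y <- rep(ys, lengths(xs))
  keep <- !(x == 15 & abs(y) == 3)
  data.frame(index = seq_len(sum(keep)), x = x[keep], y = y[keep])
}

#' Humphrey 30-2 test-point grid
#'
#' Returns the 74 total-deviation locations of the 30-2 pattern (76 minus
#' the two blind-spot points), in printout order.
#'
#' @return A data frame with columns `index` (1..74), `x` and `y`.
#' @export
vf_grid30 <- function() {
  rows <- data.frame(
    y = c(27, 21, 15, 9, 3, -3, -9, -15, -21, -27),
    n = c(4, 6, 8, 10, 10, 10, 10, 8, 6, 4)
  )
  .make_grid(rows)
}

#' Index map from the 30-2 grid onto the 24-2 grid
#'
#' For each of the 52 points of [vf_grid24()], gives the row index of the
#' same (x, y) location in [vf_grid30()]. The 24-2 pattern is a spatial
#' subset of the 30-2 pattern, so the map is total.
#'
#' @return Integer vector of length 52 with values in 1..74.
#' @export
vf_overlap_30_to_24 <- function() {
  g24 <- vf_grid24()
  g30 <- vf_grid30()
  idx <- match(paste(g24$x, g24$y), paste(g30$x, g30$y))
  if (anyNA(idx)) stop("internal error: 24-2 point missing from 30-2 grid")
  idx
}

#' Mirror a left-eye field into right-eye orientation
#'
#' Visual fields of left eyes are conventionally mirrored about the
#' vertical midline so that nasal points align across eyes. Because the
#' left-eye 24-2 chart is itself the mirror image of the right-eye chart,
#' the conversion of a printout-ordered 52-value vector is a reversal of
#' the point order within each horizontal row. The map is an involution:
#' applying it twice returns the input.
#'
#' @param td Numeric vector of 52 total-deviation values in the printout
#'   order of the source eye.
#' @return Numeric vector of 52 values in the mirrored printout order.
#' @export
mirror_eye <- function(td) {
  if (length(td) != 52L) stop("`td` must have exactly 52 values")
  g <- vf_grid24()
  idx <- unlist(lapply(split(g$index, -g$y), rev), use.names = FALSE)
  td[idx]
}
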