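#' Convert a boundary map to a segmentation
#'
#' Connected components of 1-pixels become segments with unique positive
#' labels. Every 0-pixel is a segment containing just that pixel, so a
#' border pixel never silently joins a neighbouring cell; this singleton
#' convention is what makes border pixels maximally "wrong" against any
#' other segmentation and is part of the scoring contract.
#'
#' @param bmap binary matrix (1 = interior, 0 = border).
#' @param connectivity 4 (edge-adjacent, default) or 8 (edge- or
#'   corner-adjacent) for the foreground components. With 8-connectivity
#'   a one-pixel diagonal border does not separate segments, so 4 is the
#'   default for scoring boundary maps.
#' @return An integer label matrix; all labels positive, foreground
#'   components labeled first, then one fresh label per 0-pixel.
#' @examples
#' segment_boundary_map(matrix(c(1, 0, 1,
#'                               1, 0, 1,
#'                               1, 0, 1), 3, 3, byrow = TRUE))
#' @export
segment_boundary_map <- function(bmap, connectivity = 4) {
  assert_binary_map(bmap)
  connectivity <- assert_connectivity(connectivity)
  lab <- cc_label(as_int_matrix(bmap), connectivity)
  k <- max(lab)
  zeros <- which(lab == 0L)
  lab[zeros] <- k + seq_along(zeros)
  lab
}

#' Thin borders without merging segments
#'
#' Flips border (0) pixels back to foreground wherever doing so cannot
#' connect two distinct segments, until no further pixel can be flipped.
#' The result has borders of roughly one-pixel width regardless of how
#' wide the input drew them, while the partition of the input's
#' foreground into segments is exactly preserved: thinning can never
#' merge two objects. Scoring thinned maps removes the dependence of
#' region scores on border width.
#'
#' The operator is deterministic: passes repeat until a fixpoint; each
#' pass fixes the current frontier (0-pixels adjacent to foreground) and
#' scans it in row-major order, flipping a pixel to its neighbours'
#' segment only when all its current foreground neighbours agree on one
#' segment, with labels updated immediately. Border pixels adjacent to a
#' single segment (spurs, isolated interior holes) are absorbed.
#'
#' @inheritParams segment_boundary_map
#' @return A binary matrix `>=` the input pointwise (only 0 to 1 flips).
#' @examples
#' m <- matrix(1, 4, 6); m[, 3:4] <- 0      # two-pixel-wide border
#' thin_borders(m)                          # one border column remains
#' @export
thin_borders <- function(bmap, connectivity = 4) {
  assert_binary_map(bmap)
  connectivity <- assert_connectivity(connectivity)
  out <- thin_cpp(as_int_matrix(bmap), connectivity)
  storage.mode(out) <- storage.mode(bmap)   # match the input's type
  out
}

#' Dilate borders of a boundary map
#'
#' Widens every border: each pixel within Chebyshev distance `radius` of
#' an input 0-pixel becomes 0. This is the perturbation primitive used
#' to emulate submissions that draw markedly wider borders than others;
#' it only flips 1 to 0, so it can fragment but never merge objects.
#'
#' @inheritParams segment_boundary_map
#' @param radius positive integer dilation radius (a one-pixel border
#'   becomes `2 * radius + 1` pixels wide).
#' @return A binary matrix `<=` the input pointwise.
#' @export
dilate_borders <- function(bmap, radius) {
  assert_binary_map(bmap)
  if (length(radius) != 1 || radius < 1 || radius != round(radius))
    stop("`radius` must be a positive integer", call. = FALSE)
  radius <- as.integer(radius)
  nr <- nrow(bmap); nc <- ncol(bmap)
  if (radius > max(nr, nc))
    stop("`radius` exceeds the image extent", call. = FALSE)
  out <- bmap
  for (dr in -radius:radius) {
    for (dc in -radius:radius) {
      if (dr == 0 && dc == 0) next
      r1 <- max(1, 1 - dr); r2 <- min(nr, nr - dr)
      c1 <- max(1, 1 - dc); c2 <- min(nc, nc - dc)
      if (r1 > r2 || c1 > c2) next
      out[r1:r2, c1:c2] <-
        pmin(out[r1:r2, c1:c2], bmap[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)])
    }
  }
  out
}
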