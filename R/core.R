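#' Foreground evaluation mask from a ground-truth boundary map
#'
#' Region scores are restricted to the ground-truth foreground: border
#' (0) pixels of the ground truth are excluded from the pixel set over
#' which predicted and true segmentations are compared, so that
#' unimportant variations in border width do not dominate the score.
#' Only the ground truth is masked; predicted segments are computed on
#' the full image.
#'
#' @param gt binary matrix, 1 = inside a cell, 0 = border.
#' @return A logical matrix, `TRUE` where the pixel enters the
#'   evaluation, i.e. exactly where `gt == 1`.
#' @examples
#' gt <- matrix(c(1, 1, 0, 1), 4, 4, byrow = TRUE)
#' sum(foreground_mask(gt))  # 12 of 16 pixels are scored
#' @export
foreground_mask <- function(gt) {
  assert_binary_map(gt)
  mask <- gt == 1
  if (!any(mask)) stop("empty foreground: ground truth has no 1-pixels",
                       call. = FALSE)
  mask
}

#' Contingency table of a predicted vs. true segmentation
#'
#' Counts in-mask pixels jointly by (predicted segment, true segment).
#' The table is the sufficient statistic for every region-based score in
#' this package: with `N` in-mask pixels and counts `n_ij`, the joint
#' distribution is `p_ij = n_ij / N` with marginals `s_i` (predicted)
#' and `t_j` (true). Storage is sparse -- one row per occupied label
#' pair -- because the singleton convention for border pixels creates
#' many one-pixel segments.
#'
#' @param pred,truth label matrices (positive integers = segment ids,
#'   0 = unlabeled). `truth` must be positive everywhere inside `mask`.
#' @param mask logical matrix selecting the pixels to count.
#' @return An object of class `contingency_table`: a list with
#'   `counts` (data.frame with columns `pred`, `truth`, `n`) and `N`.
#' @seealso [rand_scores()], [info_scores()], [foreground_mask()]
#' @export
build_contingency <- function(pred, truth, mask) {
  assert_label_image(pred)
  assert_label_image(truth)
  assert_same_dim(pred, truth, "pred and truth")
  assert_same_dim(pred, mask, "labels and mask")
  if (!is.logical(mask)) stop("`mask` must be a logical matrix", call. = FALSE)
  if (!any(mask)) stop("empty mask: no pixels to score", call. = FALSE)
  i <- as.integer(pred[mask])
  j <- as.integer(truth[mask])
  if (any(j == 0L))
    stop("truth label 0 inside evaluation mask", call. = FALSE)
  if (any(i == 0L))
    stop("pred label 0 inside evaluation mask; segment the full image first",
         call. = FALSE)
  # aggregate sparse (i, j) pairs without materializing the dense table;
  # keys in double precision: label products can exceed .Machine$integer.max
  base <- max(j) + 1
  key <- as.numeric(i) * base + j
  u <- sort(unique(key))
  n <- tabulate(match(key, u), nbins = length(u))
  ui <- as.integer(floor(u / base))
  uj <- as.integer(u - floor(u / base) * base)
  structure(
    list(counts = data.frame(pred = ui, truth = uj, n = n), N = length(i)),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("contingency table: %d occupied label pairs, N = %d pixels\n",
              nrow(x$counts), x$N))
  cat(sprintf("  %d predicted segments vs %d true segments\n",
              length(unique(x$counts$pred)), length(unique(x$counts$truth))))
  invisible(x)
}

# Joint and marginal distributions of a contingency table.
# Returns p (vector over occupied pairs), s (per predicted segment),
# t (per true segment); all sum to 1.
ct_distributions <- function(ct) {
  stopifnot(inherits(ct, "contingency_table"))
  p <- ct$counts$n / ct$N
  s <- tapply(p, ct$counts$pred, sum)
  t <- tapply(p, ct$counts$truth, sum)
  list(p = p, s = as.numeric(s), t = as.numeric(t))
}
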