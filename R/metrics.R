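#' @rdname rand_scores
#' @export
metric_result <- function(split, merge, fscore, alpha,
                          degenerate_flags = character()) {
  structure(
    list(split = split, merge = merge, fscore = fscore, alpha = alpha,
         degenerate_flags = degenerate_flags),
    class = "metric_result"
  )
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("split = %.6f  merge = %.6f  F(alpha=%g) = %.6f\n",
              x$split, x$merge, x$alpha, x$fscore))
  if (length(x$degenerate_flags))
    cat("  degenerate:", paste(x$degenerate_flags, collapse = ", "), "\n")
  invisible(x)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Rand split, merge and F-scores
#'
#' With joint pixel distribution `p_ij` over (predicted, true) segment
#' pairs and marginals `s_i`, `t_j`, the quantity `sum(p_ij^2)` is the
#' probability that two randomly chosen in-mask pixels fall in the same
#' segment of both segmentations. Normalizing it gives
#' \deqn{split = \sum p_{ij}^2 / \sum t_j^2,\quad
#'       merge = \sum p_{ij}^2 / \sum s_i^2,}
#' the probabilities that a pair co-clustered in the truth is
#' co-clustered in the prediction (fewer split errors means higher
#' split score) and vice versa (fewer merge errors means higher merge
#' score). They are precision and recall on pixel pairs. The F-score is
#' their weighted harmonic mean,
#' `fscore = sum(p^2) / (alpha * sum(s^2) + (1 - alpha) * sum(t^2))`,
#' so `alpha = 0` recovers the split score and `alpha = 1` the merge
#' score; `alpha = 0.5` weights both error types equally.
#'
#' @param ct a [build_contingency()] table.
#' @param alpha weight in `[0, 1]` on merge errors (default 0.5).
#' @param split,merge,fscore,degenerate_flags components, for the
#'   `metric_result` constructor.
#' @return A `metric_result` with fields `split`, `merge`, `fscore`,
#'   `alpha`, `degenerate_flags`; all scores in `[0, 1]`.
#' @export
rand_scores <- function(ct, alpha = 0.5) {
  stopifnot(inherits(ct, "contingency_table"))
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]", call. = FALSE)
  # work on integer counts (exact in doubles up to 2^53; the N^2 of the
  # probability normalization cancels in every ratio) and sum sorted
  # values, so a one-to-one table yields scores of exactly 1
  cn <- count_sums(ct)
  sp2 <- sum_sorted(cn$n^2)
  ss2 <- sum_sorted(cn$ns^2)
  st2 <- sum_sorted(cn$nt^2)
  metric_result(
    split  = sp2 / st2,
    merge  = sp2 / ss2,
    fscore = sp2 / (alpha * ss2 + (1 - alpha) * st2),
    alpha  = alpha
  )
}

# joint counts and integer marginal count sums of a contingency table
count_sums <- function(ct) {
  n <- as.numeric(ct$counts$n)
  list(n = n,
       ns = as.numeric(tapply(n, ct$counts$pred, sum)),
       nt = as.numeric(tapply(n, ct$counts$truth, sum)))
}

# order-independent summation: identical multisets give identical sums
sum_sorted <- function(x) sum(sort(x))

#' Information-theoretic split, merge and F-scores
#'
#' The mutual information between the predicted and true segment of a
#' random in-mask pixel,
#' `I(S;T) = sum(p log p) - sum(s log s) - sum(t log t)`, is normalized
#' by the partition entropies: `split = I / H(S)` is the fraction of
#' information in the prediction explained by the truth (low when the
#' prediction fragments true objects), `merge = I / H(T)` the fraction
#' of information in the truth recovered by the prediction (low when
#' objects are fused). The F-score is the weighted harmonic mean
#' `I / ((1 - alpha) * H(S) + alpha * H(T))`; `alpha = 0` and `1` give
#' the split and merge scores. All ratios are invariant to the
#' logarithm base (natural log is used internally).
#'
#' Degenerate partitions: if `H(S) = 0` (one predicted segment covers
#' the mask) then `I = 0`; the split score is set to 1 -- a single
#' segment asserts no false splits -- and the flag `zero_entropy_pred`
#' is recorded; symmetrically for `H(T) = 0` with `zero_entropy_truth`.
#' The F-score is always evaluated from its defining ratio, so an
#' all-merged prediction degrades to `fscore = 0` at `alpha = 0.5`;
#' only when both entropies vanish (both partitions trivial and
#' identical) is `fscore = 1`.
#'
#' @inheritParams rand_scores
#' @return A `metric_result`; see [rand_scores()].
#' @export
info_scores <- function(ct, alpha = 0.5) {
  stopifnot(inherits(ct, "contingency_table"))
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]", call. = FALSE)
  cn <- count_sums(ct)
  N <- ct$N
  # entropies in count form: H = log N - sum(n log n) / N, with sorted
  # summation so a one-to-one table gives I = H(S) = H(T) exactly
  hs <- log(N) - sum_sorted(cn$ns * log(cn$ns)) / N
  ht <- log(N) - sum_sorted(cn$nt * log(cn$nt)) / N
  hj <- log(N) - sum_sorted(cn$n * log(cn$n)) / N
  pred_trivial  <- length(cn$ns) == 1L
  truth_trivial <- length(cn$nt) == 1L
  if (pred_trivial) hs <- 0
  if (truth_trivial) ht <- 0
  # I(S;T) = H(S) + H(T) - H(S,T)
  info <- if (pred_trivial || truth_trivial) 0 else hs + ht - hj
  info <- min(max(info, 0), min(hs, ht))  # clip floating-point residue
  flags <- c(if (pred_trivial) "zero_entropy_pred",
             if (truth_trivial) "zero_entropy_truth")
  denom <- (1 - alpha) * hs + alpha * ht
  metric_result(
    split  = if (pred_trivial) 1 else clamp01(info / hs),
    merge  = if (truth_trivial) 1 else clamp01(info / ht),
    fscore = if (denom == 0) 1 else clamp01(info / denom),
    alpha  = alpha,
    degenerate_flags = as.character(flags)
  )
}

#' Pixel error between two boundary maps
#'
#' Fraction of pixels whose binary boundary label disagrees. This is the
#' naive baseline: it ignores the segmentation consequences of a
#' mistake, so a one-pixel gap that merges two cells costs almost
#' nothing while a harmless border shift costs a lot. Region scores
#' ([rand_scores()], [info_scores()]) exist to fix exactly that.
#'
#' @param pred,gt binary matrices of equal dimension.
#' @return A number in `[0, 1]`.
#' @export
pixel_error <- function(pred, gt) {
  assert_binary_map(pred)
  assert_binary_map(gt)
  assert_same_dim(pred, gt, "pred and gt")
  mean(pred != gt)
}
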