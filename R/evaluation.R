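#' Scoring pipeline configuration
#'
#' Collects the knobs of the scoring pipeline in one record so that
#' every report can state exactly how it was produced.
#'
#' @param foreground_restricted exclude ground-truth border pixels from
#'   the evaluation mask (default `TRUE`, the challenge convention).
#' @param thin apply [thin_borders()] to the prediction before scoring
#'   (default `FALSE`; the historical official score is unthinned).
#' @param connectivity 4 or 8, for components and thinning.
#' @param alpha split/merge weight of the F-scores, in `[0, 1]`.
#' @param threshold optional binarization threshold for probabilistic
#'   boundary maps (`pixel >= threshold` becomes 1).
#' @return A list of class `score_config`.
#' @export
score_config <- function(foreground_restricted = TRUE, thin = FALSE,
                         connectivity = 4, alpha = 0.5, threshold = NULL) {
  connectivity <- assert_connectivity(connectivity)
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]", call. = FALSE)
  if (!is.null(threshold) && (threshold < 0 || threshold > 1))
    stop("`threshold` must be in [0, 1]", call. = FALSE)
  structure(
    list(foreground_restricted = isTRUE(foreground_restricted),
         thin = isTRUE(thin), connectivity = connectivity,
         alpha = alpha, threshold = threshold),
    class = "score_config"
  )
}

#' Score one predicted boundary map against ground truth
#'
#' Runs the full per-image pipeline: optionally thin the prediction,
#' convert both maps to segmentations (border pixels as singleton
#' segments), build the foreground-restricted contingency table, and
#' compute Rand and information-theoretic split/merge/F-scores plus the
#' baseline pixel error.
#'
#' @param pred,gt binary boundary maps of equal dimension.
#' @param config a [score_config()].
#' @return A list of class `pair_score` with elements `rand` and `info`
#'   (each a `metric_result`), `pixel_error` (computed on the map as
#'   scored, i.e. after thinning when enabled), and `config`.
#' @examples
#' gt <- matrix(c(1, 1, 0, 1), 4, 4, byrow = TRUE)
#' score_pair(gt, gt)$rand$fscore                  # 1: perfect
#' score_pair(matrix(1, 4, 4), gt)$rand$fscore     # 5/7: all merged
#' @export
score_pair <- function(pred, gt, config = score_config()) {
  assert_binary_map(pred)
  assert_binary_map(gt)
  assert_same_dim(pred, gt, "pred and gt")
  stopifnot(inherits(config, "score_config"))
  scored <- if (config$thin) thin_borders(pred, config$connectivity) else pred
  seg_pred <- segment_boundary_map(scored, config$connectivity)
  seg_gt <- segment_boundary_map(gt, config$connectivity)
  mask <- if (config$foreground_restricted) foreground_mask(gt)
          else matrix(TRUE, nrow(gt), ncol(gt))
  ct <- build_contingency(seg_pred, seg_gt, mask)
  structure(
    list(rand = rand_scores(ct, config$alpha),
         info = info_scores(ct, config$alpha),
         pixel_error = pixel_error(scored, gt),
         config = config),
    class = "pair_score"
  )
}

#' Score a stack of images slice by slice
#'
#' Each slice is scored independently with [score_pair()] (the
#' challenge scored 2D sections, not the 3D volume) and the per-slice
#' F-scores are aggregated as mean plus standard error
#' (`sd / sqrt(n)`), the uncertainty attached to every reported score.
#'
#' @param preds,gts equal-length lists of dimension-matched binary maps.
#' @inheritParams score_pair
#' @return An object of class `score_report`: `per_image` (data.frame
#'   with columns slice, metric, split, merge, fscore, pixel_error),
#'   `summary` (metric, mean, stderr, n), and `config`.
#' @export
score_stack <- function(preds, gts, config = score_config()) {
  if (!is.list(preds) || !is.list(gts))
    stop("`preds` and `gts` must be lists of matrices", call. = FALSE)
  if (length(preds) != length(gts))
    stop(sprintf("stack length mismatch: %d predictions vs %d ground truths",
                 length(preds), length(gts)), call. = FALSE)
  if (length(preds) == 0) stop("empty stack", call. = FALSE)
  rows <- vector("list", length(preds))
  for (k in seq_along(preds)) {
    ps <- score_pair(preds[[k]], gts[[k]], config)
    rows[[k]] <- data.frame(
      slice = k,
      metric = c("rand", "info"),
      split = c(ps$rand$split, ps$info$split),
      merge = c(ps$rand$merge, ps$info$merge),
      fscore = c(ps$rand$fscore, ps$info$fscore),
      pixel_error = ps$pixel_error
    )
  }
  per_image <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(c("rand", "info"), function(m) {
    f <- per_image$fscore[per_image$metric == m]
    data.frame(metric = m, mean = mean(f),
               stderr = if (length(f) > 1) sd(f) / sqrt(length(f)) else 0,
               n = length(f))
  }))
  structure(list(per_image = per_image, summary = summ, config = config),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("score report over %d slice(s) (%s, %s)\n",
              max(x$per_image$slice),
              if (x$config$thin) "thinned" else "raw",
              if (x$config$foreground_restricted)
                "foreground-restricted" else "unrestricted"))
  for (k in seq_len(nrow(x$summary)))
    cat(sprintf("  %s F-score: %.4f +/- %.4f (stderr, n = %d)\n",
                x$summary$metric[k], x$summary$mean[k],
                x$summary$stderr[k], x$summary$n[k]))
  invisible(x)
}

#' Threshold sweep for probabilistic boundary maps
#'
#' A probabilistic boundary map (values in `[0, 1]`, higher = more
#' interior-like) is binarized at each threshold (`pixel >= t` becomes
#' 1) and the stack scored; the curve of (split, merge) points traces
#' the submission's operating characteristic, and the point maximizing
#' the Rand F-score is the score a probabilistic submission receives.
#'
#' @param probs list of probability matrices.
#' @param gts list of binary ground-truth maps.
#' @param thresholds increasing vector of thresholds in `[0, 1]`.
#' @inheritParams score_pair
#' @return An object of class `sweep_curve`: `points` (data.frame with
#'   threshold and both families' split/merge/fscore means), `best`
#'   (the row index maximizing `rand_fscore`), and `config`.
#' @export
threshold_sweep <- function(probs, gts,
                            thresholds = seq(0.01, 0.99, by = 0.01),
                            config = score_config()) {
  if (length(thresholds) == 0) stop("empty threshold list", call. = FALSE)
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing", call. = FALSE)
  lapply(probs, assert_prob_map)
  pts <- lapply(thresholds, function(t) {
    bin <- lapply(probs, function(m) (m >= t) + 0)
    rep_ <- score_stack(bin, gts, config)
    s <- rep_$summary
    pi <- rep_$per_image
    data.frame(
      threshold = t,
      rand_split = mean(pi$split[pi$metric == "rand"]),
      rand_merge = mean(pi$merge[pi$metric == "rand"]),
      rand_fscore = s$mean[s$metric == "rand"],
      info_split = mean(pi$split[pi$metric == "info"]),
      info_merge = mean(pi$merge[pi$metric == "info"]),
      info_fscore = s$mean[s$metric == "info"]
    )
  })
  points <- do.call(rbind, pts)
  structure(list(points = points,
                 best = which.max(points$rand_fscore),
                 config = config),
            class = "sweep_curve")
}

#' @export
print.sweep_curve <- function(x, ...) {
  b <- x$points[x$best, ]
  cat(sprintf("threshold sweep over %d points; best Rand F = %.4f at t = %g\n",
              nrow(x$points), b$rand_fscore, b$threshold))
  invisible(x)
}

#' Spearman rank-order correlation between two score vectors
#'
#' Pearson correlation of the (average-tie) ranks; used to compare the
#' rankings induced by two scoring variants over the same submissions.
#'
#' @param scores_a,scores_b numeric vectors of equal length `>= 3`.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rank <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must have equal length", call. = FALSE)
  if (length(scores_a) < 3)
    stop("need at least 3 paired scores", call. = FALSE)
  if (length(unique(scores_a)) == 1 || length(unique(scores_b)) == 1)
    stop("constant scores: rank correlation undefined", call. = FALSE)
  cor(scores_a, scores_b, method = "spearman")
}

#' Paired Wilcoxon signed-rank test on per-image scores
#'
#' Two-sided test of whether two submissions differ on the same slices.
#' Zero differences are dropped. For `n <= 12` remaining pairs the
#' p-value is exact, by enumeration of all `2^n` sign assignments of
#' the (average-tie) ranks -- at challenge scale (10-30 slices, many
#' tied score differences) the exact distribution matters. Larger `n`
#' uses the normal approximation with tie correction and continuity
#' correction.
#'
#' @param per_image_a,per_image_b paired numeric vectors (e.g. per-slice
#'   F-scores of two submissions).
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(per_image_a, per_image_b) {
  if (length(per_image_a) != length(per_image_b))
    stop("paired vectors must have equal length", call. = FALSE)
  d <- per_image_a - per_image_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences zero", call. = FALSE)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    p <- 2 * min(mean(w_all <= w), mean(w_all >= w))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
    z <- (w - mu - sign(w - mu) * 0.5) / sigma
    p <- 2 * pnorm(-abs(z))
  }
  min(p, 1)
}

#' Rank submissions on a shared ground truth
#'
#' Scores every submission raw and thinned with both metric families
#' and ranks by the raw Rand F-score -- the historical official
#' challenge ranking -- with ties broken alphabetically by submission
#' name so the ordering is deterministic.
#'
#' @param submissions named list; each element a list of binary
#'   boundary maps (one stack per submission).
#' @param gts list of ground-truth boundary maps.
#' @inheritParams score_pair
#' @return A data.frame sorted by rank with per-metric means and
#'   standard errors, raw and thinned.
#' @export
leaderboard <- function(submissions, gts, config = score_config()) {
  if (length(submissions) < 1) stop("need at least one submission",
                                    call. = FALSE)
  nms <- names(submissions)
  if (is.null(nms) || any(nms == ""))
    stop("`submissions` must be a fully named list", call. = FALSE)
  raw_cfg <- config; raw_cfg$thin <- FALSE
  thin_cfg <- config; thin_cfg$thin <- TRUE
  rows <- lapply(nms, function(nm) {
    raw <- score_stack(submissions[[nm]], gts, raw_cfg)$summary
    thn <- score_stack(submissions[[nm]], gts, thin_cfg)$summary
    g <- function(s, m, col) s[[col]][s$metric == m]
    data.frame(
      submission = nm,
      rand_fscore = g(raw, "rand", "mean"),
      rand_stderr = g(raw, "rand", "stderr"),
      info_fscore = g(raw, "info", "mean"),
      info_stderr = g(raw, "info", "stderr"),
      rand_fscore_thinned = g(thn, "rand", "mean"),
      info_fscore_thinned = g(thn, "info", "mean")
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$rand_fscore, out$submission), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
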