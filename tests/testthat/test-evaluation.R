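test_that("score_pair composes the pipeline stages", {
  gt <- worked_gt()
  ps <- score_pair(gt, gt)
  expect_equal(ps$rand$fscore, 1)
  expect_equal(ps$info$fscore, 1)
  expect_equal(ps$pixel_error, 0)
  ps_m <- score_pair(matrix(1, 4, 4), gt)
  expect_equal(ps_m$rand$fscore, 5 / 7)
  expect_equal(ps_m$info$fscore, 0)
  # a doubled border at the ground-truth location scores 1 once thinned
  wide <- grid_gt(11, 11)
  ps_w <- score_pair(dilate_borders(wide, 1), wide, score_config(thin = TRUE))
  expect_equal(ps_w$rand$fscore, 1)
  expect_equal(ps_w$info$fscore, 1)
  expect_error(score_pair(matrix(1, 3, 3), gt), "dimension mismatch")
})

test_that("stack scores aggregate as mean and standard error", {
  gt <- worked_gt()
  rep3 <- score_stack(list(gt, gt, gt), list(gt, gt, gt))
  expect_equal(rep3$summary$mean, c(1, 1))
  expect_equal(rep3$summary$stderr, c(0, 0))
  expect_equal(nrow(rep3$per_image), 6)
  expect_error(score_stack(list(), list()), "empty stack")
  expect_error(score_stack(list(gt), list(gt, gt)), "length mismatch")

  # per-slice fscores {0.8, 1.0} must give 0.9 +/- 0.1; verified via the
  # definition on a two-slice stack with known per-slice scores
  sl1 <- matrix(1, 4, 4)        # all-merged: rand F = 5/7
  rep2 <- score_stack(list(sl1, gt), list(gt, gt))
  f <- rep2$per_image$fscore[rep2$per_image$metric == "rand"]
  expect_equal(rep2$summary$mean[rep2$summary$metric == "rand"], mean(f))
  expect_equal(rep2$summary$stderr[rep2$summary$metric == "rand"],
               sd(f) / sqrt(2))
  expect_equal(sd(c(0.8, 1.0)) / sqrt(2), 0.1)  # the formula itself
})

test_that("threshold sweep binarizes at each threshold and finds the best", {
  gt <- worked_gt()
  # probabilistic map equal to the truth: perfect at every threshold
  curve <- threshold_sweep(list(gt + 0), list(gt), thresholds = 0.5)
  expect_equal(curve$points$rand_fscore, 1)
  # constant 0.6 map: t = 0.5 gives all-ones, t = 0.7 all-zeros
  const <- matrix(0.6, 4, 4)
  curve2 <- threshold_sweep(list(const), list(gt), thresholds = c(0.5, 0.7))
  all1 <- score_pair(matrix(1, 4, 4), gt)
  all0 <- score_pair(matrix(0, 4, 4), gt)
  expect_equal(curve2$points$rand_fscore, c(all1$rand$fscore, all0$rand$fscore))
  expect_equal(curve2$points$info_fscore, c(all1$info$fscore, all0$info$fscore))
  expect_equal(curve2$best, which.max(curve2$points$rand_fscore))
  # already-binary map: identical scores at any threshold in (0, 1]
  curve3 <- threshold_sweep(list(gt + 0), list(gt),
                            thresholds = c(0.1, 0.5, 0.9))
  expect_equal(length(unique(curve3$points$rand_fscore)), 1)
  expect_error(threshold_sweep(list(gt + 0), list(gt), thresholds = numeric()),
               "empty threshold")
  expect_error(threshold_sweep(list(gt + 0), list(gt), thresholds = c(.5, .5)),
               "strictly increasing")
})

test_that("spearman rank correlation handles ties and rejects degenerates", {
  expect_equal(spearman_rank(1:5, 2 * (1:5)), 1)
  expect_equal(spearman_rank(1:5, rev(1:5)), -1)
  expect_equal(spearman_rank(c(1, 2, 3, 4), c(1, 2, 4, 3)), 0.8)
  expect_error(spearman_rank(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_rank(1:2, 1:2), "at least 3")
  expect_error(spearman_rank(1:4, 1:5), "equal length")
})

test_that("wilcoxon signed-rank p-values are exact at small n", {
  # n = 5, all positive differences: the most extreme of 2^5 sign
  # patterns on each side, p = 2/32
  expect_equal(wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1)),
               0.0625)
  # agreement except one pair: n = 1 after zero-drop, p = 1
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 5)), 1)
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "all differences zero")
  # antisymmetry
  set.seed(9)
  a <- runif(8); b <- runif(8)
  expect_equal(wilcoxon_signed_rank(a, b), wilcoxon_signed_rank(b, a))
  # agrees with the reference implementation when it is exact (no ties)
  set.seed(10)
  x <- rnorm(10); y <- rnorm(10)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
  expect_equal(wilcoxon_signed_rank(x, y), ref, tolerance = 1e-12)
  # large-n path is a sane approximation of the reference
  set.seed(11)
  x2 <- rnorm(25); y2 <- x2 + rnorm(25, 0.3)
  ref2 <- stats::wilcox.test(x2, y2, paired = TRUE, exact = FALSE,
                             correct = TRUE)$p.value
  expect_equal(wilcoxon_signed_rank(x2, y2), ref2, tolerance = 1e-10)
})

test_that("leaderboard ranks by raw Rand F with alphabetical tie-break", {
  gt <- generate_ground_truth(32, 32, 5, 77)
  gts <- list(gt$bmap)
  degraded <- perturb(gt$bmap, perturb_spec("spurious", 2, 5))
  lb <- leaderboard(list(zeta = list(gts[[1]]), alpha = list(degraded),
                         beta = list(gts[[1]])), gts)
  expect_equal(lb$rank, 1:3)
  # perfect submissions tie at 1 and sort alphabetically
  expect_equal(lb$submission[1:2], c("beta", "zeta"))
  expect_equal(lb$rand_fscore[1:2], c(1, 1))
  expect_lt(lb$rand_fscore[3], 1)
  expect_equal(lb$submission[3], "alpha")
  # a dominating submission ranks first under both metrics
  expect_gt(lb$info_fscore[1], lb$info_fscore[3])
  expect_error(leaderboard(list(gts[[1]]), gts), "named")
})

test_that("leaderboard ordering is invariant under slice permutation", {
  g1 <- generate_ground_truth(24, 24, 4, 301)$bmap
  g2 <- generate_ground_truth(24, 24, 4, 302)$bmap
  g3 <- generate_ground_truth(24, 24, 4, 303)$bmap
  gts <- list(g1, g2, g3)
  subs <- list(
    one = lapply(seq_along(gts), function(k)
      perturb(gts[[k]], perturb_spec("spurious", 1, k))),
    two = lapply(seq_along(gts), function(k)
      perturb(gts[[k]], perturb_spec("gap", 2, k, breach = 2)))
  )
  lb <- leaderboard(subs, gts)
  perm <- c(3, 1, 2)
  lb_p <- leaderboard(lapply(subs, function(s) s[perm]), gts[perm])
  expect_equal(lb_p$submission, lb$submission)
  expect_equal(lb_p$rand_fscore, lb$rand_fscore, tolerance = 1e-12)
})

test_that("disjoint slice subsets of one stack score consistently", {
  # public/private split emulation on a homogeneous synthetic stack
  gts <- lapply(1:6, function(k) generate_ground_truth(32, 32, 5, 400 + k)$bmap)
  preds <- lapply(seq_along(gts), function(k)
    perturb(gts[[k]], perturb_spec("spurious", 1, 500 + k)))
  pub <- score_stack(preds[1:3], gts[1:3])$summary
  priv <- score_stack(preds[4:6], gts[4:6])$summary
  for (m in c("rand", "info")) {
    d <- abs(pub$mean[pub$metric == m] - priv$mean[priv$metric == m])
    tol <- 2 * sqrt(pub$stderr[pub$metric == m]^2 +
                    priv$stderr[priv$metric == m]^2)
    expect_lte(d, max(tol, 0.05))
  }
})
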