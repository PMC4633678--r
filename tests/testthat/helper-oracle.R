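# Independent oracles, deliberately naive: everything is recomputed by
# brute force straight from the definitions, never through the package's
# contingency-table path.

# Pair-counting oracle: enumerate all N^2 ordered in-mask pixel pairs.
# Returns the probabilities that a random pair agrees in pred, in truth,
# and in both, plus precision/recall of "same segment" pair classification.
pair_oracle <- function(pred, truth, mask) {
  i <- pred[mask]
  j <- truth[mask]
  same_pred <- outer(i, i, "==")
  same_truth <- outer(j, j, "==")
  both <- same_pred & same_truth
  list(
    sum_p2 = mean(both),
    sum_s2 = mean(same_pred),
    sum_t2 = mean(same_truth),
    precision = sum(both) / sum(same_pred),
    recall = sum(both) / sum(same_truth)
  )
}

# Direct-count entropy oracle (base-e by default).
entropy_oracle <- function(pred, truth, mask, base = exp(1)) {
  i <- pred[mask]
  j <- truth[mask]
  N <- length(i)
  pj <- as.vector(table(paste(i, j))) / N
  ps <- as.vector(table(i)) / N
  pt <- as.vector(table(j)) / N
  H <- function(p) -sum(p * log(p, base = base))
  hs <- H(ps); ht <- H(pt); hj <- H(pj)
  list(hs = hs, ht = ht, I = hs + ht - hj)
}

# Oracle-side score recomputation from the definitions.
rand_oracle <- function(pred, truth, mask, alpha = 0.5) {
  o <- pair_oracle(pred, truth, mask)
  list(split = o$sum_p2 / o$sum_t2,
       merge = o$sum_p2 / o$sum_s2,
       fscore = o$sum_p2 / (alpha * o$sum_s2 + (1 - alpha) * o$sum_t2))
}

info_oracle <- function(pred, truth, mask, alpha = 0.5, base = exp(1)) {
  e <- entropy_oracle(pred, truth, mask, base = base)
  list(split = e$I / e$hs,
       merge = e$I / e$ht,
       fscore = e$I / ((1 - alpha) * e$hs + alpha * e$ht))
}

# Foreground-component labels only (no singleton border segments), for
# counting objects in tests.
cc_labels_for_test <- function(m, conn = 4) {
  mm <- m
  storage.mode(mm) <- "integer"
  segeval:::cc_label(mm, as.integer(conn))
}

# Random positive-label image for property tests.
random_labels <- function(nr, nc, k, seed) {
  set.seed(seed)
  matrix(sample.int(k, nr * nc, replace = TRUE), nr, nc)
}

# Random contingency table via the package constructor on random labels.
random_table <- function(seed, nr = 8, nc = 8, kp = 4, kt = 3) {
  pred <- random_labels(nr, nc, kp, seed)
  truth <- random_labels(nr, nc, kt, seed + 10000)
  build_contingency(pred, truth, matrix(TRUE, nr, nc))
}

# The 4x4 two-segment worked example: ground truth with a one-pixel
# vertical border, foreground segments of 8 and 4 pixels.
worked_gt <- function() matrix(rep(c(1, 1, 0, 1), 4), 4, 4, byrow = TRUE)

# An axis-aligned 2x2 grid of rectangular cells with one-pixel borders
# (all borders horizontal/vertical, so thinning can reposition them
# exactly).
grid_gt <- function(nr = 11, nc = 11) {
  m <- matrix(1, nr, nc)
  m[(nr + 1) %/% 2, ] <- 0
  m[, (nc + 1) %/% 2] <- 0
  m
}
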