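#' Generate a synthetic ground-truth segmentation and boundary map
#'
#' Emulates a section of densely packed cell cross-sections as a
#' Voronoi tessellation of random seed points: cells are convex,
#' space-filling, and have a realistic spread of sizes, which is all
#' the region metrics see (they are geometry-agnostic, so EM texture is
#' irrelevant). One-pixel borders are drawn between 4-adjacent pixels
#' of different cells and then reduced to a [thin_borders()] fixpoint,
#' so the generated map has exactly `n_cells` foreground segments under
#' 4-connectivity and no removable border pixel. Nearest-seed ties are
#' broken by the lowest seed index. If a draw of seed points yields a
#' degenerate tessellation (a cell without surviving interior), new
#' points are drawn internally and a message is logged.
#'
#' @param height,width image dimensions in pixels.
#' @param n_cells number of cells, `>= 2`.
#' @param rng_seed integer seed; output is deterministic given the seed.
#' @return A list with `labels` (label matrix, borders 0), `bmap` (the
#'   boundary map), and `rng_seed`.
#' @export
generate_ground_truth <- function(height, width, n_cells, rng_seed) {
  if (n_cells < 2) stop("`n_cells` must be >= 2", call. = FALSE)
  if (height * width < 4 * n_cells)
    stop("image too small for every cell to have interior", call. = FALSE)
  with_seed(rng_seed, {
    result <- NULL
    for (attempt in 1:25) {
      idx <- sample.int(height * width, n_cells)
      sr <- (idx - 1) %% height + 1
      sc <- (idx - 1) %/% height + 1
      # squared distance from every pixel to every seed
      pr <- rep(seq_len(height), times = width)
      pc <- rep(seq_len(width), each = height)
      d2 <- outer(pr, sr, function(a, b) (a - b)^2) +
            outer(pc, sc, function(a, b) (a - b)^2)
      vor <- matrix(max.col(-d2, ties.method = "first"), height, width)
      bmap <- matrix(1L, height, width)
      # zero the right/lower pixel of each differing 4-adjacent pair, so
      # no two foreground pixels of different cells stay 4-adjacent
      if (width > 1) {
        h <- vor[, -width] != vor[, -1]
        bmap[, -1][h] <- 0L
      }
      if (height > 1) {
        v <- vor[-height, ] != vor[-1, ]
        bmap[-1, ][v] <- 0L
      }
      bmap <- thin_borders(bmap, 4)
      labels <- cc_label(as_int_matrix(bmap), 4L)
      if (max(labels) == n_cells) {
        result <- list(labels = labels, bmap = bmap, rng_seed = rng_seed)
        break
      }
      message(sprintf(
        "generate_ground_truth: degenerate tessellation (attempt %d), redrawing seeds",
        attempt))
    }
    if (is.null(result))
      stop("could not place ", n_cells,
           " cells with interior; enlarge the image", call. = FALSE)
    result
  })
}

#' Perturbation specification
#'
#' Describes a controlled corruption of a boundary map, one error type
#' at a time: `widen` thickens every border (border-width variation;
#' flips only 1 to 0 near existing borders, and is undone by
#' [thin_borders()]), `gap` opens holes in borders (flips only 0 to 1;
#' induces merge errors), `spurious` draws false border lines across
#' cells (flips only 1 to 0; induces split errors).
#'
#' @param mode one of `"widen"`, `"gap"`, `"spurious"`.
#' @param magnitude integer `>= 1`: dilation radius, number of gaps, or
#'   number of spurious lines.
#' @param rng_seed integer seed for the random placements.
#' @param breach for `gap` only: Chebyshev radius of the opened hole
#'   (default 1, the picked border pixel and its border neighbours).
#'   A hole must be wider than the border it pierces to cause a merge,
#'   so emulating a missed membrane in a wide-border submission needs
#'   `breach` larger than the border radius.
#' @return A list of class `perturb_spec`.
#' @export
perturb_spec <- function(mode = c("widen", "gap", "spurious"),
                         magnitude, rng_seed = 1L, breach = 1L) {
  mode <- match.arg(mode)
  if (magnitude < 1 || magnitude != round(magnitude))
    stop("`magnitude` must be a positive integer", call. = FALSE)
  if (breach < 1 || breach != round(breach))
    stop("`breach` must be a positive integer", call. = FALSE)
  structure(list(mode = mode, magnitude = as.integer(magnitude),
                 rng_seed = as.integer(rng_seed),
                 breach = as.integer(breach)),
            class = "perturb_spec")
}

#' Apply a controlled perturbation to a boundary map
#'
#' @param bmap binary boundary map.
#' @param spec a [perturb_spec()].
#' @return A perturbed binary map; only the flip direction allowed by
#'   the mode occurs (see [perturb_spec()]).
#' @export
perturb <- function(bmap, spec) {
  assert_binary_map(bmap)
  stopifnot(inherits(spec, "perturb_spec"))
  # safe vector sampling (sample() treats a scalar x as 1:x)
  resample <- function(x, n) x[sample.int(length(x), n)]
  if (spec$mode == "widen")
    return(dilate_borders(bmap, spec$magnitude))
  if (spec$mode == "gap") {
    zeros <- which(bmap == 0)
    if (length(zeros) == 0) return(bmap)
    if (spec$magnitude > length(zeros))
      stop("gap magnitude exceeds the number of border pixels", call. = FALSE)
    return(with_seed(spec$rng_seed, {
      out <- bmap
      picks <- resample(zeros, spec$magnitude)
      nr <- nrow(bmap); nc <- ncol(bmap)
      b <- spec$breach
      for (p in picks) {
        r <- (p - 1) %% nr + 1
        c <- (p - 1) %/% nr + 1
        # breach the border: all border pixels within Chebyshev
        # distance `breach` of the picked pixel become foreground
        rs <- max(1, r - b):min(nr, r + b)
        cs <- max(1, c - b):min(nc, c + b)
        blk <- out[rs, cs, drop = FALSE]
        blk[blk == 0] <- 1
        out[rs, cs] <- blk
      }
      out
    }))
  }
  # spurious lines
  lab <- cc_label(as_int_matrix(bmap), 4L)
  k <- max(lab)
  if (k == 0) return(bmap)
  sizes <- tabulate(lab[lab > 0], nbins = k)
  eligible <- which(sizes >= 3)
  if (length(eligible) == 0) return(bmap)
  with_seed(spec$rng_seed, {
    out <- bmap
    for (q in seq_len(spec$magnitude)) {
      cell <- resample(eligible, 1)
      px <- which(lab == cell)
      nr <- nrow(bmap)
      rs <- (px - 1) %% nr + 1
      cs <- (px - 1) %/% nr + 1
      if (runif(1) < 0.5) {             # horizontal cut
        r0 <- resample(unique(rs), 1)
        out[cbind(rs[rs == r0], cs[rs == r0])] <- 0
      } else {                          # vertical cut
        c0 <- resample(unique(cs), 1)
        out[cbind(rs[cs == c0], cs[cs == c0])] <- 0
      }
    }
    out
  })
}

#' Simulate a segmentation challenge and its ranking robustness
#'
#' Builds a synthetic ground-truth stack and `n_teams` submissions that
#' cross segmentation quality (number of gap + spurious-line errors;
#' lower is better) with border width (dilation radius; a nuisance that
#' an ideal score ignores). Every submission is scored with both metric
#' families, raw and after border thinning, and the agreement between
#' the four rankings is summarized by Spearman correlations:
#' rand-vs-info raw, rand-vs-info thinned, rand raw-vs-thinned, and
#' info raw-vs-thinned. Because thinning removes the width nuisance,
#' the first correlation is expected to rise after thinning, and the
#' Rand ranking is expected to be more robust to thinning than the
#' information-theoretic one.
#'
#' @param n_teams number of synthetic teams; must equal
#'   `length(quality_grid) * length(border_width_grid)` and be `>= 5`.
#' @param quality_grid integer error counts per slice (gaps and
#'   spurious lines each), one level per value.
#' @param border_width_grid dilation radii; 0 = borders left at
#'   one-pixel width.
#' @param rng_seed integer seed; the whole experiment is deterministic
#'   given the seed.
#' @param height,width,n_cells,n_slices geometry of the synthetic stack.
#' @param alpha,connectivity scoring parameters.
#' @return An object of class `challenge_sim`: `teams` (data.frame with
#'   quality, width and the four F-scores per team), `correlations`
#'   (named vector of the four Spearman rho), `rng_seed`.
#' @export
simulate_challenge <- function(n_teams = 12,
                               quality_grid = c(1, 3, 6),
                               border_width_grid = c(0, 1, 2, 3),
                               rng_seed = 1L,
                               height = 128, width = 128,
                               n_cells = 10, n_slices = 2,
                               alpha = 0.5, connectivity = 4) {
  if (n_teams < 5) stop("`n_teams` must be >= 5", call. = FALSE)
  grid <- expand.grid(quality = quality_grid, width = border_width_grid)
  if (nrow(grid) != n_teams)
    stop(sprintf("`n_teams` (%d) must equal the quality x width crossing (%d)",
                 n_teams, nrow(grid)), call. = FALSE)
  seeds <- with_seed(rng_seed,
                     sample.int(.Machine$integer.max, 1 + n_teams * n_slices))
  gt <- lapply(seq_len(n_slices), function(k)
    generate_ground_truth(height, width, n_cells, seeds[1] + k))
  gts <- lapply(gt, `[[`, "bmap")
  raw_cfg <- score_config(thin = FALSE, alpha = alpha,
                          connectivity = connectivity)
  thin_cfg <- score_config(thin = TRUE, alpha = alpha,
                           connectivity = connectivity)
  rows <- vector("list", n_teams)
  for (tm in seq_len(n_teams)) {
    q <- grid$quality[tm]; w <- grid$width[tm]
    subm <- vector("list", n_slices)
    for (k in seq_len(n_slices)) {
      # a submission inherits its border width everywhere: false
      # membranes (spurious) are drawn first and widened along with the
      # true ones; missed membranes (gaps) are missed at full width, so
      # the breach is scaled to pierce the widened border
      s0 <- seeds[1 + (tm - 1) * n_slices + k]
      m <- perturb(gts[[k]], perturb_spec("spurious", q, s0))
      if (w >= 1) m <- perturb(m, perturb_spec("widen", w))
      m <- perturb(m, perturb_spec("gap", q, s0 %% 1000003L + 1L,
                                   breach = w + 2L))
      subm[[k]] <- m
    }
    raw <- score_stack(subm, gts, raw_cfg)$summary
    thn <- score_stack(subm, gts, thin_cfg)$summary
    rows[[tm]] <- data.frame(
      team = sprintf("team%02d", tm), quality = q, width = w,
      rand_raw = raw$mean[raw$metric == "rand"],
      info_raw = raw$mean[raw$metric == "info"],
      rand_thinned = thn$mean[thn$metric == "rand"],
      info_thinned = thn$mean[thn$metric == "info"]
    )
  }
  teams <- do.call(rbind, rows)
  correlations <- c(
    rand_info_raw = spearman_rank(teams$rand_raw, teams$info_raw),
    rand_info_thinned = spearman_rank(teams$rand_thinned,
                                      teams$info_thinned),
    rand_raw_thinned = spearman_rank(teams$rand_raw, teams$rand_thinned),
    info_raw_thinned = spearman_rank(teams$info_raw, teams$info_thinned)
  )
  structure(list(teams = teams, correlations = correlations,
                 rng_seed = rng_seed,
                 config = list(quality_grid = quality_grid,
                               border_width_grid = border_width_grid,
                               height = height, width = width,
                               n_cells = n_cells, n_slices = n_slices,
                               alpha = alpha, connectivity = connectivity)),
            class = "challenge_sim")
}

#' @export
print.challenge_sim <- function(x, ...) {
  cat(sprintf("simulated challenge: %d teams, seed %d\n",
              nrow(x$teams), x$rng_seed))
  cat("Spearman rank correlations:\n")
  for (nm in names(x$correlations))
    cat(sprintf("  %-18s %.3f\n", nm, x$correlations[[nm]]))
  invisible(x)
}
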