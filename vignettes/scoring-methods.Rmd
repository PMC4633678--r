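---
title: "Scoring boundary-map segmentations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring boundary-map segmentations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segeval)
```

# The scoring model

`segeval` scores 2D segmentations of densely packed cell cross-sections,
given as binary *boundary maps*: 1 = pixel inside a cell, 0 = border
pixel. Both the prediction and the ground truth are converted to
segmentations by connected-component labeling of 1-pixels; every
0-pixel becomes a one-pixel segment of its own. The singleton convention
matters: a predicted border pixel then disagrees with (almost) every
pixel it is paired with, so drawing borders where there are none is
penalized instead of being absorbed into a neighbouring segment.

All region scores are *foreground restricted*: the contingency table is
accumulated only over pixels that are foreground in the ground truth.
Border placement in the ground truth is partly arbitrary (annotators and
algorithms legitimately disagree about a border's exact pixels), so
ground-truth border pixels are excluded from scoring. The prediction is
*not* masked before segmentation — predicted segments are computed on
the full image and only the pair counting is restricted — because
masking the prediction would let a submission game the score by labeling
everything near a plausible border as border.

From the joint distribution $p_{ij}$ of (predicted segment, true
segment) over in-mask pixels, with marginals $s_i$ and $t_j$:

* **Rand family.** $\sum_{ij} p_{ij}^2$ is the probability that two
  random pixels are co-segmented in both partitions. Normalizing by
  $\sum_j t_j^2$ gives the split score (pair recall), by
  $\sum_i s_i^2$ the merge score (pair precision), and
  $V_\alpha = \sum p_{ij}^2 / (\alpha \sum s_i^2 + (1-\alpha)\sum t_j^2)$
  is their weighted harmonic mean.
* **Information-theoretic family.** The mutual information $I(S;T)$
  normalized by $H(S)$ (split), $H(T)$ (merge), or the weighted mean
  $(1-\alpha)H(S) + \alpha H(T)$ (F-score).

$\alpha$ defaults to 0.5; $\alpha = 0$ and $1$ recover the split and
merge scores in both families — an identity the test suite asserts
exactly, not approximately. The two families react differently to the
same mistakes: a merge of two large segments costs the Rand merge score
a term quadratic in the segment masses, while the information score
loses only an entropy term roughly linear in mass times log-mass; a dust
of singleton segments barely moves $\sum s_i^2$ but inflates $H(S)$ by
about $f \log N$ for singleton fraction $f$. This difference is exactly
why the two leaderboards disagree under border-width variation (below).

## Degenerate partitions

The information ratios are undefined when an entropy is zero. The
conventions, flagged in `degenerate_flags`, are: if $H(S) = 0$ (one
predicted segment covers the whole mask) then $I = 0$ and the split
score is set to 1 — a single segment asserts no false splits — and
symmetrically for $H(T) = 0$. The F-score is always evaluated from its
defining ratio rather than recombined from the two ratios, so an
all-merged prediction correctly degrades to $V_{0.5} = 0$; only when
both entropies vanish (both partitions are the same trivial partition)
is the F-score 1. The Rand denominators contain $\sum s_i^2 \ge 1/N^2$
and need no convention.

# Border thinning

Submissions differ in how wide they draw borders, which is a nuisance:
widening a border between two cells changes no segmentation decision,
yet (because of the singleton convention) converts a band of in-mask
pixels into singletons and drags both scores down — the information
score hardest. `thin_borders()` removes the nuisance: it flips border
pixels back to foreground wherever that cannot connect two distinct
segments, until no flippable pixel remains.

The algorithm labels the foreground once, then runs passes to a
fixpoint. Each pass freezes its frontier — the 0-pixels with at least
one foreground neighbour — and scans it in row-major order; a pixel is
flipped if and only if all of its *current* foreground neighbours carry
one common label, and it adopts that label immediately so later pixels
in the same pass see the update. A pixel whose neighbours carry two
labels is where two segments would meet: it is never flipped, which is
the non-merging guarantee (stated formally: the contingency between the
thinned and original segmentations over the original foreground is
one-to-one; the tests assert it on hundreds of perturbed maps).
Freezing the frontier per pass is deliberate: a naive full-image
sequential scan lets the first flip enable the next, dragging one
segment's frontier across an entire thick border band in a single pass;
frontier passes erode a band evenly from both sides, so symmetric
dilation is undone symmetrically. Within a pass the row-major order
resolves genuinely ambiguous pixels (a two-pixel band between two
segments keeps exactly one border pixel) deterministically.

Two properties are weaker than one might hope, and the tests state them
honestly:

* On *axis-aligned* borders, thinning exactly undoes dilation
  (`thin(dilate(b, r)) == b`). On digitized Voronoi borders — diagonal
  staircases — the restored one-pixel border can sit one pixel off the
  original line and a handful of border-adjacent pixels can end up on
  the other side; no deterministic thinning that has not seen the
  original can phase-lock every staircase. Restoration is therefore
  asserted at partition level (cell count, dominant one-to-one
  correspondence, score recovery to > 0.95) rather than pixel identity.
* Dilation by $r$ can fragment a cell that is locally thinner than
  $2r+1$ (acute Voronoi wedges); the fragments are then genuinely
  distinct input segments that a non-merging thinning must keep apart.
  The round-trip properties are conditioned on thickness accordingly.

"About one pixel wide" is realized as the fixpoint property, not a hard
width bound: at junctions where three cells meet, locally two-pixel zero
sets can remain because every remaining pixel separates two segments.
Spurs — border pixels touching only one segment — are absorbed.

# Pipeline, aggregation, comparisons

`score_pair()` composes the stages in a fixed order: optional thinning
of the prediction, segmentation of both maps, foreground mask from the
ground truth, contingency table, both metric families. `score_stack()`
scores slices independently (the challenge scored 2D sections) and
reports mean ± standard error of the per-slice F-scores; the standard
error convention is a package decision, recorded in the output column
names. `threshold_sweep()` binarizes a probabilistic map at each
threshold (`pixel >= t` is foreground; default grid 0.01–0.99 in steps
of 0.01) and reports the curve plus the Rand-F-maximizing point, which
is the score a probabilistic submission receives. `leaderboard()` ranks
by raw Rand F-score — the historical official ranking — breaking ties
alphabetically, and reports thinned scores alongside.

`wilcoxon_signed_rank()` is exact for up to 12 nonzero paired
differences, by enumerating all $2^n$ sign assignments of the
average-tie ranks. Challenge comparisons involve 10–30 slices with many
tied differences, where the textbook exact distribution (which assumes
no ties) is unavailable and the normal approximation is at its worst,
so enumeration is worth its negligible cost; above $n = 12$ the normal
approximation with tie and continuity correction takes over.
`spearman_rank()` is the Pearson correlation of average-tie ranks and
refuses constant inputs.

# Synthetic data: what it emulates and what it does not

`generate_ground_truth()` produces a Voronoi tessellation of random
seed points: convex, space-filling cells with a realistic size spread,
separated by one-pixel borders reduced to a thinning fixpoint, with
exactly `n_cells` foreground components under 4-connectivity.
Nearest-seed ties break to the lowest seed index; a degenerate draw (a
cell with no surviving interior) is redrawn internally and logged. The
region metrics see only the partition structure, so fidelity to EM
texture, grayscale appearance, or 3D slice-to-slice continuity is
deliberately out of scope: passing tests say the *scoring system*
behaves correctly, not that any segmentation algorithm performs well on
real micrographs. Real ground truth also contains non-convex and
elongated profiles, which the generator does not emulate; none of the
scored properties depend on convexity.

`perturb()` induces the three error types one at a time, each flipping
in only one direction: `widen` (border-width nuisance, 1→0 near
borders), `gap` (missed membrane → merge errors, 0→1 in a Chebyshev
`breach` radius around a border pixel), `spurious` (false membrane →
split errors, 1→0 along a straight line across one cell). A gap's hole
must be wider than the border it pierces — a missed membrane is missed
at whatever width the submission draws — which is why `breach` is a
parameter rather than fixed at 1.

`simulate_challenge()` crosses segmentation quality (gap and spurious
counts per slice) with border width (dilation radius) over synthetic
teams, scores everyone raw and thinned with both families, and reports
the four Spearman correlations between the rankings. The defaults —
128×128 images, 10 cells, 2 slices, qualities {1, 3, 6}, width radii
{0, 1, 2, 3}, hence 12 teams — were chosen once to put the simulation
in the regime the scoring system was designed for: the border strip is
a minority of each cell's mass, so width variation perturbs the Rand
ranking mildly but, through the $f \log N$ entropy inflation, dominates
the information-theoretic ranking. Each team's submission is built as
spurious lines → widening → gaps with `breach = width + 2`; applying
gaps before widening would let the dilation re-close them, quietly
rewarding wide borders with fewer merge errors. Under these conditions
the simulation reproduces the qualitative robustness finding in
essentially every replicate: thinning raises the rank agreement between
the two families (median correlation ≈ 0.75 → 0.95 across 20
replicates), and the Rand ranking is far more robust to thinning than
the information-theoretic ranking (median ≈ 0.8 vs ≈ 0.55). The
absolute correlations depend on the synthetic conditions; only the
direction of both comparisons is asserted.

# Numerical choices

* **Exact identity.** Scores are computed from integer pixel counts
  (exact in doubles far beyond any image size here), with each sum taken
  over sorted values so identical multisets accumulate identically.
  Consequently a segmentation scored against itself returns exactly 1.0
  in all six scores — asserted with `expect_identical` over 100
  generated ground truths — and $\alpha$-endpoint identities are exact.
* **Logarithms.** Natural log internally; every information ratio is
  base-invariant, asserted against a base-2 oracle at 1e-12.
* **Clipping.** $I$ is clipped to $[0, \min(H(S), H(T))]$ and ratios to
  $[0, 1]$ to absorb last-ulp residue; the clip is inert on exact paths.
* **Sparse tables.** The contingency table stores one row per occupied
  label pair; the singleton convention makes dense storage quadratic in
  border length. Pair keys are formed in double precision because label
  products overflow 32-bit integers on large images.
* **Determinism.** Every random routine takes an explicit seed, uses a
  private RNG state (the caller's `.Random.seed` is restored), and logs
  the seed in its output; the CLI's `simulate` subcommand is
  byte-identical for a repeated seed.

# Problem sizes in the test suite

The suite generates everything at run time: 32×32/5-cell ground truths
for the 100-fold identity check, 16×16 label images for the 50-fold
$O(N^2)$ pair-enumeration oracle comparisons, ~200 perturbed 24×24 maps
for thinning safety, and 20 replicate simulated challenges at the
default conditions for the robustness direction. These sizes keep the
full suite under a couple of minutes on one core while leaving every
property's sample size large enough to be meaningful.

# Known limitations

* Scoring is strictly 2D; anisotropic 3D stacks are scored slice by
  slice, and ambiguities inherent to 2D scoring (a membrane parallel to
  the sectioning plane) are outside what any 2D score can resolve.
* The default 4-connectivity is a choice, not a theorem: with
  8-connectivity a one-pixel diagonal border fails to separate segments,
  defeating the boundary-map representation, so 4 is the default for
  foreground components and thinning; 8 remains available.
* Predicted one-pixel segments from the singleton convention are kept
  distinct rather than collapsed; with heavy border noise their count
  is large, which is intended (it is the penalty) but means the
  information scores depend on the image size through $\log N$.
* Thinning's output is deterministic but scan-order dependent at
  genuinely ambiguous pixels; two-pixel bands keep the later pixel in
  row-major order, and staircase borders restore only to partition
  level, as described above.
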