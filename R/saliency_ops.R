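# Deterministic saliency-map operators: top-t% pooling, greedy patch
# selection by mean intensity, patch aggregation, multi-scale fusion.
# These reproduce the map mechanics of globally-aware multiple-instance
# mammography classifiers as standalone, weight-free operators.

#' Top-t% pooling of a saliency map
#'
#' Returns the mean of the largest `ceiling(t/100 * n)` values of the grid
#' (the pooling used to turn a malignancy map into a scalar score; t = 6 in
#' the models this package evaluates). The result always lies between the
#' grid minimum and maximum, is monotone in the grid values, and scales
#' linearly with the grid.
#'
#' @param grid nonempty numeric matrix (values >= 0 for saliency use, though
#'   the operator itself is sign-agnostic).
#' @param t_percent pooling percentage in (0, 100\]; default 6.
#' @return scalar pooled value.
#' @examples
#' top_t_percent_pool(matrix(1:100, 10), 6)  # mean(95:100) = 97.5
#' @export
top_t_percent_pool <- function(grid, t_percent = 6) {
  if (!length(grid)) stop_mc("empty grid", "mc_empty_grid")
  if (t_percent <= 0 || t_percent > 100)
    stop_mc("t_percent must be in (0, 100]", "mc_bad_t")
  k <- ceiling(t_percent / 100 * length(grid))
  mean(sort(as.vector(grid), decreasing = TRUE)[seq_len(k)])
}

# Summed-area table: S[i+1, j+1] = sum of grid[1..i, 1..j]. Internal.
integral_image <- function(grid) {
  s <- grid
  if (nrow(s) > 1) s <- apply(s, 2, cumsum)
  s <- matrix(s, nrow(grid), ncol(grid))
  if (ncol(s) > 1) s <- t(apply(s, 1, cumsum))
  s <- matrix(s, nrow(grid), ncol(grid))
  rbind(0, cbind(0, s))
}

# Mean intensity of every patch position; returns matrix of window means
# with [i, j] = mean over grid[i..i+ph-1, j..j+pw-1]. Internal.
window_means <- function(grid, patch_shape) {
  ph <- patch_shape[1]; pw <- patch_shape[2]
  nr <- nrow(grid) - ph + 1L
  nc <- ncol(grid) - pw + 1L
  s <- integral_image(grid)
  i <- seq_len(nr); j <- seq_len(nc)
  (s[i + ph, j + pw, drop = FALSE] - s[i, j + pw, drop = FALSE] -
      s[i + ph, j, drop = FALSE] + s[i, j, drop = FALSE]) / (ph * pw)
}

#' Greedy patch selection by largest average intensity
#'
#' At each step the patch position with the largest mean intensity under the
#' current grid is chosen, recorded, and its footprint zeroed out
#' (non-maximum suppression by erasure) before the next step. Selection-time
#' mean intensities are therefore non-increasing. Ties (window means equal
#' within a 1e-9 relative tolerance, absorbing summation round-off) break
#' toward the smallest (row, col) in lexicographic order.
#'
#' @param grid numeric matrix, values >= 0.
#' @param K number of patches (3 for the compact-map model, 6 for the
#'   multi-scale model).
#' @param patch_shape integer `c(rows, cols)`; must fit inside the grid.
#' @return data.frame with columns `row`, `col` (0-based top-left corner),
#'   `rows`, `cols` (patch shape) and `mean_intensity` (at selection time).
#' @export
select_patches <- function(grid, K, patch_shape) {
  if (K < 1) stop_mc("K must be >= 1", "mc_bad_k")
  if (any(patch_shape > dim(grid)))
    stop_mc("patch larger than grid", "mc_patch_too_big")
  g <- grid
  out <- vector("list", K)
  for (k in seq_len(K)) {
    wm <- window_means(g, patch_shape)
    best <- max(wm)
    tol <- 1e-9 * max(1, abs(best))
    hits <- which(wm >= best - tol, arr.ind = TRUE)
    # lexicographic (row, col) tie-break
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    out[[k]] <- data.frame(row = i - 1L, col = j - 1L,
                           rows = patch_shape[1], cols = patch_shape[2],
                           mean_intensity = wm[i, j])
    g[i:(i + patch_shape[1] - 1L), j:(j + patch_shape[2] - 1L)] <- 0
  }
  do.call(rbind, out)
}

#' Aggregate patch-level maps onto a full-size canvas
#'
#' Each patch map is placed at its patch position on a zero canvas and the
#' results are combined as a weighted sum; overlapping footprints add.
#' Weighted mass is conserved exactly: the canvas total equals
#' `sum(weights * patch totals)`.
#'
#' @param patches data.frame as returned by [select_patches()] (columns
#'   `row`, `col`, `rows`, `cols`).
#' @param maps list of matrices, one per patch, each of the patch's shape.
#' @param canvas_shape integer `c(rows, cols)`.
#' @param weights non-negative weights summing to 1; uniform by default.
#' @return matrix of dimension `canvas_shape`.
#' @export
aggregate_patch_maps <- function(patches, maps, canvas_shape, weights = NULL) {
  n <- nrow(patches)
  weights <- weights %||% rep(1 / n, n)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop_mc("weights must be >= 0 and sum to 1", "mc_bad_weights")
  canvas <- matrix(0, canvas_shape[1], canvas_shape[2])
  for (k in seq_len(n)) {
    p <- patches[k, ]
    if (p$row < 0 || p$col < 0 || p$row + p$rows > canvas_shape[1] ||
        p$col + p$cols > canvas_shape[2])
      stop_mc("patch footprint outside canvas", "mc_out_of_bounds")
    ri <- (p$row + 1):(p$row + p$rows)
    ci <- (p$col + 1):(p$col + p$cols)
    canvas[ri, ci] <- canvas[ri, ci] + weights[k] * maps[[k]]
  }
  canvas
}

#' Fuse a multi-scale saliency pyramid to the finest scale
#'
#' Coarser maps are bilinearly upsampled (corner-aligned, see
#' [resize_bilinear()]) to the finest grid and the maps averaged with the
#' given weights. The default pyramid is the three-scale layout
#' 184x120 / 92x60 / 46x30 used by the multi-scale model; any strict 2x
#' pyramid is accepted.
#'
#' @param maps list of matrices, finest first; each subsequent map must halve
#'   both dimensions of its predecessor.
#' @param weights weights over scales, >= 0 summing to 1; uniform by default.
#' @return matrix at the finest scale.
#' @export
fuse_multiscale <- function(maps, weights = NULL) {
  n <- length(maps)
  if (n < 1) stop_mc("need at least one map", "mc_empty_pyramid")
  fine <- dim(maps[[1]])
  for (k in seq_len(n)) {
    expected <- fine / 2^(k - 1)
    if (!all(dim(maps[[k]]) == expected))
      stop_mc(sprintf("map %d has shape %dx%d; expected %dx%d (strict 2x pyramid)",
                      k, nrow(maps[[k]]), ncol(maps[[k]]), expected[1], expected[2]),
              "mc_bad_pyramid")
  }
  weights <- weights %||% rep(1 / n, n)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop_mc("weights must be >= 0 and sum to 1", "mc_bad_weights")
  out <- matrix(0, fine[1], fine[2])
  for (k in seq_len(n)) {
    up <- if (k == 1) maps[[k]] else resize_bilinear(maps[[k]], fine)
    out <- out + weights[k] * up
  }
  out
}
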