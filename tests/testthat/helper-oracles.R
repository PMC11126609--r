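# Independent oracles and shared fixtures for the test suite.

# Pixel-counting IoU: rasterize both boxes on an integer grid and count.
iou_raster_oracle <- function(a, b, grid = 20) {
  cells_in <- function(box) {
    m <- matrix(FALSE, grid, grid)
    r <- seq_len(grid) - 1
    inside_r <- r >= box$row_min & r < box$row_max
    inside_c <- r >= box$col_min & r < box$col_max
    m[inside_r, inside_c] <- TRUE
    m
  }
  ma <- cells_in(a); mb <- cells_in(b)
  sum(ma & mb) / sum(ma | mb)
}

# Closed-form Lin's CCC through a different route (sample moments from
# cor/var, rescaled to population moments).
ccc_cor_oracle <- function(x, y) {
  n <- length(x)
  f <- (n - 1) / n
  sx2 <- stats::var(x) * f
  sy2 <- stats::var(y) * f
  sxy <- stats::cov(x, y) * f
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

# Brute-force greedy patch selection: scan every position with loops,
# applying the documented tie rule (equal within 1e-9 relative tolerance
# breaks to the lexicographically smallest position).
greedy_patches_oracle <- function(grid, K, patch_shape) {
  g <- grid
  ph <- patch_shape[1]; pw <- patch_shape[2]
  out <- NULL
  for (k in seq_len(K)) {
    means <- matrix(NA_real_, nrow(g) - ph + 1, ncol(g) - pw + 1)
    for (i in seq_len(nrow(means))) {
      for (j in seq_len(ncol(means))) {
        means[i, j] <- mean(g[i:(i + ph - 1), j:(j + pw - 1)])
      }
    }
    best <- max(means)
    tol <- 1e-9 * max(1, abs(best))
    bi <- bj <- NULL
    for (i in seq_len(nrow(means))) {       # lexicographic scan order
      for (j in seq_len(ncol(means))) {
        if (means[i, j] >= best - tol) { bi <- i; bj <- j; break }
      }
      if (!is.null(bi)) break
    }
    out <- rbind(out, data.frame(row = bi - 1, col = bj - 1,
                                 mean_intensity = means[bi, bj]))
    g[bi:(bi + ph - 1), bj:(bj + pw - 1)] <- 0
  }
  out
}

# Exhaustive one-to-one assignment maximizing total IoU (for small n).
best_assignment_oracle <- function(iou_mat) {
  n <- nrow(iou_mat); m <- ncol(iou_mat)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- -Inf; best_p <- NULL
  for (p in perms(seq_len(m))) {
    tot <- sum(vapply(seq_len(min(n, m)), function(i) iou_mat[i, p[i]], 0))
    if (tot > best) { best <- tot; best_p <- p }
  }
  best_p
}

# Shared expensive fixtures, computed once per test session.
.mc_cache <- new.env(parent = emptyenv())

shared_band_sigmas <- function() {
  if (is.null(.mc_cache$sigmas))
    .mc_cache$sigmas <- calibrate_band_sigmas(seed = 99L)
  .mc_cache$sigmas
}

shared_banded_cohort <- function(uplift = 1) {
  key <- paste0("banded_", uplift)
  if (is.null(.mc_cache[[key]])) {
    cfg <- synth_config(n_cases = 400, jitter_mode = "relative",
                        band_sigmas = shared_band_sigmas(),
                        quality_uplift = uplift, seed = 42L)
    .mc_cache[[key]] <- generate_cohort(cfg)
  }
  .mc_cache[[key]]
}

band_order <- c("almost_perfect", "substantial", "moderate", "poor")
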