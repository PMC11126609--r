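# Saliency-map agreement metrics: histogram intersection (SIM) and the
# regularized Kullback-Leibler divergence (KLD), applicable between two
# saliency maps or between a map and a reader-annotation mask.

#' Normalized histogram of pixel values
#'
#' Counts pixel values into `n_bins` equal-width bins over `value_range` and
#' divides by the pixel count, so the masses sum to exactly 1. Values outside
#' the range are clamped into the edge bins.
#'
#' @param grid nonempty numeric matrix or vector.
#' @param n_bins number of bins (default 256).
#' @param value_range `c(lo, hi)` with `lo < hi`; default `c(0, 1)`.
#' @return object of class `mc_histogram`: list with `masses` (length
#'   `n_bins`, summing to 1) and `bin_edges` (length `n_bins + 1`).
#' @export
to_histogram <- function(grid, n_bins = 256, value_range = c(0, 1)) {
  if (!length(grid)) stop_mc("empty grid", "mc_empty_grid")
  if (n_bins < 1) stop_mc("n_bins must be >= 1", "mc_bad_bins")
  if (value_range[2] <= value_range[1])
    stop_mc("degenerate value_range", "mc_bad_range")
  edges <- seq(value_range[1], value_range[2], length.out = n_bins + 1)
  idx <- findInterval(as.vector(grid), edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n_bins)
  masses <- tabulate(idx, nbins = n_bins) / length(grid)
  structure(list(masses = masses, bin_edges = edges), class = "mc_histogram")
}

#' Normalized spatial distribution on a common grid
#'
#' Converts either a saliency map or a set of annotation boxes into a
#' probability mass function on a spatial grid of shape `common_shape`.
#' Saliency maps are bilinearly resampled (corner-aligned) then divided by
#' their total mass; annotation boxes are rasterized to a binary mask (1 on
#' cells whose center falls inside any box, after scaling the box
#' coordinates to the target grid) and normalized the same way.
#'
#' @param source a numeric matrix (saliency grid), or a data.frame of boxes.
#' @param common_shape integer `c(rows, cols)` of the common grid.
#' @param image_shape required when `source` is a box set: the `c(rows,
#'   cols)` pixel shape the box coordinates refer to.
#' @return matrix of shape `common_shape` with non-negative entries summing
#'   to 1.
#' @export
to_distribution <- function(source, common_shape, image_shape = NULL) {
  if (is.matrix(source)) {
    g <- if (all(dim(source) == common_shape)) source
         else resize_bilinear(source, common_shape)
    g[g < 0] <- 0
  } else if (is.data.frame(source)) {
    if (is.null(image_shape))
      stop_mc("image_shape is required to rasterize annotation boxes",
              "mc_missing_shape")
    g <- rasterize_boxes(source, common_shape, image_shape)
  } else {
    stop_mc("source must be a matrix or a boxes data.frame", "mc_bad_source")
  }
  total <- sum(g)
  if (total <= 0)
    stop_mc("source has zero total mass; distribution undefined", "mc_zero_mass")
  g / total
}

# Binary mask on a target grid: cell (i, j) is 1 when its center, mapped to
# image coordinates, lies inside any half-open box. Internal.
rasterize_boxes <- function(boxes, common_shape, image_shape) {
  g <- matrix(0, common_shape[1], common_shape[2])
  if (!nrow(boxes)) return(g)
  rc <- (seq_len(common_shape[1]) - 0.5) * image_shape[1] / common_shape[1]
  cc <- (seq_len(common_shape[2]) - 0.5) * image_shape[2] / common_shape[2]
  for (k in seq_len(nrow(boxes))) {
    b <- boxes[k, ]
    ri <- rc >= b$row_min & rc < b$row_max
    ci <- cc >= b$col_min & cc < b$col_max
    g[ri, ci] <- 1
  }
  g
}

#' Histogram intersection similarity (SIM)
#'
#' SIM(H1, H2) = sum_i min(H1_i, H2_i) for two normalized histograms (or any
#' two equally shaped normalized mass arrays, e.g. spatial distributions).
#' Symmetric, in \[0, 1\]; 1 iff the distributions coincide, 0 iff their
#' supports are disjoint. Larger values mean more overlap.
#'
#' @param h1,h2 `mc_histogram` objects with identical binning, or numeric
#'   arrays of identical shape with masses summing to 1.
#' @return SIM in \[0, 1\].
#' @export
sim <- function(h1, h2) {
  m1 <- if (inherits(h1, "mc_histogram")) h1$masses else as.vector(h1)
  m2 <- if (inherits(h2, "mc_histogram")) h2$masses else as.vector(h2)
  if (inherits(h1, "mc_histogram") != inherits(h2, "mc_histogram"))
    stop_mc("cannot mix a histogram with a raw array", "mc_binning_mismatch")
  if (inherits(h1, "mc_histogram") &&
      !isTRUE(all.equal(h1$bin_edges, h2$bin_edges, tolerance = 1e-12)))
    stop_mc("histograms have different binning", "mc_binning_mismatch")
  if (length(m1) != length(m2))
    stop_mc("inputs have different sizes", "mc_binning_mismatch")
  sum(pmin(m1, m2))
}

#' Regularized Kullback-Leibler divergence (KLD)
#'
#' KLD(D1, D2) = sum_i D1_i * log(eps + D1_i / (eps + D2_i)) with natural
#' log and regularization constant eps = 1e-10, evaluated exactly in this
#' printed form. Not symmetric, and not exactly zero at D1 = D2 (the
#' regularizer contributes up to about eps times the number of cells).
#' Small values indicate close distributions.
#'
#' @param d1,d2 normalized mass arrays of identical shape (spatial
#'   distributions or histogram masses).
#' @param epsilon regularization constant, default `1e-10`.
#' @return divergence value (>= 0 up to the regularization tolerance).
#' @export
kld <- function(d1, d2, epsilon = 1e-10) {
  m1 <- if (inherits(d1, "mc_histogram")) d1$masses else d1
  m2 <- if (inherits(d2, "mc_histogram")) d2$masses else d2
  if (length(m1) != length(m2) ||
      (is.matrix(m1) && is.matrix(m2) && !all(dim(m1) == dim(m2))))
    stop_mc("distributions are on different grids", "mc_grid_mismatch")
  sum(m1 * log(epsilon + m1 / (epsilon + m2)))
}

#' Per-case saliency agreement table
#'
#' Compares, per cancer case and view, either two models' saliency maps
#' (`mode = "map_vs_map"`: SIM on value histograms, KLD on spatial
#' distributions resampled to the coarser shape) or one model's map against
#' the union of the readers' annotation boxes (`mode = "map_vs_annotation"`:
#' both metrics on spatial distributions).
#'
#' @param maps1 named list (by case id) of per-view saliency map lists.
#' @param maps2 second model's maps (for `map_vs_map`), or `NULL`.
#' @param annotations annotation data.frame (for `map_vs_annotation`).
#' @param image_shape pixel shape that annotation coordinates refer to.
#' @param mode comparison mode.
#' @param n_bins histogram bins for the histogram pathway.
#' @return data.frame with columns `case_id`, `view`, `sim`, `kld`, `mode`.
#' @export
agreement_table <- function(maps1, maps2 = NULL, annotations = NULL,
                            image_shape = NULL,
                            mode = c("map_vs_annotation", "map_vs_map"),
                            n_bins = 256) {
  mode <- match.arg(mode)
  rows <- list()
  for (id in names(maps1)) {
    for (view in names(maps1[[id]])) {
      g1 <- maps1[[id]][[view]]
      if (mode == "map_vs_map") {
        g2 <- maps2[[id]][[view]]
        if (is.null(g2) || sum(g1) <= 0 || sum(g2) <= 0) next
        shape <- pmin(dim(g1), dim(g2))
        vmax <- max(g1, g2, 1e-12)
        s <- sim(to_histogram(g1 / vmax, n_bins), to_histogram(g2 / vmax, n_bins))
        k <- kld(to_distribution(g1, shape), to_distribution(g2, shape))
      } else {
        ref <- annotations[annotations$case_id == id & annotations$view == view, ]
        if (!nrow(ref) || sum(g1) <= 0) next
        d1 <- to_distribution(g1, dim(g1))
        d2 <- to_distribution(ref, dim(g1), image_shape = image_shape)
        s <- sim(d1, d2)
        k <- kld(d1, d2)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(case_id = id, view = view, sim = s, kld = k, mode = mode,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(case_id = character(0), view = character(0),
                      sim = numeric(0), kld = numeric(0), mode = character(0)))
  do.call(rbind, rows)
}
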