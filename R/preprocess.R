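# Image standardization: breast segmentation, tight crop, laterality flip,
# bilinear resize. Matrices are indexed [row, col] with row 1 at the top;
# box coordinates are 0-based half-open pixel indices.

#' Segment the breast region of a mammogram-like image
#'
#' Thresholds the image (Otsu on nonzero pixels by default), keeps the
#' largest connected foreground component, then applies morphological closing
#' and hole filling. The result is a single connected binary mask.
#'
#' @param image 2-D non-negative numeric matrix.
#' @param threshold either `"otsu"` (default: Otsu's threshold over the full
#'   intensity range, separating the dark background from the breast) or a
#'   numeric cutoff; pixels strictly above the cutoff are foreground
#'   candidates.
#' @param closing_radius radius in pixels of the disc structuring element
#'   used for closing (default 5).
#' @return logical matrix, `TRUE` on the breast.
#' @export
segment_breast <- function(image, threshold = "otsu", closing_radius = 5) {
  if (!is.matrix(image) || any(image < 0))
    stop_mc("image must be a non-negative 2-D matrix", "mc_bad_image")
  if (identical(threshold, "otsu")) {
    if (!any(image > 0))
      stop_mc("image has no nonzero pixels; cannot segment", "mc_empty_foreground")
    rng <- range(image)
    th <- if (rng[1] == rng[2]) rng[1] / 2 else
      EBImage::otsu(EBImage::Image(image), range = rng)
  } else {
    th <- threshold
  }
  fg <- image > th
  if (!any(fg))
    stop_mc("thresholding produced an empty foreground", "mc_empty_foreground")
  fg <- largest_component(fg)
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    fg <- as.matrix(EBImage::closing(fg * 1, brush)) > 0
  }
  fg <- as.matrix(EBImage::fillHull(fg * 1)) > 0
  largest_component(fg)
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- as.matrix(lab)
  if (max(lab) < 1) stop_mc("empty mask", "mc_empty_foreground")
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Tightly crop an image to a mask
#'
#' @param image 2-D matrix.
#' @param mask logical matrix of the same shape; must contain at least one
#'   `TRUE` pixel.
#' @return list with `pixels` (the cropped image), `mask` (cropped mask) and
#'   `crop_offset` = `c(row, col)` of the crop origin in 0-based original
#'   coordinates; annotation boxes transform into crop coordinates by
#'   subtracting the offset.
#' @export
crop_to_breast <- function(image, mask) {
  if (!all(dim(image) == dim(mask)))
    stop_mc("image and mask shapes differ", "mc_shape_mismatch")
  if (!any(mask)) stop_mc("mask is empty", "mc_empty_foreground")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  list(pixels = image[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE],
       mask = mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE],
       crop_offset = c(rows[1] - 1, cols[1] - 1))
}

#' Standardize breast laterality
#'
#' Right-side views (RCC, RMLO) are flipped horizontally so the breast sits
#' on the left side of every image; left-side views pass through unchanged.
#' Applying the operation twice is the identity.
#'
#' @param image 2-D matrix.
#' @param view one of `"LCC"`, `"RCC"`, `"LMLO"`, `"RMLO"`.
#' @param boxes optional data.frame of boxes on this view, remapped
#'   consistently via [flip_box()].
#' @return list with `pixels`, `flipped` (logical) and, when supplied,
#'   `boxes`.
#' @export
standardize_orientation <- function(image, view, boxes = NULL) {
  if (!view %in% VIEWS) stop_mc("unknown view", "mc_bad_view")
  flip <- is_right_view(view)
  out <- if (flip) image[, ncol(image):1, drop = FALSE] else image
  res <- list(pixels = out, flipped = flip)
  if (!is.null(boxes)) {
    if (flip && nrow(boxes)) boxes <- flip_box(boxes, ncol(image))
    res$boxes <- boxes
  }
  res
}

#' Bilinear resize with corner-aligned sampling
#'
#' Output pixel (i, j) samples the input at
#' (i (R-1)/(R'-1), j (C-1)/(C'-1)), so the four corners map exactly and a
#' constant image stays constant to machine precision. Output values never
#' overshoot the input range.
#'
#' @param image 2-D numeric matrix.
#' @param target_shape integer `c(rows, cols)`, both >= 1.
#' @return matrix of dimension `target_shape`.
#' @examples
#' resize_bilinear(matrix(c(0, 1, 1, 0), 2, 2), c(3, 3))[2, 2]  # 0.5
#' @export
resize_bilinear <- function(image, target_shape) {
  if (any(target_shape < 1)) stop_mc("target dims must be >= 1", "mc_bad_shape")
  src <- dim(image)
  coord <- function(n_out, n_in) {
    if (n_out == 1) rep(0, 1) else (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  }
  r <- coord(target_shape[1], src[1])
  c_ <- coord(target_shape[2], src[2])
  r0 <- pmin(floor(r), src[1] - 1); fr <- r - r0
  c0 <- pmin(floor(c_), src[2] - 1); fc <- c_ - c0
  r1 <- pmin(r0 + 1, src[1] - 1)
  c1 <- pmin(c0 + 1, src[2] - 1)
  a00 <- image[r0 + 1, c0 + 1, drop = FALSE]
  a01 <- image[r0 + 1, c1 + 1, drop = FALSE]
  a10 <- image[r1 + 1, c0 + 1, drop = FALSE]
  a11 <- image[r1 + 1, c1 + 1, drop = FALSE]
  wr <- matrix(fr, nrow = length(fr), ncol = length(fc))
  wc <- matrix(fc, nrow = length(fr), ncol = length(fc), byrow = TRUE)
  a00 * (1 - wr) * (1 - wc) + a01 * (1 - wr) * wc +
    a10 * wr * (1 - wc) + a11 * wr * wc
}

#' Full standardization pipeline for one view
#'
#' segment -> tight crop -> laterality flip -> bilinear resize, with
#' annotation boxes carried through every coordinate change. Box coordinates
#' after the resize step are continuous (scaled by the corner-aligned
#' mapping), not re-rounded.
#'
#' @param image 2-D matrix.
#' @param view view label.
#' @param boxes optional boxes on this view (original coordinates).
#' @param target_shape `c(rows, cols)` of the standardized image, default
#'   `c(2944, 1920)` (portrait).
#' @param ... passed to [segment_breast()].
#' @return list with `pixels`, `crop_offset`, `flipped`, `target_shape`, and
#'   transformed `boxes` (when supplied).
#' @export
preprocess_view <- function(image, view, boxes = NULL,
                            target_shape = c(2944, 1920), ...) {
  mask <- segment_breast(image, ...)
  cr <- crop_to_breast(image, mask)
  if (!is.null(boxes) && nrow(boxes)) {
    boxes$row_min <- boxes$row_min - cr$crop_offset[1]
    boxes$row_max <- boxes$row_max - cr$crop_offset[1]
    boxes$col_min <- boxes$col_min - cr$crop_offset[2]
    boxes$col_max <- boxes$col_max - cr$crop_offset[2]
  }
  ori <- standardize_orientation(cr$pixels, view, boxes)
  out <- resize_bilinear(ori$pixels, target_shape)
  sc_r <- if (nrow(cr$pixels) > 1) (target_shape[1] - 1) / (nrow(cr$pixels) - 1) else 1
  sc_c <- if (ncol(cr$pixels) > 1) (target_shape[2] - 1) / (ncol(cr$pixels) - 1) else 1
  boxes_out <- ori$boxes
  if (!is.null(boxes_out) && nrow(boxes_out)) {
    boxes_out$row_min <- boxes_out$row_min * sc_r
    boxes_out$row_max <- boxes_out$row_max * sc_r
    boxes_out$col_min <- boxes_out$col_min * sc_c
    boxes_out$col_max <- boxes_out$col_max * sc_c
  }
  list(pixels = out, crop_offset = cr$crop_offset, flipped = ori$flipped,
       target_shape = target_shape, boxes = boxes_out)
}
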