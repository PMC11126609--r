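# Axis-aligned annotation boxes.
#
# Boxes use a 0-based, half-open pixel convention [row_min, row_max) x
# [col_min, col_max), so areas and intersections are integer-exact on rasters.

#' Construct an annotation box
#'
#' @param row_min,col_min,row_max,col_max box corners, 0-based half-open:
#'   the box covers pixel rows `row_min .. row_max - 1` and columns
#'   `col_min .. col_max - 1`.
#' @param case_id,reader,view optional identity fields carried along when the
#'   box belongs to an annotated case.
#' @return a one-row `data.frame` with columns `case_id`, `reader`, `view`,
#'   `row_min`, `col_min`, `row_max`, `col_max`.
#' @examples
#' b <- annotation_box(0, 0, 2, 2)
#' box_area(b)  # 4
#' @export
annotation_box <- function(row_min, col_min, row_max, col_max,
                           case_id = NA_character_, reader = NA_character_,
                           view = NA_character_) {
  if (row_min >= row_max || col_min >= col_max)
    stop_mc("annotation box must have positive area (min < max on both axes)",
            "mc_degenerate_box")
  data.frame(case_id = case_id, reader = reader, view = view,
             row_min = row_min, col_min = col_min,
             row_max = row_max, col_max = col_max,
             stringsAsFactors = FALSE)
}

#' Box area under the half-open convention
#' @param box a box (one-row data.frame from [annotation_box()] or any object
#'   with the four corner fields).
#' @return numeric area in pixels.
#' @export
box_area <- function(box) {
  (box$row_max - box$row_min) * (box$col_max - box$col_min)
}

#' Intersection-over-union of two boxes
#'
#' IoU = |A intersect B| / |A union B| with areas computed under the half-open
#' pixel convention. Symmetric; equals 1 iff the boxes coincide and 0 iff they
#' are disjoint.
#'
#' @param a,b boxes (one-row data.frames with corner fields). If both carry a
#'   non-missing `view`, the views must agree.
#' @return IoU in \[0, 1\].
#' @examples
#' iou(annotation_box(0, 0, 2, 2), annotation_box(1, 1, 3, 3))  # 1/7
#' @export
iou <- function(a, b) {
  va <- a$view %||% NA_character_
  vb <- b$view %||% NA_character_
  if (!is.na(va) && !is.na(vb) && va != vb)
    stop_mc("IoU is only defined for boxes on the same view", "mc_view_mismatch")
  ih <- min(a$row_max, b$row_max) - max(a$row_min, b$row_min)
  iw <- min(a$col_max, b$col_max) - max(a$col_min, b$col_min)
  inter <- max(0, ih) * max(0, iw)
  union <- box_area(a) + box_area(b) - inter
  inter / union
}

# Vectorized IoU between all rows of boxes_a and all rows of boxes_b
# (matrix n_a x n_b). Internal.
iou_matrix <- function(boxes_a, boxes_b) {
  ih <- outer(boxes_a$row_max, boxes_b$row_max, pmin) -
    outer(boxes_a$row_min, boxes_b$row_min, pmax)
  iw <- outer(boxes_a$col_max, boxes_b$col_max, pmin) -
    outer(boxes_a$col_min, boxes_b$col_min, pmax)
  inter <- pmax(ih, 0) * pmax(iw, 0)
  area_a <- (boxes_a$row_max - boxes_a$row_min) * (boxes_a$col_max - boxes_a$col_min)
  area_b <- (boxes_b$row_max - boxes_b$row_min) * (boxes_b$col_max - boxes_b$col_min)
  inter / (outer(area_a, area_b, `+`) - inter)
}

#' Reflect a box horizontally within an image of known width
#'
#' Used when a view is flipped so that the breast sits on the left side:
#' column coordinates map to `width - col` with endpoints swapped, so the
#' half-open convention is preserved.
#'
#' @param box a box.
#' @param width image width in pixels (number of columns).
#' @return the reflected box.
#' @export
flip_box <- function(box, width) {
  new_min <- width - box$col_max
  new_max <- width - box$col_min
  box$col_min <- new_min
  box$col_max <- new_max
  box
}

# Validate a boxes data.frame; returns diagnostics per bad row. Internal.
validate_boxes <- function(df) {
  required <- c("case_id", "reader", "view", "row_min", "col_min", "row_max", "col_max")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_mc(paste0("annotation table is missing columns: ",
                   paste(missing_cols, collapse = ", ")), "mc_bad_schema")
  num <- c("row_min", "col_min", "row_max", "col_max")
  problems <- character(0)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    vals <- suppressWarnings(as.numeric(unlist(r[num])))
    if (anyNA(vals)) {
      problems <- c(problems, sprintf("row %d: non-numeric coordinates", i))
    } else if (vals[1] >= vals[3] || vals[2] >= vals[4]) {
      problems <- c(problems, sprintf("row %d: min >= max (zero or negative area)", i))
    } else if (!r$view %in% VIEWS) {
      problems <- c(problems, sprintf("row %d: unknown view '%s'", i, r$view))
    }
  }
  problems
}
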