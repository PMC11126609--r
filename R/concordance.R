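# Inter-reader concordance: box matching, Lin's CCC on box corners,
# McBride interpretation levels, challenging-to-localise flagging.

#' Match two readers' boxes by IoU
#'
#' Greedy one-to-one matching: among all (A, B) pairs on the same view with
#' overlap area strictly greater than zero, repeatedly take the pair with the
#' highest IoU, remove both boxes, and continue. Remaining boxes are reported
#' unmatched. Ties on IoU break toward the earlier row indices, so the result
#' is deterministic.
#'
#' @param boxes_a,boxes_b data.frames of boxes (one reader each), as produced
#'   by [annotation_box()] / [read_annotations()].
#' @return list with `pairs` (data.frame: `idx_a`, `idx_b`, `iou` plus the
#'   paired corner coordinates) and `unmatched_a` / `unmatched_b` (row indices
#'   into the inputs).
#' @export
match_boxes <- function(boxes_a, boxes_b) {
  na <- nrow(boxes_a) %||% 0L
  nb <- nrow(boxes_b) %||% 0L
  empty <- data.frame(idx_a = integer(0), idx_b = integer(0), iou = numeric(0))
  if (!na || !nb)
    return(list(pairs = empty, unmatched_a = seq_len(na), unmatched_b = seq_len(nb)))
  m <- iou_matrix(boxes_a, boxes_b)
  same_view <- outer(boxes_a$view, boxes_b$view, `==`)
  m[!same_view] <- 0
  pairs <- empty
  free_a <- rep(TRUE, na)
  free_b <- rep(TRUE, nb)
  repeat {
    m2 <- m
    m2[!free_a, ] <- 0
    m2[, !free_b] <- 0
    if (max(m2) <= 0) break
    ij <- which(m2 == max(m2), arr.ind = TRUE)[1, , drop = TRUE]
    pairs <- rbind(pairs, data.frame(idx_a = ij[[1]], idx_b = ij[[2]],
                                     iou = m2[ij[[1]], ij[[2]]]))
    free_a[ij[[1]]] <- FALSE
    free_b[ij[[2]]] <- FALSE
  }
  list(pairs = pairs, unmatched_a = which(free_a), unmatched_b = which(free_b))
}

#' Lin's concordance correlation coefficient
#'
#' CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2), with population
#' (divide-by-n) moments. Equals 1 iff `y` is identical to `x`; its magnitude
#' never exceeds that of the Pearson correlation; it penalizes location and
#' scale shifts that Pearson's r ignores.
#'
#' @param x,y equal-length numeric vectors of paired measurements, length >= 2.
#' @return CCC in \[-1, 1\].
#' @examples
#' lin_ccc(1:4, 2:5)  # 0.7142857
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y))
    stop_mc("x and y must have the same length", "mc_length_mismatch")
  if (length(x) < 2L)
    stop_mc("need at least two paired values", "mc_too_short")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  if (sx2 == 0 && sy2 == 0)
    stop_mc("both sequences are constant; CCC is undefined", "mc_constant_input")
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# The 8 corner numbers of a box, in fixed corner order
# (r0,c0), (r0,c1), (r1,c0), (r1,c1). Internal.
box_corner_values <- function(box) {
  c(box$row_min, box$col_min,
    box$row_min, box$col_max,
    box$row_max, box$col_min,
    box$row_max, box$col_max)
}

#' Case-level concordance from matched box pairs
#'
#' For each matched pair the four corner points of each reader's box
#' contribute 8 paired numbers (row and column of each corner, in a fixed
#' corner order); pairs from all views of the case are pooled and Lin's CCC
#' is computed over the pooled sequences (reader A as x, reader B as y).
#'
#' @param boxes_a,boxes_b the two readers' boxes for one case.
#' @param matching optional precomputed result of [match_boxes()].
#' @return list with `ccc` (NA when there are no matched pairs), `n_pairs`,
#'   `mean_iou`, `level` (see [mcbride_level()]; cases with no matched pair
#'   are assigned `"poor"`), and `challenging` (see [is_challenging()]).
#' @export
case_concordance <- function(boxes_a, boxes_b, matching = NULL) {
  matching <- matching %||% match_boxes(boxes_a, boxes_b)
  pairs <- matching$pairs
  if (!nrow(pairs)) {
    return(list(ccc = NA_real_, n_pairs = 0L, mean_iou = NA_real_,
                level = "poor", challenging = TRUE))
  }
  x <- unlist(lapply(pairs$idx_a, function(i) box_corner_values(boxes_a[i, ])))
  y <- unlist(lapply(pairs$idx_b, function(i) box_corner_values(boxes_b[i, ])))
  ccc <- lin_ccc(x, y)
  list(ccc = ccc, n_pairs = nrow(pairs), mean_iou = mean(pairs$iou),
       level = mcbride_level(ccc), challenging = all(pairs$iou <= 0.95))
}

#' McBride interpretation level for a CCC value
#'
#' Bands: almost perfect (CCC > 0.99), substantial (0.95 < CCC <= 0.99),
#' moderate (0.90 < CCC <= 0.95), poor (CCC <= 0.90). The quoted band
#' phrasing fixes only the outer bounds ("greater than 0.99", "less than
#' 0.9"); boundary values are assigned to the lower category here, and the
#' edges are exposed for sensitivity checks.
#'
#' @param ccc concordance value in \[-1, 1\].
#' @param edges band edges, descending, defaults `c(0.99, 0.95, 0.90)`.
#' @return one of `"almost_perfect"`, `"substantial"`, `"moderate"`, `"poor"`.
#' @export
mcbride_level <- function(ccc, edges = c(0.99, 0.95, 0.90)) {
  if (is.na(ccc) || ccc < -1 - 1e-12 || ccc > 1 + 1e-12)
    stop_mc("ccc must lie in [-1, 1]", "mc_bad_ccc")
  if (ccc > edges[1]) "almost_perfect"
  else if (ccc > edges[2]) "substantial"
  else if (ccc > edges[3]) "moderate"
  else "poor"
}

#' Is a case challenging to localise?
#'
#' A case is challenging when the readers never "significantly overlap",
#' i.e. no matched pair attains IoU > 0.95. Cases where the readers' boxes
#' are entirely disjoint are therefore always challenging.
#'
#' @param matching result of [match_boxes()] for the case.
#' @return logical.
#' @export
is_challenging <- function(matching) {
  !nrow(matching$pairs) || all(matching$pairs$iou <= 0.95)
}

#' Concordance analysis over a cohort annotation table
#'
#' Splits an annotation table by case, matches reader A against reader B on
#' each, and returns one row per case.
#'
#' @param annotations data.frame with columns `case_id`, `reader` (values
#'   `"A"`/`"B"`), `view`, and the four corner columns.
#' @return data.frame with columns `case_id`, `n_pairs`, `n_unmatched`,
#'   `mean_iou`, `ccc`, `level`, `challenging`.
#' @export
concordance_table <- function(annotations) {
  probs <- validate_boxes(annotations)
  if (length(probs))
    stop_mc(paste(probs, collapse = "; "), "mc_bad_schema")
  ids <- unique(annotations$case_id)
  rows <- lapply(ids, function(id) {
    sub <- annotations[annotations$case_id == id, ]
    a <- sub[sub$reader == "A", ]
    b <- sub[sub$reader == "B", ]
    m <- match_boxes(a, b)
    cc <- case_concordance(a, b, matching = m)
    data.frame(case_id = id, n_pairs = cc$n_pairs,
               n_unmatched = length(m$unmatched_a) + length(m$unmatched_b),
               mean_iou = cc$mean_iou, ccc = cc$ccc, level = cc$level,
               challenging = cc$challenging, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
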