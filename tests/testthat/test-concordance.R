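# Box geometry, reader matching, Lin's CCC and McBride levels.

test_that("iou handles identity, disjointness and partial overlap exactly", {
  a <- annotation_box(0, 0, 2, 2)
  expect_identical(iou(a, a), 1)
  expect_identical(iou(a, annotation_box(5, 5, 7, 7)), 0)
  # [0,2)x[0,2) vs [1,3)x[1,3): intersection 1, union 7
  expect_equal(iou(a, annotation_box(1, 1, 3, 3)), 1 / 7)
  expect_equal(iou(annotation_box(1, 1, 3, 3), a), 1 / 7)  # symmetry
  expect_error(iou(annotation_box(0, 0, 2, 2, view = "LCC"),
                   annotation_box(0, 0, 2, 2, view = "RCC")),
               class = "mc_view_mismatch")
  expect_error(annotation_box(3, 0, 3, 2), class = "mc_degenerate_box")
})

test_that("match_boxes pairs overlapping boxes one-to-one by descending IoU", {
  a1 <- annotation_box(0, 0, 10, 10, reader = "A", view = "LCC")
  b1 <- annotation_box(2, 2, 12, 12, reader = "B", view = "LCC")
  m <- match_boxes(a1, b1)
  expect_equal(nrow(m$pairs), 1)
  expect_length(m$unmatched_a, 0)

  m2 <- match_boxes(a1, annotation_box(50, 50, 60, 60, reader = "B", view = "LCC"))
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$unmatched_a, 1L)
  expect_equal(m2$unmatched_b, 1L)

  # 2 vs 2 with cross IoUs favouring the (1,1),(2,2) assignment
  A <- rbind(annotation_box(0, 0, 10, 10, view = "LCC"),
             annotation_box(100, 100, 110, 110, view = "LCC"))
  B <- rbind(annotation_box(1, 1, 11, 11, view = "LCC"),
             annotation_box(103, 103, 113, 113, view = "LCC"))
  m3 <- match_boxes(A, B)
  got <- m3$pairs[order(m3$pairs$idx_a), ]
  expect_equal(got$idx_b, c(1L, 2L))
  # agrees with the exhaustive assignment oracle on this instance
  expect_equal(best_assignment_oracle(iou_matrix(A, B))[got$idx_a], got$idx_b)
})

test_that("lin_ccc matches the closed form and its boundary cases", {
  expect_identical(lin_ccc(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(lin_ccc(1:4, 2:5), 2 * 1.25 / (1.25 + 1.25 + 1))
  expect_equal(lin_ccc(c(1, 2), c(2, 1)), -1)
  expect_error(lin_ccc(1:3, 1:4), class = "mc_length_mismatch")
  expect_error(lin_ccc(c(2, 2), c(3, 3)), class = "mc_constant_input")
})

test_that("lin_ccc is bounded by Pearson r and invariant to joint affine maps", {
  set.seed(31)
  for (i in 1:50) {
    x <- rnorm(20); y <- 0.5 * x + rnorm(20)
    expect_lte(abs(lin_ccc(x, y)), abs(cor(x, y)) + 1e-12)
    # same positive affine transform of both sequences leaves CCC unchanged
    expect_equal(lin_ccc(3 * x + 2, 3 * y + 2), lin_ccc(x, y), tolerance = 1e-10)
    # equal means and variances: CCC collapses to Pearson r
    xc <- scale(x)[, 1]; yc <- scale(y)[, 1]
    expect_equal(lin_ccc(xc, yc), cor(xc, yc), tolerance = 1e-10)
  }
})

test_that("case_concordance pools corner points and penalizes location shift", {
  a <- rbind(annotation_box(10, 10, 50, 40, reader = "A", view = "LCC"),
             annotation_box(200, 30, 260, 80, reader = "A", view = "LMLO"))
  expect_identical(case_concordance(a, a)$ccc, 1)
  # reader B shifted by a constant: Pearson r stays 1, CCC drops below 1
  b <- a
  b$row_min <- b$row_min + 30; b$row_max <- b$row_max + 30
  cc <- case_concordance(a, b)
  expect_lt(cc$ccc, 1)
  expect_gt(cc$ccc, 0)
  # no matched pairs: undefined CCC, worst level, challenging
  far <- annotation_box(600, 400, 650, 450, reader = "B", view = "LCC")
  cc2 <- case_concordance(a[1, ], far)
  expect_true(is.na(cc2$ccc))
  expect_identical(cc2$level, "poor")
  expect_true(cc2$challenging)
})

test_that("mcbride_level honors the band edges and boundary convention", {
  expect_identical(mcbride_level(0.995), "almost_perfect")
  expect_identical(mcbride_level(0.97), "substantial")
  expect_identical(mcbride_level(0.92), "moderate")
  expect_identical(mcbride_level(0.80), "poor")
  # boundary values fall to the lower category
  expect_identical(mcbride_level(0.99), "substantial")
  expect_identical(mcbride_level(0.95), "moderate")
  expect_identical(mcbride_level(0.90), "poor")
  expect_error(mcbride_level(1.2), class = "mc_bad_ccc")
})

test_that("challenging flag means no pair overlaps significantly", {
  a <- annotation_box(0, 0, 20, 20, reader = "A", view = "LCC")
  expect_false(is_challenging(match_boxes(a, a)))  # IoU 1 > 0.95
  b <- annotation_box(5, 5, 25, 25, reader = "B", view = "LCC")
  expect_true(is_challenging(match_boxes(a, b)))   # best IoU well under 0.95
  far <- annotation_box(100, 100, 120, 120, reader = "B", view = "LCC")
  expect_true(is_challenging(match_boxes(a, far))) # disjoint
})

test_that("concordance_table summarizes a cohort per case", {
  ann <- rbind(
    annotation_box(10, 10, 50, 40, "c1", "A", "LCC"),
    annotation_box(10, 10, 50, 40, "c1", "B", "LCC"),
    annotation_box(10, 10, 50, 40, "c2", "A", "RCC"),
    annotation_box(30, 20, 80, 60, "c2", "B", "RCC"))
  ct <- concordance_table(ann)
  expect_equal(ct$ccc[ct$case_id == "c1"], 1)
  expect_identical(ct$level[ct$case_id == "c1"], "almost_perfect")
  expect_lt(ct$ccc[ct$case_id == "c2"], 1)
})
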