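# Synthetic cohort generator: images, jittered reader boxes, saliency maps,
# cohort assembly and its determinism/mix contracts.

test_that("generated images have one foreground component and visible lesions", {
  img <- generate_image("RCC", NULL, noise_level = 0, seed = 1,
                        image_shape = c(160, 110))
  expect_equal(max(as.matrix(EBImage::bwlabel(img$mask * 1))), 1)
  # background border stays dark
  expect_true(all(img$pixels[1, ] == 0))
  expect_true(all(img$pixels[, 1] == 0))  # chest wall is on the right for RCC

  lesion <- data.frame(view = "LCC", center_row = 80, center_col = 30,
                       a = 15, b = 8, diameter_cm = 0.3, intensity_gain = 0.5)
  img2 <- generate_image("LCC", lesion, noise_level = 0, seed = 1,
                         image_shape = c(160, 110))
  r <- matrix(seq_len(160) - 1, 160, 110)
  cc <- matrix(seq_len(110) - 1, 160, 110, byrow = TRUE)
  inside <- ((r - 80) / 15)^2 + ((cc - 30) / 8)^2 <= 1
  expect_gt(mean(img2$pixels[inside]), mean(img2$pixels[img2$mask & !inside]))

  a <- generate_image("LMLO", lesion, noise_level = 0.05, seed = 7,
                      image_shape = c(160, 110))
  b <- generate_image("LMLO", lesion, noise_level = 0.05, seed = 7,
                      image_shape = c(160, 110))
  expect_identical(a$pixels, b$pixels)

  outside <- data.frame(view = "LCC", center_row = 10, center_col = 100,
                        a = 9, b = 9, diameter_cm = 0.2, intensity_gain = 0.5)
  expect_error(generate_image("LCC", outside, 0, 1, c(160, 110)),
               class = "mc_lesion_outside")
})

test_that("box jitter is zero-mean Gaussian with the stated magnitude", {
  tb <- annotation_box(100, 50, 200, 120)
  expect_equal(jitter_box(tb, 0, seed = 1)[, 4:7], tb[, 4:7])
  j1 <- jitter_box(tb, 2, seed = 5)
  expect_identical(j1, jitter_box(tb, 2, seed = 5))
  expect_true(j1$row_min < j1$row_max && j1$col_min < j1$col_max)

  # mean absolute corner displacement at sigma = 5 is sigma * sqrt(2/pi)
  disp <- vapply(1:1000, function(s) {
    j <- jitter_box(tb, 5, seed = s, image_shape = c(736, 480))
    mean(abs(unlist(j[, 4:7]) - unlist(tb[, 4:7])))
  }, numeric(1))
  expect_equal(mean(disp), 5 * sqrt(2 / pi), tolerance = 0.1)
})

test_that("saliency maps follow lesions, offsets and the Poisson blob rate", {
  empty <- generate_saliency(NULL, fp_blob_rate = 0, seed = 1,
                             saliency_shape = c(40, 30))
  expect_true(all(empty$grid == 0))
  expect_equal(empty$peak, 0)

  lesion <- data.frame(view = "LCC", center_row = 368, center_col = 120)
  sm <- generate_saliency(lesion, offset_sigma = 0, spread = 4, seed = 2,
                          saliency_shape = c(92, 60), image_shape = c(736, 480))
  am <- which(sm$grid == max(sm$grid), arr.ind = TRUE)[1, ]
  expect_equal(as.integer(am), c(round(368 * 92 / 736) + 1L, round(120 * 60 / 480) + 1L))

  counts <- vapply(1:500, function(s)
    generate_saliency(NULL, fp_blob_rate = 3, seed = s,
                      saliency_shape = c(30, 20))$n_fp, numeric(1))
  expect_gte(mean(counts), 2.7)
  expect_lte(mean(counts), 3.3)
})

test_that("cohort allocation is exact largest-remainder and deterministic", {
  cfg <- synth_config(n_cases = 100,
                      category_mix = c(missed = 0.25, prior_vis = 0.35,
                                       prior_invis = 0.40),
                      normal_fraction = 0.5, seed = 9)
  coh <- generate_cohort(cfg, with_saliency = FALSE)
  expect_equal(as.numeric(table(coh$case_table$category)[c("missed", "prior_vis", "prior_invis")]),
               c(25, 35, 40))
  expect_equal(sum(coh$case_table$category == "normal"), 50)
  expect_equal(as.numeric(table(coh$case_table$size_group)[c("T1", "T2", "T3")]),
               as.numeric(mammoconcord:::largest_remainder(100, cfg$size_mix)))

  coh2 <- generate_cohort(cfg, with_saliency = FALSE)
  expect_identical(coh$case_table, coh2$case_table)
  expect_identical(coh$annotations, coh2$annotations)

  expect_error(synth_config(n_cases = 0), class = "mc_bad_config")
  expect_error(synth_config(category_mix = c(0.5, 0.2, 0.2)), class = "mc_bad_config")
})

test_that("zero jitter yields perfect concordance everywhere", {
  cfg <- synth_config(n_cases = 25, jitter_sigma = 0, solo_box_rate = 0,
                      normal_fraction = 0, seed = 4)
  coh <- generate_cohort(cfg, with_saliency = FALSE)
  ct <- concordance_table(coh$annotations)
  expect_true(all(ct$ccc == 1))
  expect_true(all(ct$level == "almost_perfect"))
})

test_that("category and size invariants hold case by case", {
  cfg <- synth_config(n_cases = 30, seed = 12)
  coh <- generate_cohort(cfg, with_saliency = FALSE)
  for (case in coh$cases) {
    if (case$category == "normal") {
      expect_null(case$truth_lesions)
      expect_null(case$reader_boxes)
    } else {
      expect_gt(nrow(case$truth_lesions), 0)
      expect_true(all(case$reader_boxes$view %in%
                        if (case$laterality_of_cancer == "left")
                          c("LCC", "LMLO") else c("RCC", "RMLO")))
      d <- case$truth_lesions$diameter_cm[1]
      expected_group <- if (d <= 2) "T1" else if (d < 5) "T2" else "T3"
      expect_identical(case$size_group, expected_group)
    }
  }
})

test_that("saliency localization degrades as the offset knob grows", {
  hit_rate <- vapply(c(0, 6, 15), function(off) {
    cfg <- synth_config(n_cases = 40, saliency_offset_sigma = off,
                        fp_blob_rate = 0, normal_fraction = 0, seed = 77)
    coh <- generate_cohort(cfg)
    ev <- evaluate_cohort(coh)
    mean(ev$results$loc_hit[ev$results$truth], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(hit_rate) <= 0))
  expect_gt(hit_rate[1], hit_rate[3])
})
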