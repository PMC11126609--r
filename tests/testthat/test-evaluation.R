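# Classification, localization scoring, stratified tables, group tests.

test_that("case classification is the max-over-views rule", {
  cl <- classify_case(c(0.9, 0.1, 0.05, 0.2), 0.5)
  expect_identical(cl$predicted, "positive")
  expect_equal(cl$score, 0.9)
  expect_identical(classify_case(c(0, 0, 0, 0))$predicted, "negative")
  expect_error(classify_case(numeric(0)), class = "mc_no_scores")
})

test_that("threshold sweep moves sensitivity and specificity oppositely", {
  cfg <- synth_config(n_cases = 60, seed = 14)
  coh <- generate_cohort(cfg)
  sweep <- lapply(c(0.2, 0.4, 0.6, 0.8), function(th) {
    ev <- evaluate_cohort(coh, threshold = th)
    ev$rates$rate
  })
  sens <- vapply(sweep, `[`, numeric(1), 1)
  spec <- vapply(sweep, `[`, numeric(1), 2)
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("localization hits follow the saliency argmax", {
  g <- matrix(0, 92, 60); g[40, 20] <- 1
  # argmax cell center maps to image pixel (~316, ~156) on a 736x480 frame
  inside <- annotation_box(280, 120, 360, 200)
  outside <- annotation_box(600, 300, 700, 400)
  expect_true(localization_hit(g, inside, c(736, 480)))
  expect_false(localization_hit(g, outside, c(736, 480)))
  expect_true(is.na(localization_hit(g, inside[0, ], c(736, 480))))
  # mass criterion: all mass inside the box union
  expect_true(localization_hit(g, inside, c(736, 480), criterion = "mass"))
  expect_false(localization_hit(g, outside, c(736, 480), criterion = "mass"))
})

test_that("rates come with exact counts and Wilson intervals", {
  truth <- c(rep(TRUE, 94), rep(FALSE, 50))
  pred <- c(rep(TRUE, 78), rep(FALSE, 16), rep(FALSE, 45), rep(TRUE, 5))
  r <- sensitivity_specificity(truth, pred)
  expect_equal(r["sensitivity", "rate"], 78 / 94)          # 82.98%
  expect_equal(round(100 * r["sensitivity", "rate"], 2), 82.98)
  expect_equal(r["sensitivity", c("numerator", "denominator")],
               data.frame(numerator = 78, denominator = 94,
                          row.names = "sensitivity"))
  expect_equal(r["specificity", "rate"], 45 / 50)
  expect_true(r["sensitivity", "ci_lo"] < 78 / 94 &&
                78 / 94 < r["sensitivity", "ci_hi"])

  all_found <- sensitivity_specificity(rep(TRUE, 20), rep(TRUE, 20))
  expect_equal(all_found["sensitivity", "rate"], 1)
  expect_true(is.na(all_found["specificity", "rate"]))  # empty stratum: NA
})

test_that("stratification partitions positives with exact cell counts", {
  results <- data.frame(
    case_id = paste0("c", 1:10),
    truth = c(rep(TRUE, 8), FALSE, FALSE),
    category = c(rep("missed", 4), rep("prior_vis", 4), "normal", "normal"),
    level = c(rep("almost_perfect", 2), rep("poor", 2),
              rep("almost_perfect", 2), rep("poor", 2), NA, NA),
    detected = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  tb <- stratify(results, c("level", "category"))
  cell <- function(lv, cat) tb[tb$level == lv & tb$category == cat, ]
  expect_equal(cell("almost_perfect", "missed")$sensitivity, 1)
  expect_equal(cell("poor", "missed")$sensitivity, 0.5)
  expect_equal(cell("almost_perfect", "prior_vis")$numerator, 1)
  expect_true(is.na(cell("moderate", "missed")$sensitivity))  # empty, not 0
  expect_equal(sum(tb$denominator), 8)  # partition of the positives
  expect_error(stratify(results, "nonexistent"), class = "mc_bad_axes")
})

test_that("identical group rates are never called significant", {
  results <- data.frame(
    truth = TRUE,
    category = rep(c("missed", "prior_vis", "prior_invis"), each = 100),
    detected = rep(rep(c(TRUE, FALSE), c(80, 20)), 3))
  out <- compare_groups(results, "category", "chisq")
  expect_equal(out$p_value, 1)

  out2 <- compare_groups(results, "category", "anova", n_replicates = 10)
  expect_gt(out2$p_value, 0.5)
  expect_true(all(out2$p_pairwise >= 0.5, na.rm = TRUE))

  one_group <- results[results$category == "missed", ]
  expect_true(is.na(compare_groups(one_group, "category")$p_value))
})

test_that("clearly different detection quality is detected with high power", {
  set.seed(6)
  results <- data.frame(
    truth = TRUE,
    category = rep(c("missed", "prior_vis"), each = 200),
    detected = c(runif(200) < 0.60, runif(200) < 0.95))
  out <- compare_groups(results, "category", "chisq")
  expect_lt(out$p_value, 1e-6)
})

test_that("evaluate_cohort assembles consistent case results", {
  cfg <- synth_config(n_cases = 30, seed = 18)
  coh <- generate_cohort(cfg)
  ev <- evaluate_cohort(coh)
  expect_s3_class(ev, "mc_eval")
  res <- ev$results
  expect_equal(nrow(res), 60)
  expect_true(all(res$detected == (res$score >= 0.5)))
  expect_true(all(!is.na(res$level[res$truth])))
  expect_true(all(is.na(res$loc_hit[!res$truth])))
  # marginals: stratified denominators sum to the positive count
  expect_equal(sum(ev$by_level$denominator), sum(res$truth))
  out <- capture.output(print(ev))
  expect_true(any(grepl("sensitivity", out)))
})
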