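# Case-level classification, localization scoring, stratified
# sensitivity/specificity tables and group-comparison tests.

#' Classify a case from its per-view malignancy scores
#'
#' The case score is the maximum over the view scores; the case is called
#' positive when the score reaches the decision threshold.
#'
#' @param view_scores numeric vector of per-view malignancy scores (>= 1).
#' @param threshold decision threshold, default 0.5.
#' @return list with `predicted` (`"positive"`/`"negative"`) and `score`.
#' @export
classify_case <- function(view_scores, threshold = 0.5) {
  if (!length(view_scores)) stop_mc("no view scores", "mc_no_scores")
  s <- max(view_scores)
  list(predicted = if (s >= threshold) "positive" else "negative", score = s)
}

#' Localization hit test for one case
#'
#' Default criterion (`"argmax"`): the argmax of the saliency map, mapped to
#' image coordinates, lies inside the union of the reference boxes.
#' Alternative criterion (`"mass"`): at least `mass_tau` of the map's total
#' mass falls inside the box union.
#'
#' @param saliency saliency matrix for the view.
#' @param boxes reference boxes on this view (reader annotations or truth).
#' @param image_shape pixel shape the box coordinates refer to.
#' @param criterion `"argmax"` or `"mass"`.
#' @param mass_tau mass-fraction threshold for the `"mass"` criterion.
#' @return `TRUE`/`FALSE`, or `NA` when there are no reference boxes
#'   (not-applicable, never a silent miss).
#' @export
localization_hit <- function(saliency, boxes, image_shape,
                             criterion = c("argmax", "mass"), mass_tau = 0.5) {
  criterion <- match.arg(criterion)
  if (is.null(boxes) || !nrow(boxes)) return(NA)
  if (criterion == "argmax") {
    ij <- which(saliency == max(saliency), arr.ind = TRUE)[1, ]
    r <- (ij[1] - 0.5) * image_shape[1] / nrow(saliency)
    cc <- (ij[2] - 0.5) * image_shape[2] / ncol(saliency)
    any(r >= boxes$row_min & r < boxes$row_max &
          cc >= boxes$col_min & cc < boxes$col_max)
  } else {
    mask <- rasterize_boxes(boxes, dim(saliency), image_shape)
    total <- sum(saliency)
    if (total <= 0) return(FALSE)
    sum(saliency * mask) / total >= mass_tau
  }
}

#' Sensitivity and specificity with Wilson intervals
#'
#' Computes sensitivity = TP/(TP+FN) and specificity = TN/(TN+FP) with exact
#' numerator/denominator counts and 95% Wilson score intervals. Rates whose
#' stratum is empty are reported as `NA` ("undefined"), never as zero.
#'
#' @param truth logical vector: cancer present.
#' @param predicted logical vector: model called positive.
#' @return data.frame with rows `sensitivity` and `specificity` and columns
#'   `rate`, `numerator`, `denominator`, `ci_lo`, `ci_hi`.
#' @export
sensitivity_specificity <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  tp <- sum(truth & predicted); fn <- sum(truth & !predicted)
  tn <- sum(!truth & !predicted); fp <- sum(!truth & predicted)
  row <- function(k, n) {
    if (n == 0) return(data.frame(rate = NA_real_, numerator = k, denominator = n,
                                  ci_lo = NA_real_, ci_hi = NA_real_))
    ci <- wilson_ci(k, n)
    data.frame(rate = k / n, numerator = k, denominator = n,
               ci_lo = ci[1], ci_hi = ci[2])
  }
  out <- rbind(row(tp, tp + fn), row(tn, tn + fp))
  rownames(out) <- c("sensitivity", "specificity")
  out
}

# 95% Wilson score interval for k successes out of n. Internal.
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, center - half), min(1, center + half))
}

#' Stratified sensitivity table
#'
#' One cell per combination of the requested stratification axes, each with
#' the exact numerator (cases detected) and denominator (cases in the
#' stratum). Cells with an empty stratum carry `NA` rates. Cell denominators
#' partition the truth-positive cohort exactly.
#'
#' @param results case-result data.frame (see [evaluate_cohort()]); needs
#'   logical columns `truth`, `detected` plus the axis columns.
#' @param axes character vector of stratification column names, e.g.
#'   `c("level", "category")`.
#' @return data.frame with one row per stratum combination: axis labels,
#'   `sensitivity`, `numerator`, `denominator`.
#' @export
stratify <- function(results, axes) {
  if (!all(axes %in% names(results)))
    stop_mc(paste("unknown stratification axes:",
                  paste(setdiff(axes, names(results)), collapse = ", ")),
            "mc_bad_axes")
  pos <- results[results$truth, , drop = FALSE]
  known_levels <- list(level = LEVELS, category = CATEGORIES,
                       size_group = SIZE_GROUPS, intended_band = LEVELS)
  vals <- lapply(axes, function(a) {
    lv <- known_levels[[a]]
    if (!is.null(lv)) lv else sort(unique(pos[[a]]))
  })
  grid <- expand.grid(vals, stringsAsFactors = FALSE)
  names(grid) <- axes
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- rep(TRUE, nrow(pos))
    for (a in axes) sel <- sel & pos[[a]] == grid[i, a]
    k <- sum(pos$detected[sel]); n <- sum(sel)
    cbind(grid[i, , drop = FALSE],
          data.frame(sensitivity = if (n > 0) k / n else NA_real_,
                     numerator = k, denominator = n))
  })
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}

#' Compare detection rates between groups
#'
#' Two designs, reported transparently:
#' \describe{
#'   \item{`"chisq"`}{chi-square test of independence on the detected /
#'     missed confusion counts across groups (proportion comparison).}
#'   \item{`"anova"`}{each group's cases are split into `n_replicates`
#'     subsamples, per-subsample sensitivities are compared by one-way
#'     ANOVA, and pairwise post-hoc t tests are Holm-corrected.}
#' }
#'
#' @param results case-result data.frame; truth-positive rows are used.
#' @param group name of the grouping column (e.g. `"category"`, `"level"`).
#' @param method `"chisq"` or `"anova"`.
#' @param n_replicates subsamples per group for the ANOVA design.
#' @return list with `method`, `p_value`, and for `"anova"` also
#'   `p_pairwise` (Holm-adjusted matrix).
#' @export
compare_groups <- function(results, group = "category",
                           method = c("chisq", "anova"), n_replicates = 10) {
  method <- match.arg(method)
  pos <- results[results$truth, , drop = FALSE]
  g <- factor(pos[[group]])
  if (nlevels(droplevels(g)) < 2)
    return(list(method = method, p_value = NA_real_,
                note = "fewer than two groups with cases; not testable"))
  g <- droplevels(g)
  if (method == "chisq") {
    tab <- table(g, factor(pos$detected, levels = c(FALSE, TRUE)))
    # small strata trip the usual approximation warning; the counts are
    # reported alongside so the reader can judge
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    list(method = "chisq", p_value = p, counts = tab)
  } else {
    reps <- do.call(rbind, lapply(levels(g), function(lv) {
      d <- pos$detected[g == lv]
      idx <- rep_len(seq_len(n_replicates), length(d))
      sens <- tapply(d, idx, mean)
      data.frame(group = lv, sens = as.numeric(sens))
    }))
    if (stats::var(reps$sens) < 1e-20) {
      # degenerate: every subsample sensitivity identical; no evidence of
      # any group difference
      return(list(method = "anova", p_value = 1,
                  p_pairwise = matrix(1, 0, 0)))
    }
    fit <- stats::aov(sens ~ group, data = reps)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    pw <- stats::pairwise.t.test(reps$sens, reps$group,
                                 p.adjust.method = "holm")$p.value
    list(method = "anova", p_value = p, p_pairwise = pw)
  }
}

#' Evaluate a synthetic cohort end to end
#'
#' Joins per-case concordance (level, challenging flag), case-level
#' classification at the decision threshold, and localization hits into a
#' case-result table, then builds the stratified sensitivity tables and
#' group-comparison p-values.
#'
#' @param cohort an `mc_cohort` from [generate_cohort()].
#' @param threshold decision threshold on the case score, default 0.5.
#' @param loc_criterion localization criterion, see [localization_hit()].
#' @return object of class `mc_eval`: list with `results` (per-case rows:
#'   `case_id`, `truth`, `category`, `size_group`, `level`, `challenging`,
#'   `ccc`, `score`, `detected`, `loc_hit`), `rates`
#'   (sensitivity/specificity with Wilson CIs), `by_level_category`,
#'   `by_level`, `by_size`, `tests` (p-values), `threshold`.
#' @export
evaluate_cohort <- function(cohort, threshold = 0.5,
                            loc_criterion = "argmax") {
  stopifnot(inherits(cohort, "mc_cohort"))
  conc <- if (!is.null(cohort$annotations)) concordance_table(cohort$annotations)
          else NULL
  tab <- cohort$case_table
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$case_id[i]
    truth <- tab$category[i] != "normal"
    sc <- cohort$scores[cohort$scores$case_id == id, ]
    cl <- classify_case(sc$score, threshold)
    level <- challenging <- NA
    ccc <- NA_real_
    if (truth && !is.null(conc)) {
      cr <- conc[conc$case_id == id, ]
      if (nrow(cr)) { level <- cr$level; challenging <- cr$challenging; ccc <- cr$ccc }
    }
    loc <- NA
    if (truth && length(cohort$saliency)) {
      case <- cohort$cases[[i]]
      hits <- vapply(unique(case$reader_boxes$view), function(v) {
        isTRUE(localization_hit(cohort$saliency[[id]][[v]],
                                case$reader_boxes[case$reader_boxes$view == v, ],
                                case$image_shape, criterion = loc_criterion))
      }, logical(1))
      loc <- any(hits)
    }
    data.frame(case_id = id, truth = truth, category = tab$category[i],
               size_group = tab$size_group[i],
               intended_band = tab$intended_band[i],
               level = level, challenging = challenging, ccc = ccc,
               score = cl$score, detected = cl$predicted == "positive",
               loc_hit = loc, stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  rates <- sensitivity_specificity(results$truth, results$detected)
  has_levels <- any(!is.na(results$level))
  out <- list(
    results = results,
    rates = rates,
    by_level_category = if (has_levels) stratify(results, c("level", "category")) else NULL,
    by_level = if (has_levels) stratify(results, "level") else NULL,
    by_size = stratify(results, "size_group"),
    tests = list(
      category = compare_groups(results, "category", "chisq"),
      level = if (has_levels) compare_groups(results, "level", "chisq") else NULL),
    threshold = threshold)
  class(out) <- "mc_eval"
  out
}

#' @export
print.mc_eval <- function(x, ...) {
  r <- x$rates
  fmt_rate <- function(i) {
    if (is.na(r$rate[i])) return("  -  ")
    sprintf("%.2f%% (%d/%d)", 100 * r$rate[i], r$numerator[i], r$denominator[i])
  }
  cat("Cohort evaluation (threshold ", x$threshold, ")\n", sep = "")
  cat("  sensitivity: ", fmt_rate(1), "\n  specificity: ", fmt_rate(2), "\n", sep = "")
  if (!is.null(x$by_level_category)) {
    cat("\nSensitivity by concordance level x category",
        " (correct counts in parentheses):\n", sep = "")
    t <- x$by_level_category
    for (lv in LEVELS) {
      cells <- vapply(CATEGORIES, function(cat) {
        row <- t[t$level == lv & t$category == cat, ]
        if (!nrow(row) || is.na(row$sensitivity)) "   -    "
        else sprintf("%5.1f%% (%d)", 100 * row$sensitivity, row$numerator)
      }, character(1))
      cat(sprintf("  %-15s %s\n", lv, paste(sprintf("%-14s", cells), collapse = " ")))
    }
    cat("  (columns: ", paste(CATEGORIES, collapse = ", "), ")\n", sep = "")
  }
  p <- x$tests$category$p_value
  if (!is.null(p) && !is.na(p))
    cat(sprintf("\nCategory difference (chi-square): p = %.4g\n", p))
  invisible(x)
}

#' @export
summary.mc_eval <- function(object, ...) {
  print(object)
  if (!is.null(object$by_level)) {
    cat("\nSensitivity by concordance level:\n")
    print(object$by_level, row.names = FALSE)
  }
  cat("\nSensitivity by size group:\n")
  print(object$by_size, row.names = FALSE)
  invisible(object)
}

#' @export
plot.mc_eval <- function(x, ...) {
  t <- x$by_level
  if (is.null(t)) t <- x$by_size
  ok <- !is.na(t$sensitivity)
  graphics::barplot(100 * t$sensitivity[ok], names.arg = t[[1]][ok],
                    ylab = "sensitivity (%)", ylim = c(0, 100),
                    las = 2, ...)
  invisible(x)
}
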