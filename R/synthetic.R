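# Seeded synthetic cohort generator: breast-like images, elliptical truth
# lesions spanning the T1/T2/T3 size taxonomy, paired reader annotations
# with a controllable concordance knob, and model-like saliency maps with a
# controllable localization-quality knob. Stands in for private screening
# data so every downstream stage runs end to end.

#' Synthetic cohort configuration
#'
#' All knobs of the generator in one validated object. Defaults define the
#' reference study conditions used throughout the package's tests and
#' reports; see the methods vignette for the rationale behind each value.
#'
#' @param n_cases number of cancer cases (cancer-free cases are added on top,
#'   see `normal_fraction`).
#' @param category_mix proportions over categories missed / prior_vis /
#'   prior_invis; must sum to 1.
#' @param size_mix proportions over tumor size groups T1 (<= 2 cm) / T2
#'   (2-5 cm) / T3 (>= 5 cm); must sum to 1.
#' @param jitter_sigma std (pixels) of the Gaussian perturbation applied to
#'   each reader-box corner coordinate; the concordance difficulty knob.
#' @param jitter_mode `"absolute"` (sigma in pixels) or `"relative"` (sigma
#'   as a fraction of the case's truth-corner coordinate SD, which makes a
#'   single sigma target a CCC band irrespective of box geometry).
#' @param saliency_offset_sigma std (saliency-grid pixels) of the
#'   displacement of each lesion's saliency blob; the localization-quality
#'   knob.
#' @param saliency_spread Gaussian radius (saliency-grid pixels) of lesion
#'   blobs; must be > 0.
#' @param fp_blob_rate expected number of off-lesion (false-positive) blobs
#'   per view.
#' @param fp_height base height of false-positive blobs relative to the unit
#'   lesion height.
#' @param detect_quality named per-category probability scaling of the
#'   synthetic malignancy score (free simulation parameters; the study data
#'   give no per-category difficulty constant).
#' @param size_quality named per-size-group multiplier on lesion conspicuity.
#' @param score_noise_sd lognormal sd of per-case lesion conspicuity.
#' @param score_u50 peak-score value mapped to probability 0.5 by the
#'   monotone score link `u / (u + u50)`.
#' @param quality_uplift global conspicuity multiplier emulating transfer
#'   learning (1 = pre-trained mode); it also divides false-positive blob
#'   heights, so both sensitivity and specificity improve with uplift.
#' @param pixel_spacing_cm physical size of one pixel; the default 0.01
#'   cm/pixel maps the 2 cm and 5 cm T-group thresholds to 200 and 500
#'   pixels.
#' @param image_shape `c(rows, cols)` of generated view images.
#' @param saliency_shape `c(rows, cols)` of generated saliency grids.
#' @param noise_level image noise sd.
#' @param normal_fraction cancer-free cases generated per cancer case
#'   (matched controls for specificity estimation).
#' @param solo_box_rate probability that reader B's box for a lesion-view is
#'   displaced to a disjoint location (emulates total per-lesion reader
#'   disagreement and exercises unmatched-box handling).
#' @param multi_lesion_rate probability that a cancer case carries a second
#'   lesion.
#' @param band_sigmas optional length-4 vector of jitter sigmas, one per
#'   McBride band (almost_perfect, substantial, moderate, poor); when set,
#'   cases are allocated round-robin to bands within each category and
#'   `intended_band` is recorded. See [calibrate_band_sigmas()].
#' @param band_quality optional length-4 conspicuity multipliers tied to the
#'   bands (higher jitter => lower quality); defaults to
#'   `c(1, 0.53, 0.34, 0.22)` when `band_sigmas` is set.
#' @param band_offset_add optional length-4 additions to
#'   `saliency_offset_sigma` per band; defaults to `c(0, 1.5, 3.5, 6)` when
#'   `band_sigmas` is set.
#' @param seed integer master seed; every draw derives from it.
#' @return validated list of class `mc_config`.
#' @export
synth_config <- function(n_cases = 100,
                         category_mix = c(missed = 0.25, prior_vis = 0.30,
                                          prior_invis = 0.45),
                         size_mix = c(T1 = 0.677, T2 = 0.243, T3 = 0.080),
                         jitter_sigma = 4,
                         jitter_mode = c("absolute", "relative"),
                         saliency_offset_sigma = 1.5,
                         saliency_spread = 5,
                         fp_blob_rate = 0.8,
                         fp_height = 0.15,
                         detect_quality = c(missed = 0.65, prior_vis = 0.88,
                                            prior_invis = 0.92),
                         size_quality = c(T1 = 0.95, T2 = 1.05, T3 = 1.15),
                         score_noise_sd = 0.45,
                         score_u50 = 0.35,
                         quality_uplift = 1,
                         pixel_spacing_cm = 0.01,
                         image_shape = c(736, 480),
                         saliency_shape = c(92, 60),
                         noise_level = 0.02,
                         normal_fraction = 1,
                         solo_box_rate = 0.06,
                         multi_lesion_rate = 0.25,
                         band_sigmas = NULL,
                         band_quality = NULL,
                         band_offset_add = NULL,
                         seed = 1L) {
  jitter_mode <- match.arg(jitter_mode)
  if (n_cases < 1) stop_mc("n_cases must be >= 1", "mc_bad_config")
  if (abs(sum(category_mix) - 1) > 1e-9 || abs(sum(size_mix) - 1) > 1e-9)
    stop_mc("category_mix and size_mix must each sum to 1", "mc_bad_config")
  if (any(c(category_mix, size_mix) < 0))
    stop_mc("mix proportions must be >= 0", "mc_bad_config")
  if (jitter_sigma < 0 || saliency_offset_sigma < 0 || noise_level < 0)
    stop_mc("sigmas must be >= 0", "mc_bad_config")
  if (saliency_spread <= 0) stop_mc("saliency_spread must be > 0", "mc_bad_config")
  if (any(detect_quality < 0 | detect_quality > 1))
    stop_mc("detect_quality entries must be probabilities in [0, 1]", "mc_bad_config")
  if (fp_blob_rate < 0) stop_mc("fp_blob_rate must be >= 0", "mc_bad_config")
  if (!is.null(band_sigmas)) {
    if (length(band_sigmas) != 4) stop_mc("band_sigmas must have length 4", "mc_bad_config")
    band_quality <- band_quality %||% c(1, 0.53, 0.34, 0.22)
    band_offset_add <- band_offset_add %||% c(0, 1.5, 3.5, 6)
  }
  structure(list(
    n_cases = as.integer(n_cases), category_mix = category_mix,
    size_mix = size_mix, jitter_sigma = jitter_sigma,
    jitter_mode = jitter_mode,
    saliency_offset_sigma = saliency_offset_sigma,
    saliency_spread = saliency_spread, fp_blob_rate = fp_blob_rate,
    fp_height = fp_height, detect_quality = detect_quality,
    size_quality = size_quality, score_noise_sd = score_noise_sd,
    score_u50 = score_u50, quality_uplift = quality_uplift,
    pixel_spacing_cm = pixel_spacing_cm, image_shape = image_shape,
    saliency_shape = saliency_shape, noise_level = noise_level,
    normal_fraction = normal_fraction, solo_box_rate = solo_box_rate,
    multi_lesion_rate = multi_lesion_rate, band_sigmas = band_sigmas,
    band_quality = band_quality, band_offset_add = band_offset_add,
    seed = as.integer(seed)), class = "mc_config")
}

# Exact largest-remainder allocation of n items to proportions p. Internal.
largest_remainder <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Breast foreground mask: half-ellipse touching the chest-wall edge
# (left edge for L views, right edge for R views). Internal.
breast_mask <- function(view, image_shape) {
  nr <- image_shape[1]; nc <- image_shape[2]
  r0 <- (nr - 1) / 2
  ar <- 0.45 * nr
  ac <- 0.72 * nc
  r <- matrix(seq_len(nr) - 1, nr, nc)
  cc <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  cdist <- if (is_right_view(view)) (nc - 1) - cc else cc
  ((r - r0) / ar)^2 + (cdist / ac)^2 <= 1
}

#' Generate a synthetic mammogram-like view image
#'
#' Renders a dark background, a half-disc-like breast foreground touching
#' the chest-wall edge (left edge for left-side views, right edge for
#' right-side views), smooth intensity falloff toward the skin line,
#' additive Gaussian noise, and each lesion as an additive elliptical
#' Gaussian bump. Deterministic given `seed`.
#'
#' @param view view label.
#' @param lesions data.frame of lesions for this view (columns `center_row`,
#'   `center_col`, `a`, `b`, `intensity_gain`), or an empty/NULL set.
#' @param noise_level Gaussian noise sd added inside the foreground.
#' @param seed integer seed.
#' @param image_shape `c(rows, cols)`.
#' @return list with `pixels` (matrix, values >= 0) and `mask` (logical
#'   foreground mask, one connected component).
#' @export
generate_image <- function(view, lesions = NULL, noise_level = 0.02, seed = 1L,
                           image_shape = c(736, 480)) {
  if (!view %in% VIEWS) stop_mc("unknown view", "mc_bad_view")
  mask <- breast_mask(view, image_shape)
  nr <- image_shape[1]; nc <- image_shape[2]
  r <- matrix(seq_len(nr) - 1, nr, nc)
  cc <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  cdist <- if (is_right_view(view)) (nc - 1) - cc else cc
  q <- ((r - (nr - 1) / 2) / (0.45 * nr))^2 + (cdist / (0.72 * nc))^2
  img <- matrix(0, nr, nc)
  img[mask] <- 0.40 * (1 - 0.5 * q[mask])
  if (!is.null(lesions) && nrow(lesions)) {
    for (k in seq_len(nrow(lesions))) {
      L <- lesions[k, ]
      ell <- ((r - L$center_row) / L$a)^2 + ((cc - L$center_col) / L$b)^2
      if (any(ell <= 1 & !mask))
        stop_mc("lesion ellipse extends outside the breast foreground",
                "mc_lesion_outside")
      img <- img + L$intensity_gain * exp(-2 * ell)
    }
  }
  if (noise_level > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(nr * nc, 0, noise_level), nr, nc))
    img[mask] <- img[mask] + noise[mask]
  }
  img[img < 0] <- 0
  list(pixels = img, mask = mask)
}

#' Perturb a truth box into a synthetic reader annotation
#'
#' Each of the four corner coordinates is perturbed by independent zero-mean
#' Gaussian noise with sd `jitter_sigma`, the result is rounded to integer
#' pixels, re-ordered so min < max on both axes, and clipped to the image
#' bounds. Degenerate results (zero width or height after clipping) are
#' re-drawn up to `max_retry` times.
#'
#' @param truth_box a box (one-row data.frame).
#' @param jitter_sigma corner noise sd in pixels, >= 0.
#' @param seed integer seed.
#' @param image_shape `c(rows, cols)` bounds for clipping.
#' @param max_retry bounded retry count for degenerate draws.
#' @return the jittered box (same identity fields).
#' @export
jitter_box <- function(truth_box, jitter_sigma, seed = 1L,
                       image_shape = c(736, 480), max_retry = 10L) {
  if (jitter_sigma < 0) stop_mc("jitter_sigma must be >= 0", "mc_bad_config")
  with_seed(seed, {
    for (attempt in seq_len(max_retry)) {
      e <- stats::rnorm(4, 0, jitter_sigma)
      r <- sort(round(c(truth_box$row_min + e[1], truth_box$row_max + e[2])))
      cl <- sort(round(c(truth_box$col_min + e[3], truth_box$col_max + e[4])))
      r <- pmin(pmax(r, 0), image_shape[1])
      cl <- pmin(pmax(cl, 0), image_shape[2])
      if (r[1] < r[2] && cl[1] < cl[2]) {
        out <- truth_box
        out$row_min <- r[1]; out$row_max <- r[2]
        out$col_min <- cl[1]; out$col_max <- cl[2]
        return(out)
      }
    }
    stop_mc("jittered box degenerate after bounded retries", "mc_degenerate_box")
  })
}

#' Generate a model-like saliency map for one view
#'
#' One Gaussian blob per lesion, its center displaced by Gaussian offset
#' noise (the localization-quality knob), plus a Poisson number of
#' off-lesion false-positive blobs at reduced height. All values are >= 0.
#'
#' @param lesions lesion data.frame for this view (may be empty/NULL);
#'   column `height` optionally gives per-lesion blob heights (default 1).
#' @param offset_sigma blob-center displacement sd in saliency-grid pixels.
#' @param spread blob Gaussian radius in saliency-grid pixels, > 0.
#' @param fp_blob_rate expected false-positive blob count.
#' @param seed integer seed.
#' @param saliency_shape `c(rows, cols)` of the map.
#' @param image_shape pixel shape lesion coordinates refer to.
#' @param fp_height base false-positive blob height.
#' @param fp_noise_sd lognormal sd of false-positive heights.
#' @return list with `grid` (matrix >= 0) and `peak` (largest blob height;
#'   0 when the map is empty), from which the case-level malignancy score is
#'   derived as a monotone function.
#' @export
generate_saliency <- function(lesions = NULL, offset_sigma = 1.5, spread = 5,
                              fp_blob_rate = 0, seed = 1L,
                              saliency_shape = c(92, 60),
                              image_shape = c(736, 480),
                              fp_height = 0.15, fp_noise_sd = 0.45) {
  if (spread <= 0) stop_mc("spread must be > 0", "mc_bad_config")
  nr <- saliency_shape[1]; nc <- saliency_shape[2]
  rr <- matrix(seq_len(nr) - 1, nr, nc)
  ccm <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  add_blob <- function(g, r0, c0, h, sd_) {
    g + h * exp(-((rr - r0)^2 + (ccm - c0)^2) / (2 * sd_^2))
  }
  grid <- matrix(0, nr, nc)
  peak <- 0
  n_fp <- 0L
  with_seed(seed, {
    if (!is.null(lesions) && nrow(lesions)) {
      for (k in seq_len(nrow(lesions))) {
        L <- lesions[k, ]
        h <- if ("height" %in% names(L)) L$height else 1
        r0 <- round(L$center_row * nr / image_shape[1])
        c0 <- round(L$center_col * nc / image_shape[2])
        if (offset_sigma > 0) {
          r0 <- r0 + stats::rnorm(1, 0, offset_sigma)
          c0 <- c0 + stats::rnorm(1, 0, offset_sigma)
        }
        grid <- add_blob(grid, r0, c0, h, spread)
        peak <- max(peak, h)
      }
    }
    if (fp_blob_rate > 0) n_fp <- stats::rpois(1, fp_blob_rate)
    if (n_fp > 0) {
      for (k in seq_len(n_fp)) {
        h <- fp_height * exp(stats::rnorm(1, 0, fp_noise_sd))
        grid <- add_blob(grid, stats::runif(1, 0, nr - 1),
                         stats::runif(1, 0, nc - 1), h, spread * 0.8)
        peak <- max(peak, h)
      }
    }
  })
  list(grid = grid, peak = peak, n_fp = n_fp)
}

# Monotone score link: u / (u + u50). Internal.
score_link <- function(u, u50) u / (u + u50)

# Sample one lesion's geometry inside the breast of a given view. Internal.
sample_lesion <- function(view, diameter_cm, config) {
  shape <- config$image_shape
  a <- diameter_cm / (2 * config$pixel_spacing_cm)
  a <- min(a, 0.42 * shape[1])
  b <- min(a * stats::runif(1, 0.3, 0.7), 0.30 * shape[2])
  b <- max(b, 4)
  nr <- shape[1]; nc <- shape[2]
  # sample center until the ellipse sits inside the breast half-ellipse
  for (i in 1:50) {
    cr <- stats::runif(1, a + 2, nr - a - 3)
    cw <- stats::runif(1, b + 2, 0.60 * nc)
    cc <- if (is_right_view(view)) (nc - 1) - cw else cw
    # worst-case ellipse point must satisfy the breast inequality
    q <- ((cr + a - (nr - 1) / 2) / (0.45 * nr))^2 + ((cw + b) / (0.72 * nc))^2
    q2 <- ((cr - a - (nr - 1) / 2) / (0.45 * nr))^2 + ((cw + b) / (0.72 * nc))^2
    if (max(q, q2) <= 0.96) {
      return(data.frame(view = view, center_row = cr, center_col = cc,
                        a = a, b = b, diameter_cm = diameter_cm,
                        intensity_gain = stats::runif(1, 0.3, 0.6),
                        stringsAsFactors = FALSE))
    }
  }
  # fall back to a guaranteed interior position near the chest wall
  cw <- b + 3
  cc <- if (is_right_view(view)) (nc - 1) - cw else cw
  data.frame(view = view, center_row = (nr - 1) / 2, center_col = cc,
             a = a, b = b, diameter_cm = diameter_cm,
             intensity_gain = 0.5, stringsAsFactors = FALSE)
}

truth_box_from_lesion <- function(lesion, case_id, reader = NA_character_) {
  annotation_box(max(0, round(lesion$center_row - lesion$a)),
                 max(0, round(lesion$center_col - lesion$b)),
                 round(lesion$center_row + lesion$a),
                 round(lesion$center_col + lesion$b),
                 case_id = case_id, reader = reader, view = lesion$view)
}

size_group_of <- function(diameter_cm) {
  if (diameter_cm <= 2) "T1" else if (diameter_cm < 5) "T2" else "T3"
}

# Displace a box to a far, disjoint location (total reader disagreement).
displace_box <- function(box, image_shape) {
  h <- box$row_max - box$row_min
  w <- box$col_max - box$col_min
  top_half <- (box$row_min + box$row_max) / 2 < image_shape[1] / 2
  r0 <- if (top_half) image_shape[1] - h - 5 else 5
  c0 <- max(0, min(box$col_min, image_shape[2] - w - 5))
  out <- box
  out$row_min <- r0; out$row_max <- r0 + h
  out$col_min <- c0; out$col_max <- c0 + w
  out
}

#' Generate a full synthetic screening cohort
#'
#' Produces `n_cases` cancer cases (category and size mixes respected
#' exactly by largest-remainder allocation) plus matched cancer-free cases,
#' with per-case truth lesions on both views of the cancer side, two
#' readers' jittered annotation boxes, per-view saliency maps, and per-view
#' malignancy scores. Fully reproducible from `config$seed`.
#'
#' @param config an [synth_config()] object.
#' @param render_images render per-view pixel images into each case (off by
#'   default: images are large and every downstream statistic works from
#'   boxes, maps and scores; [generate_image()] regenerates any case's
#'   images deterministically from its recorded `image_seed`).
#' @param with_saliency generate saliency maps and scores (on by default;
#'   turned off by the concordance-only calibration pilot).
#' @return object of class `mc_cohort`: list with
#'   \describe{
#'     \item{cases}{list of `mc_case` objects (id, laterality, category,
#'       size group, truth lesions, reader boxes, image seed, optional
#'       images).}
#'     \item{case_table}{one row per case: `case_id`, `category`,
#'       `size_group`, `laterality`, `intended_band`, `jitter_sigma_px`.}
#'     \item{annotations}{all reader boxes, stacked.}
#'     \item{saliency}{named list: case id -> view -> saliency matrix.}
#'     \item{scores}{data.frame `case_id`, `view`, `score`.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_cohort <- function(config, render_images = FALSE, with_saliency = TRUE) {
  stopifnot(inherits(config, "mc_config"))
  n <- config$n_cases
  n_normal <- round(config$normal_fraction * n)
  cat_counts <- largest_remainder(n, config$category_mix)
  categories <- rep(CATEGORIES, cat_counts)
  size_counts <- largest_remainder(n, config$size_mix)
  sizes <- rep(SIZE_GROUPS, size_counts)
  banded <- !is.null(config$band_sigmas)
  seeds <- derive_seeds(config$seed, 3L)
  # deterministic interleaving of sizes across categories, then per-case seeds
  sizes <- with_seed(seeds[1], sample(sizes))
  bands <- integer(n)
  if (banded) {
    for (cat in CATEGORIES) {
      idx <- which(categories == cat)
      bands[idx] <- rep_len(1:4, length(idx))
    }
  }
  case_seeds <- derive_seeds(seeds[2], n + n_normal)
  cases <- vector("list", n + n_normal)
  saliency <- list()
  scores <- list()
  ann <- list()
  tab <- list()
  for (i in seq_len(n + n_normal)) {
    is_cancer <- i <= n
    case_id <- sprintf("case_%04d", i)
    cs <- derive_seeds(case_seeds[i], 10L)
    band <- if (is_cancer && banded) bands[i] else NA_integer_
    category <- if (is_cancer) categories[i] else "normal"
    size_group <- if (is_cancer) sizes[i] else "none"
    built <- with_seed(cs[1], {
      laterality <- if (is_cancer) sample(c("left", "right"), 1) else "none"
      lesions <- NULL
      boxes <- NULL
      if (is_cancer) {
        views <- if (laterality == "left") c("LCC", "LMLO") else c("RCC", "RMLO")
        d_cm <- switch(size_group,
                       T1 = stats::runif(1, 0.8, 2),
                       T2 = stats::runif(1, 2, 5),
                       T3 = stats::runif(1, 5, 6.5))
        n_lesions <- 1L + (stats::runif(1) < config$multi_lesion_rate)
        lesions <- do.call(rbind, lapply(seq_len(n_lesions), function(l) {
          d <- if (l == 1) d_cm else stats::runif(1, 0.8, min(2, d_cm))
          do.call(rbind, lapply(views, sample_lesion, diameter_cm = d,
                                config = config))
        }))
      }
      list(laterality = laterality, lesions = lesions)
    })
    laterality <- built$laterality
    lesions <- built$lesions
    sigma_px <- NA_real_
    if (is_cancer) {
      base_sigma <- if (banded) config$band_sigmas[band] else config$jitter_sigma
      truth_boxes <- do.call(rbind, lapply(seq_len(nrow(lesions)), function(l)
        truth_box_from_lesion(lesions[l, ], case_id)))
      sigma_px <- if (config$jitter_mode == "relative") {
        vals <- unlist(lapply(seq_len(nrow(truth_boxes)), function(l)
          box_corner_values(truth_boxes[l, ])))
        base_sigma * stats::sd(vals)
      } else base_sigma
      jseeds <- derive_seeds(cs[2], 2L * nrow(truth_boxes) + nrow(truth_boxes))
      solo <- with_seed(cs[3], stats::runif(nrow(truth_boxes)) < config$solo_box_rate)
      boxes <- list()
      for (l in seq_len(nrow(truth_boxes))) {
        tb <- truth_boxes[l, ]
        ba <- jitter_box(tb, sigma_px, seed = jseeds[2 * l - 1],
                         image_shape = config$image_shape)
        bb <- jitter_box(tb, sigma_px, seed = jseeds[2 * l],
                         image_shape = config$image_shape)
        ba$reader <- "A"; bb$reader <- "B"
        if (solo[l]) bb <- displace_box(bb, config$image_shape)
        boxes[[length(boxes) + 1L]] <- ba
        boxes[[length(boxes) + 1L]] <- bb
      }
      boxes <- do.call(rbind, boxes)
      ann[[length(ann) + 1L]] <- boxes
    } else boxes <- NULL
    case <- structure(list(
      case_id = case_id, laterality_of_cancer = laterality,
      category = category, size_group = size_group,
      truth_lesions = lesions, reader_boxes = boxes,
      image_shape = config$image_shape, image_seed = cs[4]), class = "mc_case")
    if (render_images) {
      case$images <- lapply(stats::setNames(VIEWS, VIEWS), function(v) {
        vl <- if (!is.null(lesions)) lesions[lesions$view == v, ] else NULL
        generate_image(v, vl, config$noise_level,
                       seed = cs[4] + match(v, VIEWS),
                       image_shape = config$image_shape)$pixels
      })
    }
    if (with_saliency) {
      sseeds <- derive_seeds(cs[5], 5L)
      conspicuity <- with_seed(sseeds[5],
                               exp(stats::rnorm(1, 0, config$score_noise_sd)))
      bq <- if (is_cancer && banded) config$band_quality[band] else 1
      sq <- if (is_cancer) config$size_quality[[size_group]] else 1
      height <- conspicuity * bq * sq * config$quality_uplift
      off <- config$saliency_offset_sigma +
        if (is_cancer && banded) config$band_offset_add[band] else 0
      dq <- if (is_cancer) config$detect_quality[[category]] else 1
      smaps <- list()
      for (v in VIEWS) {
        vl <- if (!is.null(lesions)) lesions[lesions$view == v, ] else NULL
        if (!is.null(vl) && nrow(vl)) vl$height <- height
        sm <- generate_saliency(vl, offset_sigma = off,
                                spread = config$saliency_spread,
                                fp_blob_rate = config$fp_blob_rate,
                                seed = sseeds[match(v, VIEWS)],
                                saliency_shape = config$saliency_shape,
                                image_shape = config$image_shape,
                                fp_height = config$fp_height / config$quality_uplift,
                                fp_noise_sd = config$score_noise_sd)
        smaps[[v]] <- sm$grid
        u <- sm$peak * dq
        scores[[length(scores) + 1L]] <-
          data.frame(case_id = case_id, view = v,
                     score = score_link(u, config$score_u50),
                     stringsAsFactors = FALSE)
      }
      saliency[[case_id]] <- smaps
    }
    cases[[i]] <- case
    tab[[i]] <- data.frame(
      case_id = case_id, category = category, size_group = size_group,
      laterality = laterality,
      intended_band = if (!is.na(band)) LEVELS[band] else NA_character_,
      jitter_sigma_px = sigma_px, stringsAsFactors = FALSE)
  }
  structure(list(cases = cases, case_table = do.call(rbind, tab),
                 annotations = if (length(ann)) do.call(rbind, ann) else NULL,
                 saliency = saliency,
                 scores = if (length(scores)) do.call(rbind, scores) else NULL,
                 config = config), class = "mc_cohort")
}

#' Calibrate jitter sigmas to the four McBride bands
#'
#' Pilot simulation. In relative jitter mode the per-case concordance loss
#' 1 - CCC scales as sigma^2 times a right-skewed, approximately
#' sigma-free noise factor Z (a chi-square-like functional of the corner
#' perturbations). The pilot estimates Z empirically by pooling
#' scale-collapsed losses from concordance-only cohorts at a few probe
#' sigmas, then:
#' \itemize{
#'   \item almost perfect (one-sided, loss < 0.01): sigma chosen so that
#'     the 0.995 quantile of sigma^2 Z stays below the band edge;
#'   \item substantial and moderate (two-sided): sigma^2 chosen to maximize
#'     the empirical probability that sigma^2 Z falls inside the band;
#'   \item poor (one-sided, loss > 0.10): occupancy is monotone in sigma,
#'     so a fixed large sigma (near-total disagreement) is used.
#' }
#' Optimizing on the pooled Z sample avoids the selection noise of picking
#' the best probe directly.
#'
#' @param config base configuration (jitter mode is forced to relative).
#' @param n_pilot pilot cohort size per probe sigma.
#' @param seed pilot seed.
#' @param probes probe sigmas used to estimate the Z distribution.
#' @param sigma_poor the fixed sigma for the poor band.
#' @return named numeric vector of length 4 (relative sigmas per band).
#' @export
calibrate_band_sigmas <- function(config = synth_config(), n_pilot = 250,
                                  seed = 99L,
                                  probes = c(0.06, 0.10, 0.15, 0.22),
                                  sigma_poor = 2.4) {
  z <- numeric(0)
  for (k in seq_along(probes)) {
    cfg <- config
    cfg$n_cases <- as.integer(n_pilot)
    cfg$normal_fraction <- 0
    cfg$solo_box_rate <- 0
    cfg$jitter_mode <- "relative"
    cfg$jitter_sigma <- probes[k]
    cfg$band_sigmas <- NULL
    cfg$seed <- as.integer(seed + k)
    coh <- generate_cohort(cfg, with_saliency = FALSE)
    ct <- concordance_table(coh$annotations)
    loss <- 1 - ct$ccc
    loss[is.na(loss)] <- Inf  # unmatched cases count as maximal loss
    z <- c(z, loss / probes[k]^2)
  }
  band_m <- function(lo, hi) {
    m_grid <- exp(seq(log(lo / stats::quantile(z, 0.99)),
                      log(hi / stats::quantile(z, 0.05)), length.out = 400))
    occ <- vapply(m_grid, function(m) mean(m * z > lo & m * z <= hi), 0)
    m_grid[which.max(occ)]
  }
  sig <- c(almost_perfect = sqrt(0.01 / stats::quantile(z, 0.995)),
           substantial = sqrt(band_m(0.01, 0.05)),
           moderate = sqrt(band_m(0.05, 0.10)),
           poor = sigma_poor)
  stats::setNames(as.numeric(sig), LEVELS)
}
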