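# Interchange formats and the end-to-end pipeline driver.
# Annotations travel as CSV (case_id, reader, view, row_min, col_min,
# row_max, col_max); images as PNG; saliency maps as per-case CSV matrices;
# run metadata as JSON.

#' Read an annotation CSV
#'
#' Validates the schema and every row; malformed rows are rejected with
#' diagnostics naming the offending row numbers.
#'
#' @param path CSV file with the documented columns.
#' @return data.frame of annotation boxes.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  probs <- validate_boxes(df)
  if (length(probs))
    stop_mc(paste0("invalid annotation rows in '", path, "': ",
                   paste(probs, collapse = "; ")), "mc_bad_schema")
  df
}

#' Write an annotation CSV
#' @param boxes annotation data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(boxes, path) {
  utils::write.csv(boxes, path, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic evaluation pipeline into a directory
#'
#' simulate -> concordance -> agreement -> evaluate -> report. Every stage's
#' output is persisted under `out_dir` (named by the seed unless given):
#' annotations CSV, concordance CSV, agreement CSV, stratified tables CSV,
#' a JSON summary with rates and p-values, the exact configuration used,
#' and (for the first `n_png` cases) per-view PNG images. Deterministic
#' given the config seed; rerunning with the same seed reproduces every
#' table bit for bit.
#'
#' @param config an [synth_config()].
#' @param out_dir output directory; default `runs/seed_<seed>` under the
#'   current directory.
#' @param n_png number of cases whose view images are rendered to PNG.
#' @return the `mc_eval` object, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(config = synth_config(), out_dir = NULL, n_png = 2) {
  stopifnot(inherits(config, "mc_config"))
  out_dir <- out_dir %||% file.path("runs", paste0("seed_", config$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_list <- unclass(config)
  jsonlite::write_json(cfg_list, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cohort <- generate_cohort(config)
  write_annotations(cohort$annotations, file.path(out_dir, "annotations.csv"))
  conc <- concordance_table(cohort$annotations)
  utils::write.csv(conc, file.path(out_dir, "concordance.csv"), row.names = FALSE)
  agree <- agreement_table(cohort$saliency, annotations = cohort$annotations,
                           image_shape = config$image_shape,
                           mode = "map_vs_annotation")
  utils::write.csv(agree, file.path(out_dir, "agreement.csv"), row.names = FALSE)
  ev <- evaluate_cohort(cohort)
  utils::write.csv(ev$results, file.path(out_dir, "case_results.csv"),
                   row.names = FALSE)
  if (!is.null(ev$by_level_category))
    utils::write.csv(ev$by_level_category,
                     file.path(out_dir, "sensitivity_by_level_category.csv"),
                     row.names = FALSE)
  utils::write.csv(ev$by_size, file.path(out_dir, "sensitivity_by_size.csv"),
                   row.names = FALSE)
  summary_json <- list(
    n_cases = nrow(ev$results),
    sensitivity = ev$rates["sensitivity", "rate"],
    specificity = ev$rates["specificity", "rate"],
    p_category = ev$tests$category$p_value,
    p_level = if (!is.null(ev$tests$level)) ev$tests$level$p_value else NULL,
    mean_sim = if (nrow(agree)) mean(agree$sim) else NULL,
    mean_kld = if (nrow(agree)) mean(agree$kld) else NULL)
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (n_png > 0) {
    png_dir <- file.path(out_dir, "images")
    dir.create(png_dir, showWarnings = FALSE)
    for (i in seq_len(min(n_png, length(cohort$cases)))) {
      case <- cohort$cases[[i]]
      for (v in VIEWS) {
        vl <- if (!is.null(case$truth_lesions))
          case$truth_lesions[case$truth_lesions$view == v, ] else NULL
        img <- generate_image(v, vl, config$noise_level,
                              seed = case$image_seed + match(v, VIEWS),
                              image_shape = config$image_shape)$pixels
        img <- img / max(img, 1e-9)
        png::writePNG(img, file.path(png_dir,
                                     paste0(case$case_id, "_", v, ".png")))
      }
    }
  }
  invisible(ev)
}
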