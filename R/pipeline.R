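# End-to-end pipeline: simulate -> normalize -> measure -> summarize ->
# stats, with per-stage CSV outputs and a manifest (config hash, content
# hashes, row counts) for provenance.

#' Pipeline configuration
#'
#' @param out_dir Run directory (created if absent).
#' @param cohort A [cohort_spec()] (used by the simulate stage).
#' @param seed Master seed, recorded in the manifest.
#' @param target_level Common liver reference level.
#' @param canvas_w,canvas_h Canonical canvas dimensions.
#' @return Object of class `cxr_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, cohort = cohort_spec(), seed = 1,
                            target_level = 255,
                            canvas_w = CANONICAL_CANVAS[["width"]],
                            canvas_h = CANONICAL_CANVAS[["height"]]) {
  structure(list(out_dir = out_dir, cohort = cohort,
                 seed = as.integer(seed), target_level = target_level,
                 canvas_w = canvas_w, canvas_h = canvas_h),
            class = "cxr_pipeline_config")
}

#' Simulate stage: write a cohort to disk
#'
#' Writes one 16-bit TIFF + annotation JSON per patient, plus
#' `clinical.csv` and `patient_truth.csv`.
#'
#' @param config A [pipeline_config()].
#' @return The generated `cxr_cohort`, invisibly.
#' @export
stage_simulate <- function(config) {
  dir.create(file.path(config$out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  co <- generate_cohort(config$cohort, seed = config$seed)
  for (b in co$bundles) {
    base <- file.path(config$out_dir, "images", b$patient_id)
    write_radiograph(b$image, paste0(base, ".tif"))
    write_annotations(b$annotations, paste0(base, ".json"))
  }
  utils::write.csv(co$clinical, file.path(config$out_dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(co$patients,
                   file.path(config$out_dir, "patient_truth.csv"),
                   row.names = FALSE)
  invisible(co)
}

#' Normalize stage
#'
#' Normalizes every simulated image onto the canonical canvas; writes
#' float TIFFs, transformed annotation JSONs and `provenance.csv`
#' (reference level measured, size factor, interpolation).
#'
#' @param config A [pipeline_config()].
#' @return Tibble of provenance records, invisibly.
#' @export
stage_normalize <- function(config) {
  img_dir <- file.path(config$out_dir, "images")
  norm_dir <- file.path(config$out_dir, "normalized")
  dir.create(norm_dir, showWarnings = FALSE)
  jsons <- sort(list.files(img_dir, pattern = "\\.json$", full.names = TRUE))
  prov <- lapply(jsons, function(j) {
    id <- tools::file_path_sans_ext(basename(j))
    ann <- read_annotations(j)
    raw <- read_radiograph(file.path(img_dir, paste0(id, ".tif")),
                           image_id = id)
    norm <- tryCatch(
      normalize_radiograph(raw, ann, target_level = config$target_level,
                           canvas_w = config$canvas_w,
                           canvas_h = config$canvas_h),
      error = function(e) stop("stage normalize failed on image ", id, ": ",
                               conditionMessage(e), call. = FALSE))
    write_normalized(norm, file.path(norm_dir, paste0(id, ".tif")))
    write_annotations(norm$annotations, file.path(norm_dir, paste0(id, ".json")))
    tibble::tibble(image_id = id,
                   measured_reference = norm$measured_reference,
                   reference_level = norm$reference_level,
                   size_factor = norm$size_factor,
                   interpolation = norm$interpolation,
                   pixel_scale = 65535)
  })
  prov <- dplyr::bind_rows(prov)
  utils::write.csv(prov, file.path(config$out_dir, "provenance.csv"),
                   row.names = FALSE)
  invisible(prov)
}

#' Measure stage
#'
#' Measures MPI/FHPI of all 12 segments for every normalized image;
#' writes `measurements.csv` (long format, exclusions retained).
#'
#' @param config A [pipeline_config()].
#' @return Measurement tibble, invisibly.
#' @export
stage_measure <- function(config) {
  norm_dir <- file.path(config$out_dir, "normalized")
  prov <- utils::read.csv(file.path(config$out_dir, "provenance.csv"))
  jsons <- sort(list.files(norm_dir, pattern = "\\.json$", full.names = TRUE))
  meas <- lapply(jsons, function(j) {
    id <- tools::file_path_sans_ext(basename(j))
    ann <- read_annotations(j)
    pr <- prov[prov$image_id == id, ]
    norm <- read_normalized(file.path(norm_dir, paste0(id, ".tif")), ann,
                            reference_level = pr$reference_level,
                            size_factor = pr$size_factor)
    tryCatch(measure_image(norm),
             error = function(e) stop("stage measure failed on image ", id,
                                      ": ", conditionMessage(e), call. = FALSE))
  })
  meas <- dplyr::bind_rows(meas)
  utils::write.csv(meas, file.path(config$out_dir, "measurements.csv"),
                   row.names = FALSE)
  invisible(meas)
}

#' Summarize stage
#'
#' Writes `lung_summaries.csv`, `segment_means.csv` (per group and
#' metric) and `gradients.csv` (apico-basal fits per group, side, metric).
#'
#' @param config A [pipeline_config()].
#' @return List of the three tibbles, invisibly.
#' @export
stage_summarize <- function(config) {
  meas <- tibble::as_tibble(
    utils::read.csv(file.path(config$out_dir, "measurements.csv")))
  clinical <- utils::read.csv(file.path(config$out_dir, "clinical.csv"))
  groups <- unique(clinical[, c("patient_id", "group")])
  meas <- dplyr::left_join(meas, groups, by = c(image_id = "patient_id"))

  summaries <- lung_field_summary(meas)
  cells <- dplyr::bind_rows(lapply(unique(meas$group), function(g) {
    dplyr::bind_rows(lapply(c("mpi", "fhpi"), function(metric) {
      out <- group_segment_means(meas[meas$group == g, ], metric)
      dplyr::bind_cols(tibble::tibble(group = g, metric = metric), out)
    }))
  }))
  grads <- dplyr::bind_rows(lapply(unique(meas$group), function(g) {
    dplyr::bind_rows(lapply(c("mpi", "fhpi"), function(metric) {
      out <- group_gradients(meas[meas$group == g, ], metric)
      dplyr::bind_cols(tibble::tibble(group = g), out)
    }))
  }))
  utils::write.csv(summaries, file.path(config$out_dir, "lung_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(cells, file.path(config$out_dir, "segment_means.csv"),
                   row.names = FALSE)
  utils::write.csv(grads, file.path(config$out_dir, "gradients.csv"),
                   row.names = FALSE)
  invisible(list(summaries = summaries, segment_means = cells,
                 gradients = grads))
}

#' Stats stage
#'
#' Writes `stats_report.csv`, `stats_posthoc.csv` and a human-readable
#' `stats_report.txt`.
#'
#' @param config A [pipeline_config()].
#' @return The [stats_report()] list, invisibly.
#' @export
stage_stats <- function(config) {
  meas <- tibble::as_tibble(
    utils::read.csv(file.path(config$out_dir, "measurements.csv")))
  summaries <- tibble::as_tibble(
    utils::read.csv(file.path(config$out_dir, "lung_summaries.csv")))
  clinical <- tibble::as_tibble(
    utils::read.csv(file.path(config$out_dir, "clinical.csv")))
  rep <- stats_report(meas, summaries, clinical)
  utils::write.csv(rep$report, file.path(config$out_dir, "stats_report.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$posthoc, file.path(config$out_dir, "stats_posthoc.csv"),
                   row.names = FALSE)
  txt <- c("Statistical report",
           "==================",
           sprintf("%-45s %-22s stat=%8.3f  p=%.4g",
                   rep$report$comparison, rep$report$method,
                   ifelse(is.na(rep$report$statistic), 0, rep$report$statistic),
                   rep$report$p))
  writeLines(txt, file.path(config$out_dir, "stats_report.txt"))
  invisible(rep)
}

#' Run the full pipeline
#'
#' simulate -> normalize -> measure -> summarize -> stats, then writes
#' `manifest.json` listing every output file with its MD5 content hash
#' and row count. Re-running with the same configuration is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return The run directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cxr_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_simulate(config)
  stage_normalize(config)
  stage_measure(config)
  stage_summarize(config)
  stage_stats(config)

  files <- sort(list.files(config$out_dir, recursive = TRUE))
  files <- files[files != "manifest.json"]
  entries <- lapply(files, function(f) {
    path <- file.path(config$out_dir, f)
    rows <- if (grepl("\\.csv$", f)) length(readLines(path)) - 1L else NA_integer_
    list(path = f, md5 = unname(tools::md5sum(path)), rows = rows)
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("cxraeration")),
    seed = config$seed,
    target_level = config$target_level,
    canvas = c(config$canvas_w, config$canvas_h),
    n_stg = config$cohort$n_stg, n_psg = config$cohort$n_psg,
    files = entries)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
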