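# Simulated patient cohorts: one phantom radiograph per patient, plus a
# clinical covariate table (MAP, FiO2, VT, respiratory severity score,
# radiological grade) whose day-1 mean airway pressure is linearly coupled
# to the patient's true mean MPI.

#' Cohort specification
#'
#' Two groups mirror the study design: a surfactant-treated group (STG)
#' and a smaller pre-surfactant group (PSG) whose lungs are more aerated
#' (lower MPI, `group_offset_psg`). Between-patient variability enters as
#' a common shift of both lungs' base intensities; each patient also gets
#' an independent exposure gain that the normalization must cancel.
#'
#' The day-1 MAP model is `MAP_i = alpha + beta * MPI_i + eps_i`. The
#' residual SD defaults to the value that makes the population MPI-MAP
#' correlation equal `map_r`:
#' `resid_sd = beta * sd_patient_shift * sqrt(1 / map_r^2 - 1)`.
#'
#' @param n_stg,n_psg Patients per group (each >= 2).
#' @param base_spec Template [phantom_spec()] shared by all patients.
#' @param sd_patient_shift SD (intensity units) of the per-patient base
#'   intensity shift.
#' @param group_offset_psg Additive MPI offset of the PSG group.
#' @param sd_log_gain SD of the per-patient log exposure gain.
#' @param map_alpha Intercept of the MAP model (cmH2O); default chosen so
#'   the mean MAP is ~9 cmH2O at the template's mean MPI.
#' @param map_beta Slope of the MAP model (cmH2O per intensity unit).
#' @param map_r Target population MPI-MAP correlation (used only to derive
#'   the default residual SD).
#' @param map_resid_sd Residual SD of the MAP model; overrides `map_r`.
#' @param fio2_range Uniform range for FiO2 (clamped to [0.21, 1]).
#' @param vt_mean,vt_sd Tidal volume means per day (1, 3, 7) and SD (mL/kg).
#' @param grade_thresholds Three strictly increasing MPI cut points mapping
#'   patient mean MPI to radiological grades 1-4.
#' @param grade_noise Probability that a grade is perturbed by one step.
#' @param p_r7_overlap Probability that an STG patient's right-7 segment is
#'   flagged `liver_overlap` (poorly inflated lung over the liver).
#' @return Object of class `cxr_cohort_spec`.
#' @export
cohort_spec <- function(n_stg = 52, n_psg = 8,
                        base_spec = phantom_spec(),
                        sd_patient_shift = 10, group_offset_psg = -10,
                        sd_log_gain = 0.15,
                        map_alpha = NULL, map_beta = 0.2,
                        map_r = 0.48, map_resid_sd = NULL,
                        fio2_range = c(0.25, 0.50),
                        vt_mean = c(5.0, 4.3, 5.8), vt_sd = 0.8,
                        grade_thresholds = c(100, 110, 120),
                        grade_noise = 0.1,
                        p_r7_overlap = 7 / 52) {
  if (n_stg < 2 || n_psg < 2) stop("each group needs at least 2 patients")
  if (any(diff(grade_thresholds) <= 0) || length(grade_thresholds) != 3) {
    stop("grade_thresholds must be 3 strictly increasing values")
  }
  template_mpi <- mean(phantom_truth(base_spec)$segment_mean)
  if (is.null(map_resid_sd)) {
    map_resid_sd <- map_beta * sd_patient_shift * sqrt(1 / map_r^2 - 1)
  }
  if (map_resid_sd < 0) stop("map_resid_sd must be non-negative")
  if (is.null(map_alpha)) map_alpha <- 9 - map_beta * template_mpi
  structure(list(n_stg = n_stg, n_psg = n_psg, base_spec = base_spec,
                 sd_patient_shift = sd_patient_shift,
                 group_offset_psg = group_offset_psg,
                 sd_log_gain = sd_log_gain,
                 map_alpha = map_alpha, map_beta = map_beta,
                 map_r = map_r, map_resid_sd = map_resid_sd,
                 fio2_range = fio2_range, vt_mean = vt_mean, vt_sd = vt_sd,
                 grade_thresholds = grade_thresholds,
                 grade_noise = grade_noise,
                 p_r7_overlap = p_r7_overlap),
            class = "cxr_cohort_spec")
}

# Deterministic per-patient seed derived from the master seed; kept below
# .Machine$integer.max.
patient_seed <- function(master, i) {
  x <- (as.numeric(master) %% 2147483647) * 1000003 + i * 10007
  as.integer(x %% 2147483647)
}

#' Generate a simulated cohort
#'
#' Patient-level parameters and the clinical table are drawn first under
#' the master seed, then each radiograph is rendered with its own derived
#' seed, so the clinical table is identical whether or not images are
#' rendered, and regeneration with the same master seed is bit-identical.
#'
#' @param cohort A [cohort_spec()].
#' @param seed Master integer seed.
#' @param render If `FALSE`, skip image rasterization (the per-patient
#'   phantom specs and ground truth are still returned); useful for
#'   statistical replication studies that only need truth and covariates.
#' @return Object of class `cxr_cohort`: list with `bundles` (list of
#'   `cxr_phantom`, or per-patient specs when `render = FALSE`),
#'   `clinical` (tibble, one row per patient per day 1/3/7), `patients`
#'   (per-patient truth tibble) and `spec`.
#' @export
generate_cohort <- function(cohort, seed = 1, render = TRUE) {
  stopifnot(inherits(cohort, "cxr_cohort_spec"))
  n <- cohort$n_stg + cohort$n_psg
  group <- c(rep("STG", cohort$n_stg), rep("PSG", cohort$n_psg))
  ids <- sprintf("P%03d", seq_len(n))

  withr::with_seed(as.integer(seed), {
    shift <- stats::rnorm(n, 0, cohort$sd_patient_shift)
    gain <- exp(stats::rnorm(n, 0, cohort$sd_log_gain))
    r7_overlap <- group == "STG" &
      stats::runif(n) < cohort$p_r7_overlap
    eps_map <- stats::rnorm(n, 0, cohort$map_resid_sd)
    map_drift3 <- stats::rnorm(n, -1, 1.5)
    map_drift7 <- stats::rnorm(n, -1, 1.5)
    fio2 <- matrix(stats::runif(3 * n, cohort$fio2_range[1],
                                cohort$fio2_range[2]), ncol = 3)
    vt <- sapply(1:3, function(d) stats::rnorm(n, cohort$vt_mean[d], cohort$vt_sd))
    grade_u <- stats::runif(n)
    grade_dir <- sample(c(-1L, 1L), n, replace = TRUE)
  })

  offset <- ifelse(group == "PSG", cohort$group_offset_psg, 0)
  specs <- lapply(seq_len(n), function(i) {
    b <- cohort$base_spec
    qc <- b$qc_flags
    if (r7_overlap[i]) qc$right_7 <- "liver_overlap"
    phantom_spec(
      canvas_w = b$canvas_w, canvas_h = b$canvas_h,
      base_intensity_right = b$base_intensity_right + shift[i] + offset[i],
      base_intensity_left = b$base_intensity_left + shift[i] + offset[i],
      slope_right = b$slope_right, slope_left = b$slope_left,
      speckle_sd = b$speckle_sd,
      liver_intensity = b$liver_intensity, background = b$background,
      bit_depth = b$bit_depth, scale_bar_mm = b$scale_bar_mm,
      scale_bar_px = b$scale_bar_px,
      exposure_gain = b$exposure_gain * gain[i],
      lung_geometry = b$lung_geometry, qc_flags = qc)
  })
  mpi_true <- vapply(specs, function(s) mean(phantom_truth(s)$segment_mean),
                     numeric(1))

  map1 <- cohort$map_alpha + cohort$map_beta * mpi_true + eps_map
  map3 <- map1 + map_drift3
  map7 <- map3 + map_drift7
  grade <- findInterval(mpi_true, cohort$grade_thresholds) + 1L
  noisy <- grade_u < cohort$grade_noise
  grade[noisy] <- pmin(pmax(grade[noisy] + grade_dir[noisy], 1L), 4L)

  clinical <- dplyr::bind_rows(lapply(1:3, function(d) {
    day <- c(1L, 3L, 7L)[d]
    map_d <- list(map1, map3, map7)[[d]]
    fio2_d <- pmin(pmax(fio2[, d], 0.21), 1.0)
    tibble::tibble(patient_id = ids, group = group, day = day,
                   map = map_d, fio2 = fio2_d, vt = vt[, d],
                   rss = map_d * fio2_d, grade = grade)
  })) |> dplyr::arrange(.data$patient_id, .data$day)

  patients <- tibble::tibble(patient_id = ids, group = group,
                             mean_mpi_true = mpi_true,
                             base_shift = shift, exposure_gain = gain,
                             r7_liver_overlap = r7_overlap,
                             seed = vapply(seq_len(n), function(i)
                               patient_seed(seed, i), integer(1)))

  bundles <- lapply(seq_len(n), function(i) {
    if (!render) {
      return(list(patient_id = ids[i], spec = specs[[i]],
                  truth = phantom_truth(specs[[i]])))
    }
    ph <- generate_phantom(specs[[i]], seed = patient_seed(seed, i))
    ph$image$image_id <- ids[i]
    ph$annotations$image_id <- ids[i]
    ph$patient_id <- ids[i]
    ph
  })
  names(bundles) <- ids

  structure(list(bundles = bundles, clinical = clinical,
                 patients = patients, spec = cohort, seed = as.integer(seed),
                 rendered = render),
            class = "cxr_cohort")
}
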