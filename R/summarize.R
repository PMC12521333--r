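# Per-lung summaries, group-level segment means, and apico-basal gradient
# fits. STDV-MPI / STDV-FHPI are between-segment heterogeneity indices: the
# sample SD of the six segment MPIs (or FHPIs) of one lung field.

#' Per-lung-field summaries
#'
#' For each image and side, the mean and sample SD of the segment MPI
#' values (mean_mpi, stdv_mpi) and of the segment FHPI values (mean_fhpi,
#' stdv_fhpi), computed over non-excluded segments only.
#'
#' @param measurements Tibble from [measure_image()] (one or many images).
#' @return Tibble with one row per image x side; rows with fewer than two
#'   usable segments are marked `available = FALSE`.
#' @export
lung_field_summary <- function(measurements) {
  measurements |>
    dplyr::group_by(.data$image_id, .data$side) |>
    dplyr::summarise(
      n_segments = sum(!.data$excluded),
      mean_mpi = ifelse(n_segments >= 2, mean(.data$mpi[!.data$excluded]), NA_real_),
      stdv_mpi = ifelse(n_segments >= 2, stats::sd(.data$mpi[!.data$excluded]), NA_real_),
      mean_fhpi = ifelse(n_segments >= 2, mean(.data$fhpi[!.data$excluded]), NA_real_),
      stdv_fhpi = ifelse(n_segments >= 2, stats::sd(.data$fhpi[!.data$excluded]), NA_real_),
      available = n_segments >= 2,
      .groups = "drop")
}

#' Group-level per-segment means
#'
#' Arithmetic mean of a metric per (side, space) cell over the images of a
#' group, with the number of contributing patients per cell. Excluded
#' measurements do not contribute; an empty cell is marked missing.
#'
#' @param measurements Measurement tibble (already restricted to one group).
#' @param metric `"mpi"` or `"fhpi"`.
#' @return Tibble with columns side, space, mean, n_patients, missing.
#' @export
group_segment_means <- function(measurements, metric = c("mpi", "fhpi")) {
  metric <- match.arg(metric)
  grid <- tidyr::expand_grid(side = SIDES, space = as.integer(SPACES))
  cells <- measurements |>
    dplyr::filter(!.data$excluded) |>
    dplyr::group_by(.data$side, .data$space) |>
    dplyr::summarise(mean = mean(.data[[metric]]),
                     n_patients = dplyr::n(), .groups = "drop")
  grid |>
    dplyr::left_join(cells, by = c("side", "space")) |>
    dplyr::mutate(n_patients = tidyr::replace_na(.data$n_patients, 0L),
                  missing = .data$n_patients == 0L) |>
    dplyr::arrange(match(.data$side, SIDES), .data$space)
}

#' Apico-basal gradient fit for one lung side
#'
#' Pearson correlation and ordinary least-squares line of the per-segment
#' cell means against the intercostal space index (2 apical to 7 basal);
#' the two-sided p comes from `t = r * sqrt((n - 2) / (1 - r^2))` with
#' n - 2 degrees of freedom.
#'
#' @param cell_means Tibble with columns `space` and `mean` (one side,
#'   e.g. a filtered [group_segment_means()] result).
#' @return One-row tibble: r, slope, intercept, p, n_points, note. When the
#'   cell means have zero variance, `r` is reported as `NA` (undefined),
#'   not 0.
#' @export
apicobasal_gradient <- function(cell_means) {
  cm <- cell_means[!is.na(cell_means$mean) & !(cell_means$missing %||% FALSE), ]
  if (nrow(cm) < 3) stop("gradient fit needs at least 3 non-missing cells")
  x <- as.numeric(cm$space); y <- cm$mean
  if (stats::sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, slope = 0, intercept = mean(y),
                          p = NA_real_, n_points = length(x),
                          note = "undefined: zero variance in cell means"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  tibble::tibble(r = unname(ct$estimate),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 p = ct$p.value,
                 n_points = length(x),
                 note = NA_character_)
}

#' Gradient fits for both sides of a group
#'
#' @param measurements Measurement tibble restricted to one group.
#' @param metric `"mpi"` or `"fhpi"`.
#' @return Tibble with one row per side.
#' @export
group_gradients <- function(measurements, metric = c("mpi", "fhpi")) {
  metric <- match.arg(metric)
  cells <- group_segment_means(measurements, metric)
  dplyr::bind_rows(lapply(SIDES, function(s) {
    g <- apicobasal_gradient(cells[cells$side == s, ])
    dplyr::bind_cols(tibble::tibble(side = s, metric = metric), g)
  }))
}
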