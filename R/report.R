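# The default comparison report: the study's comparison set assembled
# from segment measurements, lung-field summaries and the clinical table.

patient_mean_mpi <- function(measurements) {
  measurements |>
    dplyr::filter(!.data$excluded) |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(mean_mpi = mean(.data$mpi), .groups = "drop")
}

row_with <- function(tr, comparison) {
  dplyr::bind_cols(tibble::tibble(comparison = comparison),
                   tr[, c("method", "statistic", "df", "p", "estimate",
                          "n1", "n2", "note")])
}

# A comparison that cannot be computed (e.g. too few usable observations
# in a small cohort) is reported as an NA row, not an error.
safe_row <- function(expr, comparison) {
  tryCatch(row_with(expr, comparison), error = function(e) {
    tibble::tibble(comparison = comparison, method = NA_character_,
                   statistic = NA_real_, df = NA_real_, p = NA_real_,
                   estimate = NA_real_, n1 = NA_integer_, n2 = NA_integer_,
                   note = paste("not computed:", conditionMessage(e)))
  })
}

#' Assemble the default statistical report
#'
#' Reproduces the study's comparison set: STG vs PSG per-lung mean MPI
#' (Welch), left vs right mean MPI within each group (Welch), right-7 vs
#' left-7 FHPI in the STG (Welch), correlations of patient mean MPI with
#' day-1/3/7 MAP, day-1 FiO2, RSS, VT and the radiological grade
#' (Pearson), and day-1/3/7 tidal-volume comparisons via repeated-measures
#' ANOVA with Bonferroni-adjusted pairwise paired t tests and via the
#' Friedman test with Conover's post hoc. No multiplicity adjustment is
#' applied across distinct hypotheses; post hoc adjustment is applied only
#' within the repeated-measures families.
#'
#' @param measurements Segment measurement tibble (all images), with an
#'   `image_id` equal to the patient id.
#' @param summaries Output of [lung_field_summary()].
#' @param clinical Clinical covariate tibble from [generate_cohort()] (or
#'   same schema: patient_id, group, day, map, fio2, vt, rss, grade).
#' @return List with `report` (one row per comparison) and `posthoc`
#'   (pairwise day comparisons for tidal volume).
#' @export
stats_report <- function(measurements, summaries, clinical) {
  groups <- clinical |>
    dplyr::distinct(.data$patient_id, .data$group)
  su <- summaries |>
    dplyr::left_join(groups, by = c(image_id = "patient_id"))

  pick <- function(g, s) su$mean_mpi[su$group == g & su$side == s & su$available]
  rows <- list()
  for (s in SIDES) {
    rows[[length(rows) + 1]] <- safe_row(
      welch_t_test(pick("STG", s), pick("PSG", s)),
      sprintf("mean MPI %s lung: STG vs PSG", s))
  }
  for (g in c("STG", "PSG")) {
    rows[[length(rows) + 1]] <- safe_row(
      welch_t_test(pick(g, "left"), pick(g, "right")),
      sprintf("mean MPI left vs right lung (%s)", g))
  }

  stg_ids <- groups$patient_id[groups$group == "STG"]
  m_stg <- measurements[measurements$image_id %in% stg_ids, ]
  f7 <- function(s) {
    m_stg$fhpi[m_stg$side == s & m_stg$space == 7 & !m_stg$excluded]
  }
  rows[[length(rows) + 1]] <- safe_row(
    welch_t_test(f7("right"), f7("left")),
    "FHPI right-7 vs left-7 segment (STG)")

  pm <- patient_mean_mpi(measurements)
  corr_against <- function(day, var, label) {
    cl <- clinical[clinical$day == day, ]
    j <- dplyr::inner_join(pm, cl, by = c(image_id = "patient_id"))
    safe_row(pearson_correlation(j$mean_mpi, j[[var]]),
             sprintf("MPI vs %s (day %d)", label, day))
  }
  for (d in c(1L, 3L, 7L)) {
    rows[[length(rows) + 1]] <- corr_against(d, "map", "MAP")
  }
  rows[[length(rows) + 1]] <- corr_against(1L, "fio2", "FiO2")
  rows[[length(rows) + 1]] <- corr_against(1L, "rss", "RSS")
  rows[[length(rows) + 1]] <- corr_against(1L, "vt", "VT")
  rows[[length(rows) + 1]] <- corr_against(1L, "grade", "radiological grade")

  vt_wide <- clinical |>
    dplyr::select("patient_id", "day", "vt") |>
    tidyr::pivot_wider(names_from = "day", values_from = "vt",
                       names_prefix = "day") |>
    dplyr::select(-"patient_id") |>
    as.matrix()
  rows[[length(rows) + 1]] <- safe_row(rm_anova(vt_wide),
                                       "VT across days 1/3/7 (RM-ANOVA)")
  rows[[length(rows) + 1]] <- safe_row(friedman_test(vt_wide),
                                       "VT across days 1/3/7 (Friedman)")

  # post hoc: Bonferroni-adjusted pairwise paired t after RM-ANOVA, and
  # Conover pairs after Friedman
  pairs <- utils::combn(colnames(vt_wide), 2)
  tt <- lapply(seq_len(ncol(pairs)), function(q) {
    a <- vt_wide[, pairs[1, q]]; b <- vt_wide[, pairs[2, q]]
    pt <- stats::t.test(a, b, paired = TRUE)
    tibble::tibble(family = "RM-ANOVA/Bonferroni",
                   treatment_1 = pairs[1, q], treatment_2 = pairs[2, q],
                   statistic = unname(pt$statistic),
                   df = unname(pt$parameter), p = pt$p.value)
  })
  tt <- dplyr::bind_rows(tt)
  tt$p_adjusted <- bonferroni_adjust(tt$p, nrow(tt))
  cv <- conover_posthoc(vt_wide)
  cv <- tibble::tibble(family = "Friedman/Conover",
                       treatment_1 = cv$treatment_1,
                       treatment_2 = cv$treatment_2,
                       statistic = cv$statistic, df = cv$df, p = cv$p,
                       p_adjusted = cv$p_bonferroni)

  list(report = dplyr::bind_rows(rows), posthoc = dplyr::bind_rows(tt, cv))
}
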