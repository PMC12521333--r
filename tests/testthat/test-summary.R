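mk_meas <- function(mpi, fhpi = rep(1, 12), excluded = rep(FALSE, 12),
                    id = "img1") {
  tibble::tibble(image_id = id,
                 side = rep(c("right", "left"), each = 6),
                 space = rep(2:7, 2),
                 mpi = mpi, fhpi = fhpi, n_pixels = 100L,
                 excluded = excluded,
                 reason = ifelse(excluded, "liver_overlap", NA_character_))
}

test_that("lung-field summaries reduce to closed forms", {
  m <- mk_meas(mpi = rep(110, 12), fhpi = rep(3, 12))
  s <- lung_field_summary(m)
  expect_equal(nrow(s), 2)
  expect_equal(s$mean_mpi, c(110, 110))
  expect_equal(s$stdv_mpi, c(0, 0))
  expect_equal(s$n_segments, c(6L, 6L))

  m2 <- mk_meas(mpi = c(100, 120, rep(NA, 4), rep(105, 6)),
                excluded = c(FALSE, FALSE, rep(TRUE, 4), rep(FALSE, 6)))
  m2$mpi[is.na(m2$mpi)] <- 0
  s2 <- lung_field_summary(m2)
  right <- s2[s2$side == "right", ]
  expect_equal(right$mean_mpi, 110)
  expect_equal(right$stdv_mpi, 14.1421, tolerance = 1e-4)
  expect_equal(right$n_segments, 2L)
})

test_that("stdv_mpi is zero iff all usable segment MPIs are equal", {
  m <- mk_meas(mpi = c(rep(104, 6), rep(111, 6)))
  s <- lung_field_summary(m)
  expect_true(all(s$stdv_mpi == 0))
  m$mpi[1] <- 105
  expect_gt(lung_field_summary(m)$stdv_mpi[
    lung_field_summary(m)$side == "right"], 0)
})

test_that("right-7 exclusions reduce n_segments, not the patient", {
  excl <- rep(FALSE, 12); excl[6] <- TRUE  # right space 7
  s <- lung_field_summary(mk_meas(mpi = 100 + 1:12, excluded = excl))
  expect_equal(s$n_segments[s$side == "right"], 5L)
  expect_equal(s$n_segments[s$side == "left"], 6L)
})

test_that("group segment means average patients per cell and flag empties", {
  m <- dplyr::bind_rows(mk_meas(rep(100, 12), id = "a"),
                        mk_meas(rep(120, 12), id = "b"))
  g <- group_segment_means(m, "mpi")
  expect_equal(nrow(g), 12)
  expect_true(all(g$mean == 110))
  expect_true(all(g$n_patients == 2L))
  # single patient: cell means equal that patient's values
  g1 <- group_segment_means(mk_meas(1:12), "mpi")
  expect_equal(g1$mean[g1$side == "right"], 1:6 + 0)
  # all-excluded cell is marked missing
  excl <- rep(FALSE, 12); excl[6] <- TRUE
  g2 <- group_segment_means(mk_meas(rep(5, 12), excluded = excl), "mpi")
  expect_true(g2$missing[g2$side == "right" & g2$space == 7])
})

test_that("apico-basal gradient matches hand OLS on an arithmetic sequence", {
  cells <- tibble::tibble(space = 2:7,
                          mean = c(116, 114, 112, 110, 108, 106),
                          missing = FALSE)
  g <- apicobasal_gradient(cells)
  expect_equal(g$slope, -2.0)
  expect_equal(g$intercept, 120.0)
  expect_equal(g$r, -1)
  expect_equal(g$n_points, 6L)
  # p from t = r sqrt((n-2)/(1-r^2)), n-2 df: sanity on a noisy line
  cells$mean <- cells$mean + c(0.1, -0.2, 0.05, 0.1, -0.1, 0)
  g2 <- apicobasal_gradient(cells)
  tval <- g2$r * sqrt((g2$n_points - 2) / (1 - g2$r^2))
  expect_equal(g2$p, 2 * pt(-abs(tval), g2$n_points - 2), tolerance = 1e-12)
})

test_that("degenerate gradients report undefined r, not zero", {
  cells <- tibble::tibble(space = 2:7, mean = rep(110, 6), missing = FALSE)
  g <- apicobasal_gradient(cells)
  expect_true(is.na(g$r))
  expect_match(g$note, "undefined")
  expect_error(apicobasal_gradient(cells[1:2, ]), "at least 3")
})

test_that("noiseless cohort cell means lie exactly on the injected line", {
  cs <- cohort_spec(n_stg = 2, n_psg = 2, sd_patient_shift = 0,
                    group_offset_psg = 0, sd_log_gain = 0,
                    base_spec = tiny_spec(speckle_sd = 0, slope_right = -2,
                                          slope_left = -2))
  co <- generate_cohort(cs, seed = 3)
  meas <- dplyr::bind_rows(lapply(co$bundles, measure_phantom))
  g <- group_segment_means(meas, "mpi")
  for (side in c("right", "left")) {
    fit <- apicobasal_gradient(g[g$side == side, ])
    expect_equal(fit$slope, -2, tolerance = 1e-9)
    expect_equal(fit$r, -1, tolerance = 1e-9)
  }
})

test_that("injected left-right base offset is recovered in mean MPI", {
  cs <- cohort_spec(n_stg = 2, n_psg = 2, sd_patient_shift = 0,
                    group_offset_psg = 0, sd_log_gain = 0,
                    base_spec = tiny_spec(speckle_sd = 0,
                                          base_intensity_right = 110,
                                          base_intensity_left = 115,
                                          slope_right = -1.5,
                                          slope_left = -1.5))
  co <- generate_cohort(cs, seed = 2)
  meas <- dplyr::bind_rows(lapply(co$bundles, measure_phantom))
  s <- lung_field_summary(meas)
  diff_lr <- mean(s$mean_mpi[s$side == "left"]) -
    mean(s$mean_mpi[s$side == "right"])
  expect_lt(abs(diff_lr - 5), 0.5)
})
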