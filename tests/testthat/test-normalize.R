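test_that("liver reference is the regional maximum", {
  img <- matrix(10, 64, 64)
  img[20, 20] <- 250; img[21, 20] <- 100
  poly <- rect_polygon(15.5, 15.5, 25.5, 25.5)
  expect_equal(find_reference_intensity(img, poly), 250)
  # uniform plateau
  img2 <- matrix(117, 64, 64)
  expect_equal(find_reference_intensity(img2, poly), 117)
  # empty region and zero reference are errors
  expect_error(find_reference_intensity(img, rect_polygon(200, 200, 210, 210)),
               "no pixels")
  expect_error(find_reference_intensity(matrix(0, 64, 64), poly), "zero")
})

test_that("reference from a written phantom image matches generator arithmetic", {
  s <- tiny_spec(liver_intensity = 900, bit_depth = 16, exposure_gain = 1.3)
  ph <- generate_phantom(s, seed = 8)
  path <- withr::local_tempfile(fileext = ".tif")
  write_radiograph(ph$image, path)
  raw <- read_radiograph(path, bit_depth = 16)
  ref <- find_reference_intensity(raw, ph$annotations$liver_region)
  expect_equal(ref, 900 * 1.3, tolerance = 1e-6)
})

test_that("intensity normalization is a pure linear scaling", {
  img <- matrix(50, 64, 64)
  expect_equal(normalize_intensity(img, reference = 200, target_level = 100)[1, 1],
               25.0)
  expect_equal(normalize_intensity(img, 117, 117), img)
  expect_error(normalize_intensity(img, 0, 100), "reference")
})

test_that("exposure gain cancels end to end", {
  s1 <- tiny_spec(exposure_gain = 1.0)
  s2 <- tiny_spec(exposure_gain = 1.6)
  n1 <- norm_small(generate_phantom(s1, 3)$image, generate_phantom(s1, 3)$annotations)
  n2 <- norm_small(generate_phantom(s2, 3)$image, generate_phantom(s2, 3)$annotations)
  rel <- abs(n2$pixels - n1$pixels) / pmax(abs(n1$pixels), 1e-9)
  expect_lt(max(rel), 1e-9)
})

test_that("size factor maps the scale bar to 5 px/mm", {
  sb <- function(len, mm) list(p1 = c(0, 0), p2 = c(len, 0), mm = mm)
  expect_equal(compute_size_factor(sb(100, 10)), 0.5)
  expect_equal(compute_size_factor(sb(50, 10)), 1.0)
  expect_equal(compute_size_factor(sb(80, 20)), 1.25)
  expect_error(compute_size_factor(sb(0, 10)), "coincide")
})

test_that("bilinear resampling preserves identity and constants", {
  img <- matrix(runif(100 * 100), 100, 100)
  expect_identical(resample_image(img, 1), img)
  cst <- matrix(7.5, 100, 100)
  half <- resample_image(cst, 0.5)
  expect_equal(dim(half), c(50, 50))
  expect_equal(half, matrix(7.5, 50, 50))
  expect_error(resample_image(img, 0.05), "out of range")
  expect_error(resample_image(matrix(1, 20, 20), 0.3), "8x8")
})

test_that("resampling by 0.5 perturbs segment MPI by less than 0.5 units", {
  ph1 <- generate_phantom(phantom_spec(scale_bar_px = 50), seed = 21)
  ph2 <- generate_phantom(phantom_spec(scale_bar_px = 100), seed = 21)
  m1 <- measure_image(normalize_radiograph(ph1$image, ph1$annotations,
                                           canvas_w = 700, canvas_h = 600))
  m2 <- measure_image(normalize_radiograph(ph2$image, ph2$annotations,
                                           canvas_w = 700, canvas_h = 600))
  expect_true(all(abs(m1$mpi - m2$mpi) < 0.5))
})

test_that("canvas placement centers the image and pads with zero", {
  out <- place_on_canvas(matrix(3, 800, 1000))
  expect_equal(dim(out$pixels), c(1170, 2075))
  expect_equal(out$offset, c((2075 - 1000) %/% 2, (1170 - 800) %/% 2))
  expect_equal(out$pixels[out$offset[2] + 1, out$offset[1] + 1], 3)
  expect_equal(out$pixels[1, 1], 0)
  exact <- place_on_canvas(matrix(1, 1170, 2075))
  expect_equal(exact$offset, c(0, 0))
  expect_error(place_on_canvas(matrix(1, 1171, 10)), "scale-bar")
})

test_that("full normalization pins the liver reference and the scale bar", {
  ph <- generate_phantom(tiny_spec(exposure_gain = 1.2, scale_bar_px = 80),
                         seed = 14)
  n <- norm_small(ph$image, ph$annotations)
  # reference pinning (after resampling, within 0.5 units)
  liv <- find_reference_intensity(n$pixels, n$annotations$liver_region)
  expect_lt(abs(liv - 255), 0.5)
  # scale pinning
  d <- sqrt(sum((n$annotations$scale_bar$p2 - n$annotations$scale_bar$p1)^2))
  expect_lt(abs(d - 50), 0.5)
})

test_that("normalization is idempotent", {
  ph <- generate_phantom(tiny_spec(), seed = 4)
  n1 <- norm_small(ph$image, ph$annotations)
  raw2 <- raw_radiograph(n1$image_id, n1$pixels, bit_depth = 16)
  n2 <- normalize_radiograph(raw2, n1$annotations,
                             canvas_w = 400, canvas_h = 300)
  expect_equal(n2$pixels, n1$pixels, tolerance = 1e-12)
  expect_equal(n2$annotations$scale_bar, n1$annotations$scale_bar)
})

test_that("missing ROIs are reported by name", {
  ph <- generate_phantom(tiny_spec(), seed = 4)
  ann <- ph$annotations
  ann$rois <- ann$rois[-3]  # drop right space 4
  expect_error(normalize_radiograph(ph$image, ann), "right_4")
})

test_that("annotation JSON round-trips", {
  ph <- generate_phantom(tiny_spec(qc_flags = list(left_5 = "liver_overlap")),
                         seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(ph$annotations, path)
  back <- read_annotations(path)
  expect_equal(back$scale_bar, ph$annotations$scale_bar)
  expect_equal(unname(back$liver_region), unname(ph$annotations$liver_region))
  r5 <- Filter(function(r) r$side == "left" && r$space == 5, back$rois)[[1]]
  expect_equal(r5$qc, "liver_overlap")
})
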