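# Synthetic chest-radiograph phantoms with known ground truth.
#
# A phantom emulates the statistical structure the analysis assumes: two
# vertically elongated elliptical lung fields on a darker thoracic
# background, an apico-basal linear MPI gradient per side
# (mean(side, k) = base_side + slope_side * k for intercostal space k),
# per-segment Gaussian speckle whose SD is the FHPI ground truth, a bright
# liver plateau (the global pre-gain maximum, used as the normalization
# reference), a drawn scale bar, and a per-image exposure gain that the
# intensity normalization must cancel.

#' Phantom radiograph specification
#'
#' Defaults place the injected gradients at the apico-basal slopes and
#' intercepts reported for surfactant-treated infants (right lung
#' `-1.99x + 117.79`, left lung `-1.75x + 123.71`) and pin the liver
#' plateau at 255 so that ground truth is expressed directly on the
#' post-normalization intensity scale.
#'
#' @param canvas_w,canvas_h Native image size in pixels.
#' @param base_intensity_right,base_intensity_left Segment mean intensity
#'   at intercostal index 0 (intensity units).
#' @param slope_right,slope_left Intensity units per intercostal index;
#'   negative = basal segments darker (more aerated).
#' @param speckle_sd Per-segment speckle SD (FHPI ground truth): a scalar
#'   recycled to all 12 segments, or a length-12 vector ordered right 2-7
#'   then left 2-7.
#' @param liver_intensity Liver plateau value; must strictly exceed every
#'   expected lung intensity.
#' @param background Thoracic background intensity.
#' @param bit_depth 8 or 16 (default 16).
#' @param scale_bar_mm Physical bar length (default 10 mm).
#' @param scale_bar_px Drawn bar length in pixels before normalization.
#' @param exposure_gain Positive multiplier applied to the whole image.
#' @param lung_geometry Optional list with `right`/`left` ellipse
#'   parameters (cx, cy, rx, ry in native pixels); defaults scale with the
#'   canvas.
#' @param qc_flags Named list of per-ROI QC flags, e.g.
#'   `list(right_7 = "liver_overlap")`.
#' @return Object of class `cxr_phantom_spec`.
#' @export
phantom_spec <- function(canvas_w = 600, canvas_h = 500,
                         base_intensity_right = 117.79,
                         base_intensity_left = 123.71,
                         slope_right = -1.99, slope_left = -1.75,
                         speckle_sd = 8,
                         liver_intensity = 255, background = 40,
                         bit_depth = 16,
                         scale_bar_mm = 10, scale_bar_px = 50,
                         exposure_gain = 1,
                         lung_geometry = NULL, qc_flags = list()) {
  seg_names <- as.vector(outer(SPACES, SIDES,
                               function(k, s) paste0(s, "_", k)))
  if (length(speckle_sd) == 1) speckle_sd <- rep(speckle_sd, 12)
  if (length(speckle_sd) != 12) stop("speckle_sd must have 1 or 12 entries")
  if (is.null(names(speckle_sd))) names(speckle_sd) <- seg_names
  if (is.null(lung_geometry)) {
    lung_geometry <- list(
      right = list(cx = 0.30 * canvas_w, cy = 0.46 * canvas_h,
                   rx = 0.18 * canvas_w, ry = 0.34 * canvas_h),
      left = list(cx = 0.70 * canvas_w, cy = 0.46 * canvas_h,
                  rx = 0.18 * canvas_w, ry = 0.34 * canvas_h))
  }
  spec <- structure(
    list(canvas_w = canvas_w, canvas_h = canvas_h,
         base_intensity_right = base_intensity_right,
         base_intensity_left = base_intensity_left,
         slope_right = slope_right, slope_left = slope_left,
         speckle_sd = speckle_sd,
         liver_intensity = liver_intensity, background = background,
         bit_depth = bit_depth,
         scale_bar_mm = scale_bar_mm, scale_bar_px = scale_bar_px,
         exposure_gain = exposure_gain,
         lung_geometry = lung_geometry, qc_flags = qc_flags),
    class = "cxr_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$exposure_gain <= 0) stop("exposure_gain must be > 0")
  if (any(spec$speckle_sd < 0)) stop("speckle_sd must be non-negative")
  if (length(spec$speckle_sd) != 12) stop("exactly 12 speckle_sd entries required")
  mx <- max(phantom_truth(spec)$segment_mean, spec$background)
  if (spec$liver_intensity <= mx) {
    stop("liver_intensity (", spec$liver_intensity, ") must strictly exceed ",
         "the maximum expected lung intensity (", round(mx, 3), "): the ",
         "normalization reference would otherwise be wrong")
  }
  headroom <- spec$liver_intensity - mx
  if (any(spec$speckle_sd > 0) && headroom < 5 * max(spec$speckle_sd)) {
    warning("liver plateau less than 5 speckle SDs above the brightest ",
            "lung segment; truncation may bias the speckle")
  }
  ceiling_val <- 2^spec$bit_depth - 1
  if (spec$liver_intensity * spec$exposure_gain > ceiling_val) {
    stop("liver_intensity * exposure_gain exceeds the bit-depth ceiling")
  }
  invisible(spec)
}

# Noiseless per-segment truth on the phantom's intensity scale (which is
# the post-normalization scale when target_level = liver_intensity); the
# truth is deliberately independent of exposure_gain.
phantom_truth <- function(spec) {
  side <- rep(SIDES, each = length(SPACES))
  space <- rep(as.integer(SPACES), times = length(SIDES))
  base <- ifelse(side == "right", spec$base_intensity_right,
                 spec$base_intensity_left)
  slope <- ifelse(side == "right", spec$slope_right, spec$slope_left)
  tr <- tibble::tibble(side = side, space = space,
                       segment_mean = base + slope * space,
                       speckle_sd = unname(spec$speckle_sd[paste0(side, "_", space)]))
  attr(tr, "slopes") <- c(right = spec$slope_right, left = spec$slope_left)
  attr(tr, "intercepts") <- c(right = spec$base_intensity_right,
                              left = spec$base_intensity_left)
  attr(tr, "lr_offset") <-
    mean(tr$segment_mean[tr$side == "left"]) -
    mean(tr$segment_mean[tr$side == "right"])
  tr
}

# Horizontal segment bands within an ellipse: six equal-height bands over
# the central 88% of the vertical extent, index 2 (apical) at the top.
segment_bands <- function(geom) {
  r_top <- ceiling(geom$cy - 0.88 * geom$ry)
  r_bot <- floor(geom$cy + 0.88 * geom$ry)
  edges <- r_top + round((r_bot - r_top + 1) * (0:6) / 6)
  lapply(1:6, function(i) c(edges[i], edges[i + 1] - 1L))
}

# Inscribed rectangular ROI for one band, on half-integer bounds so every
# covered pixel center is strictly interior to both rectangle and ellipse.
band_roi_polygon <- function(geom, band) {
  maxdev <- max(abs(band - geom$cy))
  hw <- geom$rx * sqrt(max(0, 1 - ((maxdev + 0.5) / geom$ry)^2)) - 1.5
  if (hw < 2) stop("lung ellipse too small for a segment ROI")
  xlo <- floor(geom$cx - hw) + 0.5
  xhi <- ceiling(geom$cx + hw) - 0.5
  rect_polygon(xlo, band[1] - 0.5, xhi, band[2] + 0.5)
}

#' Generate a synthetic radiograph phantom
#'
#' Renders the phantom image, its annotation set (liver polygon, scale-bar
#' endpoints + physical length, 12 segment ROIs with QC flags) and the
#' ground-truth table. Identical `(spec, seed)` give bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer RNG seed for the speckle.
#' @return Object of class `cxr_phantom`: list with `image` (`cxr_raw`),
#'   `annotations` (`cxr_annotations`), `truth` (tibble with attributes
#'   `slopes`, `intercepts`, `lr_offset`) and `spec`.
#' @export
generate_phantom <- function(spec, seed = 1) {
  validate_phantom_spec(spec)
  w <- spec$canvas_w; h <- spec$canvas_h
  ceiling_val <- 2^spec$bit_depth - 1
  img <- matrix(spec$background, nrow = h, ncol = w)

  rois <- list()
  with_rng(as.integer(seed), {
    for (side in SIDES) {
      geom <- spec$lung_geometry[[side]]
      base <- if (side == "right") spec$base_intensity_right else spec$base_intensity_left
      slope <- if (side == "right") spec$slope_right else spec$slope_left
      bands <- segment_bands(geom)
      # ellipse mask over pixel centers
      xs <- 0:(w - 1); ys <- 0:(h - 1)
      ex <- ((xs - geom$cx) / geom$rx)^2
      ey <- ((ys - geom$cy) / geom$ry)^2
      mask <- outer(ey, ex, `+`) <= 1
      idx <- which(mask, arr.ind = TRUE)
      rowy <- idx[, 1] - 1L
      edges <- vapply(bands, `[`, numeric(1), 1)
      band_i <- pmin(pmax(findInterval(rowy, edges), 1L), 6L)
      k <- band_i + 1L  # intercostal index 2..7
      sds <- spec$speckle_sd[paste0(side, "_", k)]
      vals <- base + slope * k + stats::rnorm(length(k), 0, sds)
      img[idx] <- vals
      for (i in 1:6) {
        key <- paste0(side, "_", i + 1)
        rois[[key]] <- list(side = side, space = i + 1L,
                            polygon = band_roi_polygon(geom, bands[[i]]),
                            qc = as.character(spec$qc_flags[[key]] %||% character(0)))
      }
    }
  })

  # liver plateau: constant block below the right lung, global maximum
  geom_r <- spec$lung_geometry$right
  liv_y0 <- min(h - 8L, ceiling(geom_r$cy + geom_r$ry) + 4L)
  liv_y1 <- h - 8L
  if (liv_y1 - liv_y0 < 3) stop("canvas too small for a liver plateau")
  liv_x0 <- max(2L, floor(0.12 * w)); liv_x1 <- floor(0.48 * w)
  img[(liv_y0:liv_y1) + 1L, (liv_x0:liv_x1) + 1L] <- spec$liver_intensity
  liver_poly <- rect_polygon(liv_x0 + 0.5, liv_y0 + 0.5,
                             liv_x1 - 0.5, liv_y1 - 0.5)

  # scale bar: horizontal line on the bottom row margin
  bar_y <- h - 3L
  bar_x0 <- max(2L, floor(0.02 * w))
  bar_x1 <- bar_x0 + spec$scale_bar_px
  if (bar_x1 > w - 2) stop("scale bar does not fit on the canvas")
  img[bar_y + 1L, (bar_x0:bar_x1) + 1L] <- 0.8 * spec$liver_intensity

  img <- pmin(pmax(img * spec$exposure_gain, 0), ceiling_val)

  ordered <- as.vector(outer(SPACES, SIDES, function(k, s) paste0(s, "_", k)))
  ann <- annotation_set(
    image_id = sprintf("phantom_seed%d", as.integer(seed)),
    liver_region = liver_poly,
    scale_bar = list(p1 = c(bar_x0, bar_y), p2 = c(bar_x1, bar_y),
                     mm = spec$scale_bar_mm),
    rois = unname(rois[ordered]))
  check_roi_overlap(ann$rois)

  raw <- raw_radiograph(ann$image_id, img, bit_depth = spec$bit_depth,
                        meta = list(exposure_gain = spec$exposure_gain,
                                    generator = "cxraeration phantom",
                                    seed = as.integer(seed)))
  structure(list(image = raw, annotations = ann,
                 truth = phantom_truth(spec), spec = spec),
            class = "cxr_phantom")
}

check_roi_overlap <- function(rois) {
  bb <- t(vapply(rois, function(r) {
    p <- as_polygon(r$polygon)
    c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2]))
  }, numeric(4)))
  n <- nrow(bb)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (bb[i, 1] < bb[j, 2] && bb[j, 1] < bb[i, 2] &&
        bb[i, 3] < bb[j, 4] && bb[j, 3] < bb[i, 4]) {
      stop("overlapping ROI polygons: ", i, " and ", j)
    }
  }
  invisible(rois)
}
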