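# Two-step radiograph normalization: (1) scale all pixel intensities so the
# brightest liver pixel maps to a common reference level; (2) rescale the
# image so the annotated scale bar spans 5 px/mm, then place it on the
# canonical canvas.

CANONICAL_CANVAS <- c(width = 2075, height = 1170)
PX_PER_MM <- 5.0

#' Construct a raw radiograph object
#'
#' @param image_id Character identifier.
#' @param pixels Numeric matrix of non-negative intensities (rows = y,
#'   columns = x).
#' @param bit_depth 8 or 16; intensities must lie in `[0, 2^bit_depth - 1]`.
#' @param meta Optional list of acquisition metadata.
#' @return Object of class `cxr_raw`.
#' @export
raw_radiograph <- function(image_id, pixels, bit_depth = 16, meta = list()) {
  pixels <- as.matrix(pixels)
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16")
  if (nrow(pixels) < 64 || ncol(pixels) < 64) {
    stop("radiograph must be at least 64x64 pixels")
  }
  ceiling_val <- 2^bit_depth - 1
  if (min(pixels) < 0 || max(pixels) > ceiling_val) {
    stop("intensities must lie in [0, 2^bit_depth - 1]")
  }
  structure(list(image_id = as.character(image_id), pixels = pixels,
                 bit_depth = bit_depth, meta = meta),
            class = "cxr_raw")
}

#' @export
print.cxr_raw <- function(x, ...) {
  cat(sprintf("<cxr_raw> %s: %d x %d px, %d-bit, range [%.1f, %.1f]\n",
              x$image_id, ncol(x$pixels), nrow(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Liver reference intensity
#'
#' Returns the maximum pixel intensity inside the rasterized liver region;
#' this per-image reference anchors the intensity normalization.
#'
#' @param image A `cxr_raw`/`cxr_normalized` object or a plain matrix.
#' @param liver_region Polygon over the liver (columns x, y).
#' @return Scalar intensity.
#' @export
find_reference_intensity <- function(image, liver_region) {
  pixels <- if (is.matrix(image)) image else image$pixels
  idx <- polygon_pixels(liver_region, dim(pixels))
  if (nrow(idx) == 0) stop("liver region rasterizes to no pixels")
  ref <- max(pixels[idx + 1L])
  if (ref <= 0) stop("liver reference intensity is zero; cannot normalize")
  ref
}

#' Intensity normalization against a reference level
#'
#' Every pixel `p` maps to `p * target_level / reference`; the output is a
#' floating-point matrix, deliberately not clipped or re-quantized (lung
#' pixels brighter than the liver reference keep values above the target).
#'
#' @param image `cxr_raw` object or matrix.
#' @param reference Positive reference intensity (liver maximum).
#' @param target_level Positive common level the reference maps to.
#' @return Numeric matrix.
#' @export
normalize_intensity <- function(image, reference, target_level = 255) {
  pixels <- if (is.matrix(image)) image else image$pixels
  if (!is.numeric(reference) || reference <= 0) stop("reference must be > 0")
  if (target_level <= 0) stop("target_level must be > 0")
  pixels * (target_level / reference)
}

#' Spatial size factor from the scale-bar annotation
#'
#' `factor = physical_length_mm * 5 / endpoint_distance_px`, so a 10 mm bar
#' spans 50 px after rescaling.
#'
#' @param scale_bar List with `p1`, `p2` (xy endpoints) and `mm`.
#' @return Positive scalar scale factor.
#' @export
compute_size_factor <- function(scale_bar) {
  d <- sqrt(sum((scale_bar$p2 - scale_bar$p1)^2))
  if (d <= 0) stop("scale bar endpoints coincide")
  if (scale_bar$mm <= 0) stop("scale bar physical length must be > 0")
  scale_bar$mm * PX_PER_MM / d
}

#' Bilinear image resampling
#'
#' Output dimensions are `round(dim * factor)`; a coordinate x in the input
#' maps to `x * factor` in the output (pixel centers at integer positions).
#'
#' @param image Numeric matrix.
#' @param factor Scale factor in (0.05, 20).
#' @return Resampled numeric matrix.
#' @export
resample_image <- function(image, factor) {
  if (factor <= 0.05 || factor >= 20) stop("scale factor out of range (0.05, 20)")
  h <- nrow(image); w <- ncol(image)
  nh <- round(h * factor); nw <- round(w * factor)
  if (nh < 8 || nw < 8) stop("resampled image smaller than 8x8")
  if (factor == 1) return(image)
  ys <- pmin(pmax((0:(nh - 1)) / factor, 0), h - 1)
  xs <- pmin(pmax((0:(nw - 1)) / factor, 0), w - 1)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  a <- image[y0 + 1, x0 + 1, drop = FALSE]
  b <- image[y1 + 1, x0 + 1, drop = FALSE]
  cc <- image[y0 + 1, x1 + 1, drop = FALSE]
  d <- image[y1 + 1, x1 + 1, drop = FALSE]
  wy1 <- 1 - fy
  a * (wy1 %o% (1 - fx)) + b * (fy %o% (1 - fx)) +
    cc * (wy1 %o% fx) + d * (fy %o% fx)
}

#' Center an image on the canonical canvas
#'
#' @param image Numeric matrix no larger than the canvas.
#' @param canvas_w,canvas_h Canvas dimensions in pixels (default the
#'   canonical 2075 x 1170 frame).
#' @return List with `pixels` (the padded canvas, padding value 0) and
#'   `offset` (xy shift applied to coordinates).
#' @export
place_on_canvas <- function(image, canvas_w = CANONICAL_CANVAS[["width"]],
                            canvas_h = CANONICAL_CANVAS[["height"]]) {
  h <- nrow(image); w <- ncol(image)
  if (w > canvas_w || h > canvas_h) {
    stop("image (", w, "x", h, ") larger than canvas (", canvas_w, "x",
         canvas_h, "); check the scale-bar annotation")
  }
  ox <- (canvas_w - w) %/% 2
  oy <- (canvas_h - h) %/% 2
  canvas <- matrix(0, nrow = canvas_h, ncol = canvas_w)
  canvas[oy + seq_len(h), ox + seq_len(w)] <- image
  list(pixels = canvas, offset = c(ox, oy))
}

#' Full radiograph normalization
#'
#' Applies intensity normalization (liver reference pinned to
#' `target_level`), then spatial rescaling to 5 px/mm via the scale bar,
#' then centered placement on the canonical canvas. All annotations are
#' carried through in canonical coordinates.
#'
#' @param raw A `cxr_raw` object.
#' @param annotations Matching `cxr_annotations`.
#' @param target_level Common liver reference level (default 255).
#' @param canvas_w,canvas_h Canvas dimensions (default canonical).
#' @return Object of class `cxr_normalized` with fields `pixels`,
#'   `px_per_mm`, `reference_level`, `size_factor`, `annotations`.
#' @export
normalize_radiograph <- function(raw, annotations, target_level = 255,
                                 canvas_w = CANONICAL_CANVAS[["width"]],
                                 canvas_h = CANONICAL_CANVAS[["height"]]) {
  stopifnot(inherits(annotations, "cxr_annotations"))
  validate_annotations(annotations, dim(raw$pixels))
  ref <- find_reference_intensity(raw, annotations$liver_region)
  pixels <- normalize_intensity(raw, ref, target_level)
  f <- compute_size_factor(annotations$scale_bar)
  pixels <- resample_image(pixels, f)
  placed <- place_on_canvas(pixels, canvas_w, canvas_h)
  ann <- transform_annotations(annotations, scale = f, offset = placed$offset)
  structure(list(image_id = raw$image_id,
                 pixels = placed$pixels,
                 px_per_mm = PX_PER_MM,
                 reference_level = target_level,
                 measured_reference = ref,
                 size_factor = f,
                 interpolation = "bilinear",
                 annotations = ann),
            class = "cxr_normalized")
}

#' @export
print.cxr_normalized <- function(x, ...) {
  cat(sprintf(paste0("<cxr_normalized> %s: %d x %d canvas, liver ref -> %.6g",
                     " (measured %.6g), size factor %.4f\n"),
              x$image_id, ncol(x$pixels), nrow(x$pixels), x$reference_level,
              x$measured_reference, x$size_factor))
  invisible(x)
}

#' Read a grayscale radiograph image (PNG or TIFF)
#'
#' Values are mapped back from the file's [0, 1] range to
#' `[0, 2^bit_depth - 1]`.
#'
#' @param path Image file (.png/.tif/.tiff).
#' @param image_id Identifier; defaults to the file name without extension.
#' @param bit_depth Intensity scale of the stored image (default 16).
#' @return A `cxr_raw` object.
#' @export
read_radiograph <- function(path, image_id = NULL, bit_depth = 16) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  raw_radiograph(image_id %||% tools::file_path_sans_ext(basename(path)),
                 img * (2^bit_depth - 1), bit_depth = bit_depth,
                 meta = list(source = path))
}

#' Write a radiograph as 16-bit grayscale TIFF
#'
#' @param raw A `cxr_raw` object.
#' @param path Output path (.tif).
#' @export
write_radiograph <- function(raw, path) {
  scale <- 2^raw$bit_depth - 1
  tiff::writeTIFF(pmin(pmax(raw$pixels / scale, 0), 1), path,
                  bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Write a normalized radiograph as 32-bit float TIFF
#'
#' Pixel values are stored divided by 65535 (recorded in the provenance
#' output of the pipeline); [read_normalized()] restores the scale.
#'
#' @param norm A `cxr_normalized` object.
#' @param path Output path (.tif).
#' @export
write_normalized <- function(norm, path) {
  tiff::writeTIFF(pmax(norm$pixels, 0) / 65535, path,
                  bits.per.sample = 32, compression = "none")
  invisible(path)
}

#' Read a normalized radiograph written by [write_normalized()]
#'
#' @param path Float TIFF path.
#' @param annotations The matching transformed `cxr_annotations`.
#' @param reference_level,size_factor Provenance values to attach.
#' @return A `cxr_normalized` object.
#' @export
read_normalized <- function(path, annotations, reference_level = 255,
                            size_factor = NA_real_) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  structure(list(image_id = annotations$image_id,
                 pixels = img * 65535,
                 px_per_mm = PX_PER_MM,
                 reference_level = reference_level,
                 measured_reference = NA_real_,
                 size_factor = size_factor,
                 interpolation = "bilinear",
                 annotations = annotations),
            class = "cxr_normalized")
}
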