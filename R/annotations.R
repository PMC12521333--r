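# Per-image annotation sets: liver reference polygon, scale bar, and the
# twelve intercostal-segment ROIs (sides left/right x spaces 2-7).

SIDES <- c("right", "left")
SPACES <- 2:7

#' Construct a per-image annotation set
#'
#' @param image_id Character image identifier.
#' @param liver_region Polygon (matrix, columns x/y) over the liver.
#' @param scale_bar List with elements `p1`, `p2` (numeric xy endpoints) and
#'   `mm` (physical bar length in millimetres).
#' @param rois List of 12 ROI entries, each a list with `side`
#'   ("left"/"right"), `space` (integer 2-7), `polygon` and a character
#'   vector `qc` of quality-control flags (may contain `"liver_overlap"`).
#' @return An object of class `cxr_annotations`.
#' @export
annotation_set <- function(image_id, liver_region, scale_bar, rois) {
  ann <- structure(
    list(image_id = as.character(image_id),
         liver_region = as_polygon(liver_region),
         scale_bar = list(p1 = as.numeric(scale_bar$p1),
                          p2 = as.numeric(scale_bar$p2),
                          mm = as.numeric(scale_bar$mm)),
         rois = rois),
    class = "cxr_annotations")
  validate_annotations(ann)
  ann
}

validate_annotations <- function(ann, image_dim = NULL) {
  if (ann$scale_bar$mm <= 0) stop("scale bar physical length must be > 0")
  if (length(ann$scale_bar$p1) != 2 || length(ann$scale_bar$p2) != 2) {
    stop("scale bar endpoints must be xy pairs")
  }
  keys <- vapply(ann$rois, function(r) paste0(r$side, "_", r$space), "")
  wanted <- as.vector(outer(SIDES, SPACES, paste, sep = "_"))
  missing <- setdiff(wanted, keys)
  if (length(missing) > 0) {
    stop("missing ROI(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(keys)) {
    stop("duplicate ROI(s): ", paste(keys[duplicated(keys)], collapse = ", "))
  }
  if (!is.null(image_dim)) {
    check_inside <- function(p, what) {
      if (any(p[, 1] < -0.5 | p[, 1] > image_dim[2] - 0.5 |
              p[, 2] < -0.5 | p[, 2] > image_dim[1] - 0.5)) {
        stop(what, " polygon extends outside image bounds")
      }
    }
    check_inside(ann$liver_region, "liver")
    for (r in ann$rois) check_inside(as_polygon(r$polygon), paste(r$side, r$space))
  }
  invisible(ann)
}

# Look up one ROI entry by side/space, or NULL.
get_roi <- function(ann, side, space) {
  for (r in ann$rois) if (r$side == side && r$space == space) return(r)
  NULL
}

# Apply x' = x * scale + offset to every coordinate in the annotation set.
transform_annotations <- function(ann, scale = 1, offset = c(0, 0)) {
  tp <- function(p) {
    p <- as_polygon(p)
    cbind(x = p[, 1] * scale + offset[1], y = p[, 2] * scale + offset[2])
  }
  ann$liver_region <- tp(ann$liver_region)
  ann$scale_bar$p1 <- ann$scale_bar$p1 * scale + offset
  ann$scale_bar$p2 <- ann$scale_bar$p2 * scale + offset
  ann$rois <- lapply(ann$rois, function(r) {
    r$polygon <- tp(r$polygon)
    r
  })
  ann
}

#' Write annotations to JSON
#'
#' Schema: `{image_id, liver_region:[[x,y],...], scale_bar:{p1,p2,mm},
#' rois:[{side, space, polygon:[[x,y],...], qc:[...]}]}`.
#'
#' @param ann A `cxr_annotations` object.
#' @param path Output file path.
#' @export
write_annotations <- function(ann, path) {
  obj <- list(
    image_id = ann$image_id,
    liver_region = unname(as_polygon(ann$liver_region)),
    scale_bar = list(p1 = ann$scale_bar$p1, p2 = ann$scale_bar$p2,
                     mm = ann$scale_bar$mm),
    rois = lapply(ann$rois, function(r) {
      list(side = r$side, space = r$space,
           polygon = unname(as_polygon(r$polygon)),
           qc = as.list(r$qc %||% character(0)))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read annotations from JSON
#'
#' @param path JSON file written by [write_annotations()] (or conforming to
#'   the same schema).
#' @return A `cxr_annotations` object.
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  rois <- lapply(seq_len(nrow(obj$rois)), function(i) {
    list(side = obj$rois$side[i],
         space = as.integer(obj$rois$space[i]),
         polygon = as_polygon(obj$rois$polygon[[i]]),
         qc = as.character(unlist(obj$rois$qc[[i]])))
  })
  annotation_set(obj$image_id, obj$liver_region,
                 list(p1 = obj$scale_bar$p1, p2 = obj$scale_bar$p2,
                      mm = obj$scale_bar$mm),
                 rois)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
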