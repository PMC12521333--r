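# Small phantom geometries used to keep simulation-heavy tests fast; the
# injected intensity structure is unchanged from the defaults.

tiny_spec <- function(...) {
  phantom_spec(canvas_w = 300, canvas_h = 260, ...)
}

# Normalization onto a reduced canvas (placement does not affect MPI/FHPI).
norm_small <- function(raw, ann, ...) {
  normalize_radiograph(raw, ann, canvas_w = 400, canvas_h = 300, ...)
}

measure_phantom <- function(ph, ...) {
  measure_image(norm_small(ph$image, ph$annotations, ...))
}
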