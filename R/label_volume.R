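#' Label volume container
#'
#' A `label_volume` wraps a 3D array of non-negative integer region labels
#' together with voxel spacing metadata. Label 0 is reserved for background.
#' All morphometric features computed from a label volume are voxel-count
#' based and therefore independent of the affine/spacing metadata, which is
#' carried along for provenance only.
#'
#' @param voxels 3D integer array of region labels (>= 0).
#' @param spacing numeric length-3 voxel spacing (dx, dy, dz) in mm.
#' @return An object of class `label_volume` with elements `voxels`,
#'   `spacing` and `region_ids` (sorted distinct nonzero labels present).
#' @examples
#' v <- label_volume(array(c(0L, 1L, 1L, 2L, 0L, 0L, 2L, 2L), c(2, 2, 2)))
#' v$region_ids
#' @export
label_volume <- function(voxels, spacing = c(1, 1, 1)) {
  if (length(dim(voxels)) != 3L) {
    stopf("label volume must have exactly 3 dimensions, got %d",
          length(dim(voxels)))
  }
  if (any(dim(voxels) < 1L)) stopf("all dimensions must be >= 1")
  if (is.double(voxels)) {
    r <- round(voxels)
    if (max(abs(voxels - r)) > 1e-6) {
      stopf("non-integer labels in volume (tolerance 1e-6)")
    }
    voxels <- array(as.integer(r), dim(voxels))
  }
  if (!is.integer(voxels)) {
    storage.mode(voxels) <- "integer"
  }
  if (anyNA(voxels) || any(voxels < 0L)) {
    stopf("labels must be non-negative integers without NA")
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("spacing must be 3 positive finite values")
  }
  ids <- sort(unique(as.vector(voxels)))
  structure(
    list(voxels = voxels,
         spacing = as.numeric(spacing),
         region_ids = ids[ids > 0L]),
    class = "label_volume")
}

#' @exportS3Method base::print
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<label_volume> %dx%dx%d voxels, spacing %.3gx%.3gx%.3g mm, %d regions\n",
              d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              length(x$region_ids)))
  invisible(x)
}

is_label_volume <- function(x) inherits(x, "label_volume")

assert_label_volume <- function(x) {
  if (!is_label_volume(x)) stopf("expected a 'label_volume' object")
  invisible(x)
}
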