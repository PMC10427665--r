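# Minimal NIfTI-1 I/O for integer label volumes.
#
# Only the subset of NIfTI-1 needed for label maps is implemented: single-file
# .nii / .nii.gz, scalar datatypes, no extensions on write. Any affine is
# accepted on read; features downstream are voxel-count based and therefore
# affine-invariant, so only pixdim (spacing) is retained.

NIFTI_HDR_SIZE <- 348L

nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

open_nifti_con <- function(path, mode) {
  # gzfile reads plain files transparently and writes gzip when the
  # path ends in .gz; use it for reading, pick writer by extension.
  if (mode == "rb") return(gzfile(path, "rb"))
  if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
}

#' Read a 3D integer label volume from a NIfTI-1 file
#'
#' Reads single-file NIfTI-1 (`.nii` or `.nii.gz`). A 4D volume whose trailing
#' dimensions are singletons is squeezed to 3D. Voxel values must be integers
#' (within 1e-6 after any scl_slope/scl_inter scaling); spacing is taken from
#' `pixdim`.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [label_volume].
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- open_nifti_con(path, "rb")
  on.exit(close(con), add = TRUE)

  hdr_raw <- readBin(con, "raw", NIFTI_HDR_SIZE)
  if (length(hdr_raw) < NIFTI_HDR_SIZE) stopf("truncated NIfTI header: %s", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1, 4, endian = endian)
  if (sizeof_hdr != NIFTI_HDR_SIZE) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1, 4, endian = endian)
    if (sizeof_hdr != NIFTI_HDR_SIZE) stopf("not a NIfTI-1 file: %s", path)
  }
  rd <- function(off, what, n, size) {
    readBin(hdr_raw[(off + 1):(off + n * size)], what, n, size,
            signed = TRUE, endian = endian)
  }
  dim_field <- rd(40L, "integer", 8L, 2L)
  datatype  <- rd(70L, "integer", 1L, 2L)
  pixdim    <- rd(76L, "double", 8L, 4L)
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope  <- rd(112L, "double", 1L, 4L)
  scl_inter  <- rd(116L, "double", 1L, 4L)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stopf("bad NIfTI magic in %s", path)

  ndim <- dim_field[1]
  if (ndim < 3L || ndim > 7L) stopf("unsupported dimensionality %d", ndim)
  dims <- dim_field[2:(1 + ndim)]
  dims[dims == 0L] <- 1L
  if (any(dims[-(1:3)] != 1L)) {
    stopf("volume in %s is not 3D (dims beyond the third are not singletons)", path)
  }
  dims <- dims[1:3]

  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stopf("unsupported NIfTI datatype code %d", datatype)

  # Skip extension bytes between header end and data start.
  skip <- as.integer(round(vox_offset)) - NIFTI_HDR_SIZE
  if (skip > 0L) readBin(con, "raw", skip)
  n_vox <- prod(dims)
  vals <- readBin(con, dt$what, n_vox, dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n_vox) stopf("truncated NIfTI data in %s", path)
  if (is.finite(scl_slope) && scl_slope != 0 && scl_slope != 1) {
    vals <- vals * scl_slope + scl_inter
  } else if (is.finite(scl_inter) && scl_inter != 0 && scl_slope != 0) {
    vals <- vals + scl_inter
  }
  r <- round(vals)
  if (max(abs(vals - r)) > 1e-6) stopf("non-integer labels in %s", path)

  spacing <- abs(pixdim[2:4])
  spacing[!is.finite(spacing) | spacing <= 0] <- 1
  label_volume(array(as.integer(r), dims), spacing = spacing)
}

#' Write a label volume as NIfTI-1
#'
#' Writes int32 data with an axis-aligned sform built from the spacing. The
#' output round-trips bit-identically through [read_label_volume()].
#'
#' @param vol a [label_volume].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  assert_label_volume(vol)
  dims <- dim(vol$voxels)
  sp <- vol$spacing
  con <- open_nifti_con(path, "wb")
  on.exit(close(con), add = TRUE)

  w_i32 <- function(x) writeBin(as.integer(x), con, 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                      # sizeof_hdr
  w_raw(10L); w_raw(18L)           # data_type, db_name (unused)
  w_i32(0L); w_i16(0L); w_raw(2L)  # extents, session_error, regular+dim_info
  w_i16(c(3L, dims, 1L, 1L, 1L, 1L))          # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)                # intent_p1..3, intent_code
  w_i16(8L); w_i16(32L); w_i16(0L)            # datatype int32, bitpix, slice_start
  w_f32(c(1, sp, 0, 0, 0, 0))                 # pixdim[8]
  w_f32(352); w_f32(1); w_f32(0)              # vox_offset, scl_slope, scl_inter
  w_i16(0L); w_raw(2L)                        # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                        # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                            # glmax, glmin
  w_raw(80L); w_raw(24L)                      # descrip, aux_file
  w_i16(0L); w_i16(1L)                        # qform_code, sform_code
  w_f32(c(0, 0, 0, 0, 0, 0))                  # quatern b,c,d + qoffset x,y,z
  w_f32(c(sp[1], 0, 0, 0))                    # srow_x
  w_f32(c(0, sp[2], 0, 0))                    # srow_y
  w_f32(c(0, 0, sp[3], 0))                    # srow_z
  w_raw(16L)                                  # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  w_raw(4L)                                   # extension flag: none
  writeBin(as.vector(vol$voxels), con, 4L, endian = "little")
  invisible(path)
}
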