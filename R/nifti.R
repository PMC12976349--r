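# Minimal NIfTI-1 codec for 2D rasters (float32 maps, uint8 label rasters).
# No NIfTI package exists in the supported dependency set, so the 348-byte
# single-file (.nii / .nii.gz) format is read and written directly with
# binary connections. Only what the pipeline needs is supported: 2D (or
# singleton-third-dimension) images, little- or big-endian, datatypes
# uint8 / int16 / int32 / float32 / float64, pixdim spacing, scl scaling.

nifti_datatypes <- list(
  "2" = list(what = "integer", size = 1L, signed = FALSE),
  "4" = list(what = "integer", size = 2L, signed = TRUE),
  "8" = list(what = "integer", size = 4L, signed = TRUE),
  "16" = list(what = "double", size = 4L, signed = TRUE),
  "64" = list(what = "double", size = 8L, signed = TRUE)
)

#' Read a 2D NIfTI-1 image
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list(values = numeric matrix, spacing_mm = c(row, col) voxel
#'   sizes).
#' @export
read_nifti_2d <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sz <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (length(sz) == 0) stop("format error: empty file: ", path)
  if (sz != 348L) {
    if (sz == 1543503872L) endian <- "big"  # 348 byte-swapped (0x5C010000)
    else stop("format error: not a NIfTI-1 file: ", path)
  }
  rd_i16 <- function(n) readBin(con, "integer", n, size = 2, endian = endian)
  rd_i32 <- function(n) readBin(con, "integer", n, size = 4, endian = endian)
  rd_f32 <- function(n) readBin(con, "double", n, size = 4, endian = endian)
  rd_raw <- function(n) readBin(con, "raw", n)
  rd_raw(36)                      # data_type..dim_info
  dim_field <- rd_i16(8)
  if (endian == "big" && (dim_field[1] < 0 || dim_field[1] > 7))
    stop("format error: unrecognized NIfTI header in ", path)
  rd_f32(3); rd_i16(1)            # intent_p*, intent_code
  datatype <- rd_i16(1)
  rd_i16(2)                       # bitpix, slice_start
  pixdim <- rd_f32(8)
  vox_offset <- rd_f32(1)
  scl_slope <- rd_f32(1)
  scl_inter <- rd_f32(1)
  rd_i16(1); rd_raw(2)            # slice_end, slice_code, xyzt_units
  rd_f32(4); rd_i32(2)            # cal/slice_duration/toffset, glmax/glmin
  rd_raw(80 + 24)                 # descrip, aux_file
  rd_i16(2); rd_f32(6); rd_f32(12)  # qform/sform, quaternion, srows
  rd_raw(16)
  magic <- rawToChar(rd_raw(4))
  if (!startsWith(magic, "n+1") && !startsWith(magic, "ni1"))
    stop("format error: missing NIfTI magic in ", path)
  nd <- dim_field[1]
  dims <- dim_field[2:8][seq_len(max(nd, 1))]
  if (nd < 2 || any(dims[-(1:2)] > 1))
    stop("format error: expected a 2D image (or singleton extra ",
         "dimensions), got dim = ", paste(dims, collapse = "x"))
  nr <- dims[1]; nc <- dims[2]
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("format error: unsupported NIfTI datatype ", datatype)
  skip <- vox_offset - 348
  if (skip > 0) rd_raw(skip)
  vals <- readBin(con, dt$what, n = nr * nc, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < nr * nc)
    stop("format error: truncated image data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  spacing <- pixdim[2:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("format error: missing voxel spacing in ", path)
  list(values = matrix(as.numeric(vals), nr, nc), spacing_mm = spacing)
}

#' Write a 2D NIfTI-1 image
#'
#' @param values numeric matrix.
#' @param path output `.nii` or `.nii.gz` path.
#' @param spacing_mm isotropic voxel edge length (mm).
#' @param datatype `"float32"` (maps) or `"uint8"` (label rasters).
#' @return `path`, invisibly.
#' @export
write_nifti_2d <- function(values, path, spacing_mm,
                           datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  stopifnot(is.matrix(values))
  code <- if (datatype == "float32") 16L else 2L
  bitpix <- if (datatype == "float32") 32L else 8L
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2,
                                endian = "little")
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4,
                                endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4,
                                endian = "little")
  w_raw0 <- function(n) writeBin(raw(n), con)
  w_i32(348L)
  w_raw0(36)
  w_i16(c(2L, nrow(values), ncol(values), 1L, 1L, 1L, 1L, 1L))
  w_f32(c(0, 0, 0)); w_i16(0L)
  w_i16(code); w_i16(bitpix); w_i16(0L)
  w_f32(c(1, spacing_mm, spacing_mm, 1, 1, 1, 1, 1))
  w_f32(352)                       # vox_offset
  w_f32(1); w_f32(0)               # scl_slope, scl_inter
  w_i16(0L); w_raw0(2)
  w_f32(c(0, 0, 0, 0)); w_i32(c(0L, 0L))
  w_raw0(80 + 24)
  w_i16(c(0L, 0L)); w_f32(rep(0, 6))
  w_f32(c(spacing_mm, 0, 0, 0, 0, spacing_mm, 0, 0, 0, 0, 1, 0))
  w_raw0(16)
  writeBin(c(charToRaw("n+1"), raw(1)), con)
  w_raw0(4)                        # extension flag
  if (datatype == "float32") {
    w_f32(as.vector(values))
  } else {
    v <- as.integer(round(as.vector(values)))
    if (any(v < 0 | v > 255)) stop("uint8 overflow in label raster")
    writeBin(as.raw(v), con)
  }
  invisible(path)
}
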