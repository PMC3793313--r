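# Minimal single-file NIfTI-1 input/output.
#
# The package needs to read 4-D EPI series and 3-D masks and to write binary
# selection masks whose headers are copied from a reference volume. Only the
# single-file ".nii" layout (magic "n+1", vox_offset >= 352) is supported,
# optionally gzip-compressed; both byte orders are handled on read, native
# order is written. Data types: uint8, int16, int32, float32, float64.
# scl_slope / scl_inter are applied on read when scl_slope is nonzero.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

read_nifti_header <- function(con, endian) {
  rb <- function(what, n, size, signed = TRUE) {
    readBin(con, what = what, n = n, size = size, signed = signed,
            endian = endian)
  }
  rchar <- function(n) readBin(con, "raw", n = n)
  h <- list()
  h$sizeof_hdr <- rb("integer", 1L, 4L)
  h$pad1 <- rchar(36L)            # data_type, db_name, extents, session_error, regular, dim_info
  h$dim <- rb("integer", 8L, 2L)
  h$intent_p <- rb("double", 3L, 4L)
  h$intent_code <- rb("integer", 1L, 2L)
  h$datatype <- rb("integer", 1L, 2L)
  h$bitpix <- rb("integer", 1L, 2L)
  h$slice_start <- rb("integer", 1L, 2L)
  h$pixdim <- rb("double", 8L, 4L)
  h$vox_offset <- rb("double", 1L, 4L)
  h$scl_slope <- rb("double", 1L, 4L)
  h$scl_inter <- rb("double", 1L, 4L)
  h$slice_end <- rb("integer", 1L, 2L)
  h$pad2 <- rchar(2L)             # slice_code, xyzt_units
  h$cal <- rb("double", 4L, 4L)   # cal_max, cal_min, slice_duration, toffset
  h$gl <- rb("integer", 2L, 4L)   # glmax, glmin
  h$descrip <- rchar(80L)
  h$aux_file <- rchar(24L)
  h$qform_code <- rb("integer", 1L, 2L)
  h$sform_code <- rb("integer", 1L, 2L)
  h$quatern <- rb("double", 6L, 4L)
  h$srow <- rb("double", 12L, 4L)
  h$intent_name <- rchar(16L)
  h$magic <- rchar(4L)
  h$endian <- endian
  h
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into an array.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a numeric array with `dim` attribute of length 3 or 4 and an
#'   attribute `nifti_header` holding the parsed header (used to copy
#'   geometry when writing derived masks).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_value("no such file: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- read_nifti_header(con, "little")
  if (hdr$sizeof_hdr != 348L) {
    close(con)
    on.exit()
    con <- nifti_connection(path, "rb")
    on.exit(close(con), add = TRUE)
    hdr <- read_nifti_header(con, "big")
    if (hdr$sizeof_hdr != 348L) {
      stop_value(path, " is not a NIfTI-1 file (bad sizeof_hdr)")
    }
  }
  magic <- rawToChar(hdr$magic[1:3])
  if (magic != "n+1") {
    stop_value("only single-file NIfTI-1 ('n+1') is supported, got magic '",
               magic, "'")
  }
  spec <- NIFTI_DTYPES[[as.character(hdr$datatype)]]
  if (is.null(spec)) {
    stop_value("unsupported NIfTI datatype code ", hdr$datatype)
  }
  ndim <- hdr$dim[1L]
  if (ndim < 3L || ndim > 4L) {
    stop_value("expected a 3-D or 4-D volume, got dim[0] = ", ndim)
  }
  shape <- pmax(hdr$dim[2L:(1L + ndim)], 1L)
  nvox <- prod(shape)
  # skip from byte 348 to vox_offset (extension bytes)
  skip <- as.integer(round(hdr$vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  dat <- readBin(con, what = spec$what, n = nvox, size = spec$size,
                 signed = spec$signed, endian = hdr$endian)
  if (length(dat) != nvox) stop_value("truncated NIfTI data in ", path)
  dat <- as.double(dat)
  if (is.finite(hdr$scl_slope) && hdr$scl_slope != 0 &&
      !(hdr$scl_slope == 1 && hdr$scl_inter == 0)) {
    dat <- dat * hdr$scl_slope + hdr$scl_inter
  }
  arr <- array(dat, dim = shape)
  attr(arr, "nifti_header") <- hdr
  arr
}

default_nifti_header <- function(shape, pixdim = rep(1, length(shape))) {
  dim8 <- integer(8L)
  dim8[1L] <- length(shape)
  dim8[1L + seq_along(shape)] <- as.integer(shape)
  dim8[dim8 == 0L] <- 1L
  pd8 <- numeric(8L)
  pd8[1L] <- 1
  pd8[1L + seq_along(pixdim)] <- pixdim
  list(
    sizeof_hdr = 348L, pad1 = raw(36L), dim = dim8,
    intent_p = numeric(3L), intent_code = 0L,
    datatype = 64L, bitpix = 64L, slice_start = 0L,
    pixdim = pd8, vox_offset = 352, scl_slope = 1, scl_inter = 0,
    slice_end = 0L, pad2 = raw(2L), cal = numeric(4L), gl = integer(2L),
    descrip = raw(80L), aux_file = raw(24L),
    qform_code = 0L, sform_code = 0L, quatern = numeric(6L),
    srow = numeric(12L), intent_name = raw(16L),
    magic = as.raw(c(0x6e, 0x2b, 0x31, 0x00)), endian = "little"
  )
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3-D or 4-D numeric array as a single-file NIfTI-1 image. When the
#' array carries a `nifti_header` attribute (as produced by [read_nifti()]),
#' its geometry fields (pixdim, q/s-form) are preserved.
#'
#' @param x numeric array of 3 or 4 dimensions.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param datatype NIfTI datatype code: 2 (uint8), 4 (int16), 8 (int32),
#'   16 (float32) or 64 (float64).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, datatype = 16L) {
  if (!is.array(x) || !(length(dim(x)) %in% c(3L, 4L))) {
    stop_value("x must be a 3-D or 4-D array")
  }
  spec <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(spec)) stop_value("unsupported datatype code ", datatype)
  hdr <- attr(x, "nifti_header")
  if (is.null(hdr)) hdr <- default_nifti_header(dim(x))
  dim8 <- integer(8L)
  dim8[1L] <- length(dim(x))
  dim8[1L + seq_along(dim(x))] <- as.integer(dim(x))
  dim8[dim8 == 0L] <- 1L
  hdr$dim <- dim8
  hdr$datatype <- as.integer(datatype)
  hdr$bitpix <- spec$bitpix
  hdr$vox_offset <- 352
  hdr$scl_slope <- 1
  hdr$scl_inter <- 0
  con <- nifti_connection(path, "wb")
  on.exit(close(con), add = TRUE)
  wb <- function(v, size, what = "integer") {
    writeBin(as.vector(v, mode = if (what == "double") "double" else "integer"),
             con, size = size, endian = "little")
  }
  wb(hdr$sizeof_hdr, 4L)
  writeBin(hdr$pad1, con)
  wb(hdr$dim, 2L)
  wb(hdr$intent_p, 4L, "double")
  wb(hdr$intent_code, 2L)
  wb(hdr$datatype, 2L)
  wb(hdr$bitpix, 2L)
  wb(hdr$slice_start, 2L)
  wb(hdr$pixdim, 4L, "double")
  wb(hdr$vox_offset, 4L, "double")
  wb(hdr$scl_slope, 4L, "double")
  wb(hdr$scl_inter, 4L, "double")
  wb(hdr$slice_end, 2L)
  writeBin(hdr$pad2, con)
  wb(hdr$cal, 4L, "double")
  wb(hdr$gl, 4L)
  writeBin(hdr$descrip, con)
  writeBin(hdr$aux_file, con)
  wb(hdr$qform_code, 2L)
  wb(hdr$sform_code, 2L)
  wb(hdr$quatern, 4L, "double")
  wb(hdr$srow, 4L, "double")
  writeBin(hdr$intent_name, con)
  writeBin(hdr$magic, con)
  writeBin(raw(4L), con)          # no extensions
  vals <- as.vector(x)
  if (spec$what == "integer") {
    vals <- as.integer(round(vals))
    writeBin(vals, con, size = spec$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = spec$size, endian = "little")
  }
  invisible(path)
}
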