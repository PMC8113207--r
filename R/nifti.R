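# Minimal NIfTI-1 (.nii / .nii.gz) reader and writer.
#
# Scope is deliberately narrow: single-file NIfTI-1 ("n+1"), 3-D images,
# scalar datatypes uint8/int8/int16/uint16/int32/float32/float64, optional
# scl_slope/scl_inter scaling, either endianness, optional gzip. This covers
# everything the quantification pipeline reads and writes; it is not a
# general neuroimaging I/O library.

NIFTI_HDR_SIZE <- 348L
NIFTI_VOX_OFFSET <- 352L

# datatype code -> (what, size, signed)
.nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

.open_maybe_gz <- function(path, mode) {
  # gzfile transparently reads uncompressed files too
  if (grepl("\\.gz$", path) || grepl("rb", mode)) gzfile(path, mode) else file(path, mode)
}

.read_nifti_header <- function(con) {
  raw_hdr <- readBin(con, "raw", n = NIFTI_HDR_SIZE)
  if (length(raw_hdr) < NIFTI_HDR_SIZE)
    stop("file too short to contain a NIfTI-1 header")
  endian <- "little"
  sz <- readBin(raw_hdr[1:4], "integer", size = 4L, endian = endian)
  if (sz != NIFTI_HDR_SIZE) {
    endian <- "big"
    sz <- readBin(raw_hdr[1:4], "integer", size = 4L, endian = endian)
    if (sz != NIFTI_HDR_SIZE)
      stop("not a NIfTI-1 file (sizeof_hdr != 348 in either endianness)")
  }
  rd <- function(off, what, size, n) {
    readBin(raw_hdr[(off + 1L):(off + size * n)], what,
            n = n, size = size, endian = endian)
  }
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic '", magic, "')")
  list(
    endian     = endian,
    dim        = rd(40L, "integer", 2L, 8L),
    datatype   = rd(70L, "integer", 2L, 1L),
    bitpix     = rd(72L, "integer", 2L, 1L),
    pixdim     = rd(76L, "double", 4L, 8L),
    vox_offset = rd(108L, "double", 4L, 1L),
    scl_slope  = rd(112L, "double", 4L, 1L),
    scl_inter  = rd(116L, "double", 4L, 1L),
    qform_code = rd(252L, "integer", 2L, 1L),
    sform_code = rd(254L, "integer", 2L, 1L),
    srow       = rbind(rd(280L, "double", 4L, 4L),
                       rd(296L, "double", 4L, 4L),
                       rd(312L, "double", 4L, 4L)),
    qoffset    = rd(268L, "double", 4L, 3L)
  )
}

#' Read a 3-D NIfTI-1 image as a raw array
#'
#' Low-level reader used by [read_volume()] and [read_mask_set()]. Applies
#' `scl_slope`/`scl_inter` when set; no reorientation is performed.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `values` (3-D array), `spacing_mm` (length 3),
#'   `origin_mm` (length 3), `axis_codes` (character, informational).
#' @keywords internal
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- .open_maybe_gz(path, "rb")
  on.exit(close(con))
  hdr <- .read_nifti_header(con)

  ndim <- hdr$dim[1]
  if (ndim < 1L || ndim > 7L) stop("invalid NIfTI dim[0] = ", ndim)
  # trailing singleton dimensions (e.g. a 4th dim of length 1) are tolerated
  if (ndim > 3L && any(hdr$dim[(3L + 2L):(ndim + 1L)] > 1L))
    stop("image is not 3-D (dim = ",
         paste(hdr$dim[2:(ndim + 1L)], collapse = "x"), ")")
  shape <- hdr$dim[2:4]
  if (ndim < 3L) shape[(ndim + 1L):3L] <- 1L
  if (any(shape < 1L)) stop("invalid image dimensions")

  dt <- .nifti_dtypes[[as.character(hdr$datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", hdr$datatype)

  # skip any header extension up to vox_offset
  skip <- as.integer(round(hdr$vox_offset)) - NIFTI_HDR_SIZE
  if (skip > 0L) readBin(con, "raw", n = skip)

  n <- prod(shape)
  if (dt$size <= 2L) {
    vals <- readBin(con, dt$what, n = n, size = dt$size,
                    signed = dt$signed, endian = hdr$endian)
  } else {
    vals <- readBin(con, dt$what, n = n, size = dt$size, endian = hdr$endian)
  }
  if (length(vals) < n) stop("truncated NIfTI data section")
  vals <- as.double(vals)
  if (is.finite(hdr$scl_slope) && hdr$scl_slope != 0 &&
      !(hdr$scl_slope == 1 && hdr$scl_inter == 0)) {
    vals <- vals * hdr$scl_slope + hdr$scl_inter
  }

  spacing <- hdr$pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("non-positive voxel spacing in header: ",
         paste(signif(spacing, 6), collapse = ", "))

  origin <- if (hdr$sform_code > 0L) hdr$srow[, 4L] else hdr$qoffset
  list(values = array(vals, dim = shape),
       spacing_mm = spacing,
       origin_mm = as.double(origin),
       axis_codes = c("R", "A", "S"))
}

#' Write a 3-D array as a NIfTI-1 file
#'
#' @param values 3-D numeric array.
#' @param path output path; gzip-compressed when it ends in `.gz`.
#' @param spacing_mm per-axis voxel edge length, mm.
#' @param origin_mm position of the first voxel (sform translation).
#' @param datatype `"float64"` (lossless for R doubles), `"float32"`, or
#'   `"int32"` (label masks).
#' @return `path`, invisibly.
#' @keywords internal
write_nifti <- function(values, path, spacing_mm,
                        origin_mm = c(0, 0, 0),
                        datatype = c("float64", "float32", "int32")) {
  datatype <- match.arg(datatype)
  stopifnot(length(dim(values)) == 3L, length(spacing_mm) == 3L)
  if (any(spacing_mm <= 0)) stop("spacing must be positive")
  code <- switch(datatype, float64 = 64L, float32 = 16L, int32 = 8L)
  bitpix <- if (datatype == "float64") 64L else 32L

  con <- .open_maybe_gz(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wc <- function(s, width) {
    r <- raw(width)
    b <- charToRaw(s)
    if (length(b)) r[seq_along(b)] <- b
    writeBin(r, con)
  }

  wi(NIFTI_HDR_SIZE, 4L)                    # sizeof_hdr
  wc("", 10L); wc("", 18L)                  # data_type, db_name
  wi(0L, 4L); wi(0L, 2L)                    # extents, session_error
  wc("r", 1L); wc("", 1L)                   # regular, dim_info
  wi(c(3L, dim(values), 1L, 1L, 1L, 1L), 2L)  # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2L)                # intent_p1..3, intent_code
  wi(code, 2L); wi(bitpix, 2L); wi(0L, 2L)  # datatype, bitpix, slice_start
  wf(c(1, spacing_mm, 1, 1, 1, 1))          # pixdim[8] (qfac = 1)
  wf(NIFTI_VOX_OFFSET)                      # vox_offset
  wf(1); wf(0)                              # scl_slope, scl_inter
  wi(0L, 2L); wc("", 1L); writeBin(as.raw(10L), con)  # slice_end/code, xyzt_units (mm)
  wf(0); wf(0); wf(0); wf(0)                # cal_max, cal_min, slice_duration, toffset
  wi(0L, 4L); wi(0L, 4L)                    # glmax, glmin
  wc("dpdquant", 80L); wc("", 24L)          # descrip, aux_file
  wi(0L, 2L); wi(1L, 2L)                    # qform_code, sform_code
  wf(c(0, 0, 0)); wf(origin_mm)             # quatern_b/c/d, qoffset
  wf(c(spacing_mm[1], 0, 0, origin_mm[1]))  # srow_x
  wf(c(0, spacing_mm[2], 0, origin_mm[2]))  # srow_y
  wf(c(0, 0, spacing_mm[3], origin_mm[3]))  # srow_z
  wc("", 16L)                               # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(NIFTI_VOX_OFFSET - NIFTI_HDR_SIZE), con)  # pad 348 -> 352

  v <- as.vector(values)
  if (datatype == "int32") {
    writeBin(as.integer(round(v)), con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(v), con, size = bitpix %/% 8L, endian = "little")
  }
  invisible(path)
}
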