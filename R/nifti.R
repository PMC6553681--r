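# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# No NIfTI package is available in the supported dependency set, so the
# small fixed-layout NIfTI-1 header is handled directly. Supported voxel
# types: uint8 (2), int16 (4), int32 (8), float32 (16), float64 (64).
# scl_slope / scl_inter are applied on read; the writer emits float64 for
# intensities and uint8 for masks, sform identity (code 1), magic "n+1".

nifti_dtypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE))

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (numeric array), `dim`, `pixdim`, `affine`
#'   (3 x 4 sform rows), and `datatype`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path))
    rt_error(paste0("file not found: ", path), "radtex_io_error")
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) rt_error("truncated NIfTI header", "radtex_io_error")
  rd <- function(off, what, n, size, endian) {
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = TRUE)
  }
  endian <- "little"
  if (rd(0L, "integer", 1L, 4L, endian) != 348L) {
    endian <- "big"
    if (rd(0L, "integer", 1L, 4L, endian) != 348L)
      rt_error("not a NIfTI-1 file (bad sizeof_hdr)", "radtex_io_error")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    rt_error("not a NIfTI-1 file (bad magic)", "radtex_io_error")
  dim0 <- rd(40L, "integer", 8L, 2L, endian)
  nd <- dim0[1]
  dims <- dim0[2:(1 + max(nd, 1L))]
  datatype <- rd(70L, "integer", 1L, 2L, endian)
  pixdim <- rd(76L, "double", 8L, 4L, endian)
  vox_offset <- rd(108L, "double", 1L, 4L, endian)
  scl_slope <- rd(112L, "double", 1L, 4L, endian)
  scl_inter <- rd(116L, "double", 1L, 4L, endian)
  affine <- rbind(rd(280L, "double", 4L, 4L, endian),
                  rd(296L, "double", 4L, 4L, endian),
                  rd(312L, "double", 4L, 4L, endian))
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt))
    rt_error(paste0("unsupported NIfTI datatype ", datatype), "radtex_io_error")
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) < n) rt_error("truncated NIfTI data", "radtex_io_error")
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dims), dim = dims, pixdim = pixdim[2:(1 + max(nd, 1L))],
       affine = affine, datatype = datatype)
}

#' Write a NIfTI-1 volume
#'
#' @param data numeric 3D array.
#' @param path output `.nii` or `.nii.gz` path (gzip chosen by extension).
#' @param datatype 64 (float64, default) or 2 (uint8, for binary masks).
#' @param pixdim voxel sizes (mm), length 3.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, datatype = 64L, pixdim = c(1, 1, 1)) {
  d <- dim(data)
  if (length(d) != 3L) rt_error("expected a 3D array", "radtex_invalid_input")
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt) || !datatype %in% c(2L, 64L))
    rt_error("writer supports datatype 2 (uint8) or 64 (float64)",
             "radtex_io_error")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wb(348L, 4L)                                   # sizeof_hdr
  wraw(36L)                                      # data_type..dim_info
  wb(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), 2L)   # dim[8]
  wraw(14L)                                      # intent_p1..intent_code
  wb(as.integer(datatype), 2L)                   # datatype
  wb(as.integer(dt$size * 8L), 2L)               # bitpix
  wb(0L, 2L)                                     # slice_start
  wb(c(1, pixdim, 1, 1, 1, 1), 4L)               # pixdim[8]
  wb(352, 4L)                                    # vox_offset
  wb(c(1, 0), 4L)                                # scl_slope, scl_inter
  wraw(4L)                                       # slice_end..xyzt_units
  wb(c(0, 0, 0, 0), 4L)                          # cal_max..slice_duration? (4 floats: cal_max cal_min slice_duration toffset)
  wb(c(0L, 0L), 4L)                              # glmax, glmin
  wraw(104L)                                     # descrip + aux_file
  wb(c(0L, 1L), 2L)                              # qform_code, sform_code
  wb(rep(0, 6), 4L)                              # quatern + qoffset
  wb(c(pixdim[1], 0, 0, 0), 4L)                  # srow_x
  wb(c(0, pixdim[2], 0, 0), 4L)                  # srow_y
  wb(c(0, 0, pixdim[3], 0), 4L)                  # srow_z
  wraw(16L)                                      # intent_name
  writeBin(charToRaw("n+1"), con); wraw(1L)      # magic
  wraw(4L)                                       # extension flag
  if (datatype == 2L) {
    writeBin(as.raw(as.integer(data)), con)
  } else {
    wb(as.double(data), 8L)
  }
  invisible(path)
}
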