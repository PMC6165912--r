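# Volume file I/O: NIfTI-1 (.nii, .nii.gz) and MetaImage (.mha, .mhd).
# A deliberately small reader/writer pair covering the scalar 3-D
# images this pipeline uses: voxel data as stored, spacing from the
# header, origin from qoffset/srow (NIfTI) or Offset (MetaImage).
# Orientation matrices are not applied; arrays are taken in stored
# (x, y, z) order. DICOM series and RT-STRUCT contours are out of scope.

NIFTI_DTYPES <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE),   # uint8
  `4` = list(what = "integer", size = 2L, signed = TRUE),    # int16
  `8` = list(what = "integer", size = 4L, signed = TRUE),    # int32
  `16` = list(what = "double", size = 4L, signed = TRUE),    # float32
  `64` = list(what = "double", size = 8L, signed = TRUE),    # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)  # uint16
)

#' Read a CT volume from NIfTI-1 or MetaImage
#'
#' @param path file path ending in `.nii`, `.nii.gz`, `.mha` or `.mhd`.
#' @return a [volume_grid()] with spacing and origin from the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) read_nifti(path)
  else if (grepl("\\.(mha|mhd)$", lp)) read_metaimage(path)
  else stop("unsupported volume format (expect .nii/.nii.gz/.mha/.mhd): ",
            path)
}

#' Read a binary mask volume
#'
#' @param path as in [read_volume()]; nonzero voxels become foreground.
#' @param laterality stored on the returned mask.
#' @return a [binary_mask()].
#' @export
read_mask <- function(path, laterality = "unspecified") {
  v <- read_volume(path)
  binary_mask(v$voxels != 0, v, laterality = laterality)
}

read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "rb")
         else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("malformed NIfTI file (truncated header): ", path)
  rd <- function(what, n, size, off, endian, signed = TRUE)
    readBin(hdr[(off + 1):length(hdr)], what, n = n, size = size,
            endian = endian, signed = signed)
  endian <- "little"
  if (rd("integer", 1, 4, 0, endian) != 348L) {
    endian <- "big"
    if (rd("integer", 1, 4, 0, endian) != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  dims <- rd("integer", 8, 2, 40, endian)
  ndim <- dims[1]
  if (ndim > 3L && any(dims[seq(5, 1 + ndim)] > 1L))
    stop("only 3-D volumes are supported; file is ", ndim, "-D: ", path)
  ext <- pmax(dims[2:4], 1L)
  dtype <- rd("integer", 1, 2, 70, endian)
  spec <- NIFTI_DTYPES[[as.character(dtype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code ", dtype, ": ", path)
  pixdim <- rd("double", 8, 4, 76, endian)
  spacing <- abs(pixdim[2:4])
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("missing or invalid voxel spacing in NIfTI header: ", path)
  vox_offset <- rd("double", 1, 4, 108, endian)
  scl_slope <- rd("double", 1, 4, 112, endian)
  scl_inter <- rd("double", 1, 4, 116, endian)
  origin <- c(rd("double", 1, 4, 268, endian),
              rd("double", 1, 4, 272, endian),
              rd("double", 1, 4, 276, endian))
  skip <- max(vox_offset, 348) - 348
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  n <- prod(ext)
  vox <- readBin(con, spec$what, n = n, size = spec$size, endian = endian,
                 signed = spec$signed)
  if (length(vox) != n) stop("truncated NIfTI voxel data: ", path)
  vox <- as.numeric(vox)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vox <- vox * scl_slope + scl_inter
  volume_grid(array(vox, dim = ext), spacing, origin)
}

#' Write a volume to NIfTI-1 or MetaImage
#'
#' NIfTI output is float32 by default (`datatype = "float"`) or uint8
#' (`datatype = "uint8"`, for masks); `.nii.gz` is written compressed.
#' MetaImage (`.mha`) embeds the raw data in one uncompressed file;
#' `.mhd` writes a separate `.raw` next to it.
#'
#' @param vol a [volume_grid()] or [binary_mask()].
#' @param path output path; the extension selects the format.
#' @param datatype "float" or "uint8".
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = c("float", "uint8")) {
  datatype <- match.arg(datatype)
  if (inherits(vol, "binary_mask")) {
    datatype <- "uint8"
    vol <- volume_grid(array(as.numeric(vol$voxels), dim(vol$voxels)),
                       vol$spacing, vol$origin)
  }
  stopifnot(inherits(vol, c("volume_grid", "prob_map")))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) write_nifti(vol, path, datatype)
  else if (grepl("\\.(mha|mhd)$", lp)) write_metaimage(vol, path, datatype)
  else stop("unsupported output format: ", path)
  invisible(path)
}

#' @rdname write_volume
#' @param mask a [binary_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  write_volume(mask, path)
}

write_nifti <- function(vol, path, datatype) {
  dtcode <- if (datatype == "float") 16L else 2L
  size <- if (datatype == "float") 4L else 1L
  ext <- dim(vol$voxels)
  hdr <- raw(348)
  put <- function(x, what, size, off) {
    b <- writeBin(x, raw(), size = size, endian = "little")
    hdr[off + seq_along(b)] <<- b
  }
  put(348L, "integer", 4L, 0)
  put(as.integer(c(3L, ext, 1L, 1L, 1L, 1L)), "integer", 2L, 40)
  put(dtcode, "integer", 2L, 70)
  put(8L * size, "integer", 2L, 72)                    # bitpix
  put(c(1, vol$spacing, 0, 0, 0, 0), "double", 4L, 76) # pixdim
  put(352, "double", 4L, 108)                          # vox_offset
  put(1, "double", 4L, 112)                            # scl_slope
  put(0, "double", 4L, 116)                            # scl_inter
  put(c(0L, 1L), "integer", 2L, 252)                   # qform 0, sform 1
  put(vol$origin, "double", 4L, 268)                   # qoffset (informative)
  put(c(vol$spacing[1], 0, 0, vol$origin[1]), "double", 4L, 280) # srow_x
  put(c(0, vol$spacing[2], 0, vol$origin[2]), "double", 4L, 296) # srow_y
  put(c(0, 0, vol$spacing[3], vol$origin[3]), "double", 4L, 312) # srow_z
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "wb")
         else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)  # pad to vox_offset 352
  if (datatype == "float")
    writeBin(as.numeric(vol$voxels), con, size = 4L, endian = "little")
  else
    writeBin(as.integer(round(pmin(pmax(vol$voxels, 0), 255))), con,
             size = 1L, endian = "little")
  invisible(path)
}

META_TYPES <- c(MET_UCHAR = "uint8", MET_CHAR = "int8", MET_SHORT = "int16",
                MET_USHORT = "uint16", MET_INT = "int32",
                MET_FLOAT = "float32", MET_DOUBLE = "float64")

read_metaimage <- function(path) {
  # header lines are "Key = Value"; for .mha the raw data follows the
  # ElementDataFile = LOCAL line in the same file
  con <- file(path, "rb")
  con_open <- TRUE
  on.exit(if (con_open) close(con))
  keys <- list()
  repeat {
    line <- readLines(con, 1L, warn = FALSE)
    if (length(line) == 0) stop("malformed MetaImage header (no ElementDataFile): ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1])
    keys[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(keys$NDims %||% "3")
  if (ndims != 3L) stop("only 3-D MetaImage volumes are supported; file is ",
                        ndims, "-D: ", path)
  ext <- as.integer(strsplit(keys$DimSize, "\\s+")[[1]])
  sp_raw <- keys$ElementSpacing %||% keys$ElementSize
  if (is.null(sp_raw)) stop("missing ElementSpacing in MetaImage header: ", path)
  spacing <- as.numeric(strsplit(sp_raw, "\\s+")[[1]])
  origin <- as.numeric(strsplit(keys$Offset %||% "0 0 0", "\\s+")[[1]])
  if (isTRUE(toupper(keys$CompressedData %||% "FALSE") == "TRUE"))
    stop("compressed MetaImage data is not supported: ", path)
  et <- keys$ElementType
  if (is.null(et) || !et %in% names(META_TYPES))
    stop("unsupported MetaImage ElementType: ", et %||% "<missing>")
  rb <- switch(META_TYPES[[et]],
    uint8 = function(c_, n) readBin(c_, "integer", n, 1L, signed = FALSE),
    int8 = function(c_, n) readBin(c_, "integer", n, 1L, signed = TRUE),
    int16 = function(c_, n) readBin(c_, "integer", n, 2L, endian = "little"),
    uint16 = function(c_, n) readBin(c_, "integer", n, 2L, signed = FALSE,
                                     endian = "little"),
    int32 = function(c_, n) readBin(c_, "integer", n, 4L, endian = "little"),
    float32 = function(c_, n) readBin(c_, "double", n, 4L, endian = "little"),
    float64 = function(c_, n) readBin(c_, "double", n, 8L, endian = "little"))
  n <- prod(ext)
  if (keys$ElementDataFile == "LOCAL") {
    vox <- rb(con, n)
  } else {
    close(con); con_open <- FALSE
    datafile <- file.path(dirname(path), keys$ElementDataFile)
    if (!file.exists(datafile)) stop("MetaImage data file missing: ", datafile)
    dcon <- file(datafile, "rb")
    on.exit(close(dcon), add = TRUE)
    vox <- rb(dcon, n)
  }
  if (length(vox) != n) stop("truncated MetaImage voxel data: ", path)
  volume_grid(array(as.numeric(vox), dim = ext), spacing, origin)
}

write_metaimage <- function(vol, path, datatype) {
  et <- if (datatype == "float") "MET_FLOAT" else "MET_UCHAR"
  mhd <- grepl("\\.mhd$", tolower(path))
  datafile <- if (mhd) sub("\\.mhd$", ".raw", path, ignore.case = TRUE)
              else "LOCAL"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %s", paste(dim(vol$voxels), collapse = " ")),
    sprintf("ElementSpacing = %s", paste(vol$spacing, collapse = " ")),
    sprintf("Offset = %s", paste(vol$origin, collapse = " ")),
    sprintf("ElementType = %s", et),
    sprintf("ElementDataFile = %s",
            if (mhd) basename(datafile) else "LOCAL"))
  wb <- function(con) {
    if (datatype == "float")
      writeBin(as.numeric(vol$voxels), con, size = 4L, endian = "little")
    else
      writeBin(as.integer(round(pmin(pmax(vol$voxels, 0), 255))), con,
               size = 1L, endian = "little")
  }
  if (mhd) {
    writeLines(hdr, path)
    con <- file(datafile, "wb"); on.exit(close(con))
    wb(con)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    wb(con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
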