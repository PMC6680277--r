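#' @useDynLib xrh, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm sd quantile
#' @importFrom utils read.csv write.csv head
NULL

.DTYPES <- c("float32", "uint16", "uint8")
.CAL_STATES <- c("raw", "preprocessed", "calibrated")

#' Volume metadata
#'
#' Describes the grid of a reconstructed microCT volume: isotropic voxel size
#' in micrometres, array shape as `(nz, ny, nx)`, the storage scalar type and
#' the calibration state of the gray values.
#'
#' The default fixture voxel size, 8.48 um, is the isotropic voxel size of
#' the FFPE scanning protocol this toolkit was designed around.
#'
#' @param voxel_size_um Positive isotropic voxel edge length in micrometres.
#' @param shape Integer triple `(nz, ny, nx)`, all entries >= 1.
#' @param dtype_tag One of `"float32"`, `"uint16"`, `"uint8"`.
#' @param calibration_state One of `"raw"`, `"preprocessed"`, `"calibrated"`.
#' @return An object of class `xrh_meta`.
#' @export
volume_meta <- function(voxel_size_um = 8.48, shape,
                        dtype_tag = "float32",
                        calibration_state = "raw") {
  stopifnot(is.numeric(voxel_size_um), length(voxel_size_um) == 1L)
  if (!is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("voxel_size_um must be a positive real")
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("shape must be an integer triple (nz, ny, nx) with all entries >= 1")
  dtype_tag <- match.arg(dtype_tag, .DTYPES)
  calibration_state <- match.arg(calibration_state, .CAL_STATES)
  structure(list(voxel_size_um = as.numeric(voxel_size_um), shape = shape,
                 dtype_tag = dtype_tag, calibration_state = calibration_state),
            class = "xrh_meta")
}

#' Construct a volume
#'
#' A volume couples a 3D scalar array indexed `[z, y, x]` (R array with
#' `dim = c(nz, ny, nx)`) with its [volume_meta()]. By convention the XY plane
#' (fixed z) is the plane parallel to the histology cassette, so scrolling
#' through z emulates serial sectioning. Physical coordinates are zero-based:
#' the centre of voxel `(z, y, x)` sits at `c(x, y, z) * voxel_size_um`.
#'
#' @param data Numeric 3D array, `dim = c(nz, ny, nx)`.
#' @param voxel_size_um Isotropic voxel size (um).
#' @param dtype_tag Storage type tag; integer tags imply whole-number values.
#' @param calibration_state Gray-value provenance flag.
#' @return An object of class `xrh_volume` with fields `data` and `meta`.
#' @export
volume <- function(data, voxel_size_um = 8.48, dtype_tag = "float32",
                   calibration_state = "raw") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array with dim = c(nz, ny, nx)")
  meta <- volume_meta(voxel_size_um, dim(data), dtype_tag, calibration_state)
  structure(list(data = data, meta = meta), class = "xrh_volume")
}

#' @export
print.xrh_volume <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<xrh_volume> %d x %d x %d (z,y,x), %.4g um/voxel, %s, %s\n",
              m$shape[1], m$shape[2], m$shape[3], m$voxel_size_um,
              m$dtype_tag, m$calibration_state))
  rng <- range(x$data)
  cat(sprintf("  gray range [%.6g, %.6g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @rdname volume
#' @param x Object to test.
#' @export
is_volume <- function(x) inherits(x, "xrh_volume")

.assert_volume <- function(x) {
  if (!is_volume(x)) stop("expected an xrh_volume")
  if (!identical(dim(x$data), as.integer(x$meta$shape)))
    stop("volume data dimensions do not match meta$shape")
  invisible(x)
}

.with_meta <- function(vol, data, dtype_tag = vol$meta$dtype_tag,
                       calibration_state = vol$meta$calibration_state) {
  volume(data, vol$meta$voxel_size_um, dtype_tag, calibration_state)
}

# ---- sidecar ---------------------------------------------------------------

#' Read or write a raw-volume sidecar file
#'
#' Reconstructed raw volumes are headerless, so every `.raw` file is paired
#' with a small JSON sidecar declaring shape, dtype, voxel size and
#' endianness (always little-endian). No header guessing is performed.
#'
#' @param path Path to the sidecar JSON.
#' @return `read_sidecar()` returns an `xrh_meta`.
#' @export
read_sidecar <- function(path) {
  if (!file.exists(path)) stop("sidecar file not found: ", path)
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("shape", "dtype", "voxel_size_um"))
    if (is.null(s[[f]])) stop("sidecar missing field: ", f)
  if (!is.null(s$endianness) && !identical(s$endianness, "little"))
    stop("only little-endian raw volumes are supported")
  volume_meta(s$voxel_size_um, s$shape, s$dtype,
              if (is.null(s$calibration_state)) "raw" else s$calibration_state)
}

#' @rdname read_sidecar
#' @param meta An `xrh_meta` to serialize.
#' @export
write_sidecar <- function(meta, path) {
  jsonlite::write_json(
    list(shape = meta$shape, dtype = meta$dtype_tag,
         voxel_size_um = meta$voxel_size_um, endianness = "little",
         calibration_state = meta$calibration_state),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.dtype_bytes <- c(float32 = 4L, uint16 = 2L, uint8 = 1L)

# ---- read/write ------------------------------------------------------------

#' Read a volume from disk
#'
#' Supports headerless raw binaries (little-endian, x-fastest order, with a
#' mandatory JSON sidecar) and multi-page grayscale TIFF stacks (page order
#' maps to z). 16-bit TIFF values are read as unsigned integers in
#' `[0, 65535]`; 32-bit float TIFFs are read at face value.
#'
#' @param path File to read (`.raw` or `.tif`/`.tiff`).
#' @param sidecar For raw input: path to the sidecar JSON, or an `xrh_meta`.
#'   Defaults to `<path>.json` when it exists.
#' @param voxel_size_um Voxel size for TIFF input (TIFF carries no spacing
#'   metadata here); ignored for raw input.
#' @param calibration_state Calibration flag for TIFF input.
#' @return An `xrh_volume`.
#' @export
read_volume <- function(path, sidecar = NULL, voxel_size_um = 8.48,
                        calibration_state = "raw") {
  if (!file.exists(path)) stop("volume file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e) tiff::readTIFF(path, all = TRUE))
    if (!is.list(pages)) pages <- list(pages)
    if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
      stop("only single-channel grayscale TIFF stacks are supported")
    nz <- length(pages)
    ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
    data <- array(0, c(nz, ny, nx))
    for (z in seq_len(nz)) data[z, , ] <- pages[[z]]
    dtype <- if (is.integer(pages[[1]])) {
      if (max(data) > 255) "uint16" else "uint8"
    } else "float32"
    return(volume(data, voxel_size_um, dtype, calibration_state))
  }
  meta <- if (inherits(sidecar, "xrh_meta")) sidecar
          else read_sidecar(if (is.null(sidecar)) paste0(path, ".json") else sidecar)
  nvox <- prod(meta$shape)
  bytes <- .dtype_bytes[[meta$dtype_tag]]
  expected <- nvox * bytes
  actual <- file.info(path)$size
  if (actual != expected)
    stop(sprintf("raw file size mismatch: %d bytes on disk, %d expected for shape (%s) %s",
                 actual, expected, paste(meta$shape, collapse = ","), meta$dtype_tag))
  con <- file(path, "rb"); on.exit(close(con))
  vals <- switch(meta$dtype_tag,
    float32 = readBin(con, "double", n = nvox, size = 4L, endian = "little"),
    uint16  = readBin(con, "integer", n = nvox, size = 2L, signed = FALSE, endian = "little"),
    uint8   = as.integer(readBin(con, "raw", n = nvox)))
  # file order is x-fastest ([z][y][x] C order); R arrays are column-major
  data <- aperm(array(as.numeric(vals), dim = rev(meta$shape)), c(3, 2, 1))
  volume(data, meta$voxel_size_um, meta$dtype_tag, meta$calibration_state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a volume to disk
#'
#' `format = "raw"` writes a little-endian x-fastest binary plus a
#' `<path>.json` sidecar (any dtype). `format = "tiff"` writes one 16-bit
#' unsigned grayscale page per z-slice; float volumes must be windowed to
#' 16-bit first (see [window_and_quantize()]) — lossy implicit conversion is
#' refused.
#'
#' @param vol An `xrh_volume`.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"raw"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "raw", "tiff")) {
  .assert_volume(vol)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tif", "tiff")) "tiff" else "raw"
  }
  if (format == "tiff") {
    if (vol$meta$dtype_tag == "float32")
      stop("float32 volumes cannot be written as a TIFF stack losslessly; ",
           "apply window_and_quantize() first or use format = \"raw\"")
    mx <- if (vol$meta$dtype_tag == "uint16") 65535 else 255
    bits <- if (vol$meta$dtype_tag == "uint16") 16L else 8L
    pages <- lapply(seq_len(vol$meta$shape[1]),
                    function(z) matrix(vol$data[z, , ], vol$meta$shape[2]) / mx)
    tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
    return(invisible(path))
  }
  con <- file(path, "wb")
  vals <- as.vector(aperm(vol$data, c(3, 2, 1)))
  switch(vol$meta$dtype_tag,
    float32 = writeBin(vals, con, size = 4L, endian = "little"),
    uint16  = {
      iv <- as.integer(round(vals))
      if (any(iv < 0L | iv > 65535L)) { close(con); stop("uint16 values out of range [0, 65535]") }
      writeBin(as.integer(ifelse(iv > 32767L, iv - 65536L, iv)), con, size = 2L, endian = "little")
    },
    uint8   = {
      iv <- as.integer(round(vals))
      if (any(iv < 0L | iv > 255L)) { close(con); stop("uint8 values out of range [0, 255]") }
      writeBin(as.raw(iv), con)
    })
  close(con)
  write_sidecar(vol$meta, paste0(path, ".json"))
  invisible(path)
}

# ---- 2D images -------------------------------------------------------------

#' Read / write 2D raster images
#'
#' Histology slides and rendered frames travel as PNG or TIFF. Grayscale
#' images are matrices (rows = y, cols = x); colour images are
#' `height x width x 3` arrays. Values are kept in `[0, 1]` for 8/16-bit
#' containers.
#'
#' @param path Image path (`.png`, `.tif`, `.tiff`).
#' @return `read_image()` returns a matrix or 3D array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1]
  img
}

#' @rdname read_image
#' @param img Matrix or `h x w x 3` array with values in `[0, 1]`.
#' @param bits Bit depth for the container (8 or 16; 16 only for TIFF/PNG gray).
#' @export
write_image <- function(img, path, bits = 8L) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(img, 0), 1)
  switch(ext,
    png  = png::writePNG(img, path),
    tif  = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits),
                           compression = "none"),
    stop("unsupported image format: .", ext))
  invisible(path)
}
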