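#' Calibrated chemical image for one ion/fragment channel
#'
#' A `chem_image` holds one ToF-SIMS chemical image: an 8-bit intensity grid
#' (integers 0--255) plus the pixel-size calibration and channel metadata
#' needed to report particle areas and radii in micrometres. The coordinate
#' convention is row-major with the origin at the top-left pixel, 0-based in
#' index space; physical coordinates are pixel-centre positions, i.e. pixel
#' `(i, j)` (row, column, 1-based in R) is centred at
#' `((j - 0.5) * pixel_size_um, (i - 0.5) * pixel_size_um)`.
#'
#' @param data integer matrix of intensities in `[0, 255]` (rows = y,
#'   columns = x).
#' @param pixel_size_um physical edge length of one pixel in micrometres
#'   (> 0). Fields of view in this instrument class are 25x25 to
#'   100x100 um^2.
#' @param channel ion/fragment label, e.g. `"Li"`, `"Na"`, `"OH"`.
#' @param polarity `"positive"` or `"negative"` acquisition mode.
#' @param sample_id label for the sample/treatment the image came from.
#' @return An object of class `chem_image`.
#' @export
chem_image <- function(data, pixel_size_um, channel = "unknown",
                       polarity = c("positive", "negative"),
                       sample_id = "sample") {
  polarity <- match.arg(polarity)
  if (!is.matrix(data)) stop("`data` must be a matrix")
  if (anyNA(data)) stop("`data` must not contain NA")
  if (min(data) < 0 || max(data) > 255) stop("intensities must lie in [0, 255]")
  if (any(data != round(data))) stop("intensities must be whole numbers (8-bit)")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  storage.mode(data) <- "integer"
  structure(
    list(data = data, pixel_size_um = as.numeric(pixel_size_um),
         channel = channel, polarity = polarity, sample_id = sample_id),
    class = "chem_image"
  )
}

#' @export
print.chem_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<chem_image> %s (%s mode), sample '%s'\n  %d x %d px, %.4g um/px (%.4g x %.4g um^2)\n  intensity range [%d, %d]\n",
    x$channel, x$polarity, x$sample_id, d[1], d[2], x$pixel_size_um,
    d[2] * x$pixel_size_um, d[1] * x$pixel_size_um, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.chem_image <- function(x) dim(x$data)

#' Sum the three colour channels of an RGB raster into one 8-bit channel
#'
#' Image exports from ToF-SIMS acquisition software are often RGB renderings
#' of a single ion signal. Standardization first sums the three colour
#' channels per pixel (in widened integers, so no clipping at 255 occurs
#' before the rescale) and then converts the summed range `[0, 765]` linearly
#' to 8-bit `[0, 255]` with round-half-up.
#'
#' @param rgb 3-d array `height x width x 3` with channel values either in
#'   `[0, 1]` (as returned by [png::readPNG()] / [tiff::readTIFF()]) or
#'   integers in `[0, 255]`.
#' @return Integer matrix in `[0, 255]`.
#' @export
sum_channels <- function(rgb) {
  if (!(is.array(rgb) && length(dim(rgb)) == 3))
    stop("`rgb` must be a 3-d array")
  if (dim(rgb)[3] != 3)
    stop("`rgb` must have exactly 3 channels, got ", dim(rgb)[3])
  if (is.double(rgb) && max(rgb) <= 1 && min(rgb) >= 0)
    rgb <- round(rgb * 255)
  s <- rgb[, , 1] + rgb[, , 2] + rgb[, , 3]           # 0..765, no clipping
  out <- floor(s * 255 / 765 + 0.5)                   # round half up
  storage.mode(out) <- "integer"
  out
}

## Bit depth of a raster file without decoding the full image.
raster_bit_depth <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    hdr <- readBin(path, "raw", n = 26)
    return(as.integer(hdr[25]))                        # IHDR bit-depth byte
  }
  img <- tiff::readTIFF(path, info = TRUE, all = FALSE)
  bits <- attr(img, "bits.per.sample")
  if (is.null(bits)) 8L else as.integer(bits)
}

#' Read a chemical image from an 8-bit TIFF or PNG file
#'
#' Grayscale rasters are taken as-is; RGB rasters are channel-summed and
#' rescaled via [sum_channels()]. Inputs deeper than 8 bits per sample are
#' rejected: the analysis chain is defined on standardized 8-bit exports.
#' If a YAML sidecar `<path>.yml` exists, `pixel_size_um`, `channel` and
#' `polarity` default to its values.
#'
#' @param path file path (`.tif`/`.tiff`/`.png`).
#' @param pixel_size_um pixel calibration in micrometres; overrides sidecar.
#' @param channel,polarity,sample_id metadata; override sidecar values.
#' @return A [chem_image()].
#' @export
read_chem_image <- function(path, pixel_size_um = NULL, channel = NULL,
                            polarity = NULL, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  side <- paste0(path, ".yml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um %||%
    stop("`pixel_size_um` missing (no sidecar found)")
  channel <- channel %||% meta$channel %||% "unknown"
  polarity <- polarity %||% meta$polarity %||% "positive"
  sample_id <- sample_id %||% meta$sample_id %||%
    sub("\\.(tif|tiff|png)$", "", basename(path), ignore.case = TRUE)

  bits <- raster_bit_depth(path)
  if (bits > 8)
    stop("unsupported bit depth: ", bits,
         " bits per sample; standardized images must be 8-bit")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("not a supported raster format: .", ext))
  nd <- length(dim(img))
  if (nd == 3 && dim(img)[3] == 3) {
    data <- sum_channels(img)
  } else if (nd == 2) {
    data <- round(img * 255)
    storage.mode(data) <- "integer"
  } else {
    stop("expected a grayscale or 3-channel RGB raster, got ",
         if (nd == 3) paste0(dim(img)[3], " channels") else "a non-raster input")
  }
  chem_image(data, pixel_size_um, channel = channel, polarity = polarity,
             sample_id = sample_id)
}

#' Write a chemical image as 8-bit grayscale TIFF or PNG with YAML sidecar
#'
#' The sidecar `<path>.yml` records `pixel_size_um`, `channel`, `polarity`
#' and `sample_id` so [read_chem_image()] can restore the object bit-exactly.
#'
#' @param img a [chem_image()].
#' @param path output path; format chosen by extension.
#' @param sidecar write the YAML metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_chem_image <- function(img, path, sidecar = TRUE) {
  stopifnot(inherits(img, "chem_image"))
  ext <- tolower(tools::file_ext(path))
  x <- img$data / 255
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8),
    stop("not a supported raster format: .", ext))
  if (sidecar)
    yaml::write_yaml(
      list(pixel_size_um = img$pixel_size_um, channel = img$channel,
           polarity = img$polarity, sample_id = img$sample_id),
      paste0(path, ".yml"))
  invisible(path)
}

#' Physical area of a pixel count
#'
#' @param img a [chem_image()] (or anything with `$pixel_size_um`).
#' @param pixel_count number of pixels (>= 0).
#' @return Area in square micrometres: `pixel_count * pixel_size_um^2`.
#' @export
area_um2 <- function(img, pixel_count) {
  if (any(pixel_count < 0)) stop("`pixel_count` must be >= 0")
  pixel_count * img$pixel_size_um^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
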