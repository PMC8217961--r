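#' Create an intensity image
#'
#' Wraps a numeric matrix of non-negative pixel intensities together with
#' the physical pixel size, the basic container for all analyses in this
#' package.  The default pixel size corresponds to a 180 micron field of
#' view sampled at 512x512 pixels (0.3515625 um/px), typical of the SHG
#' acquisitions this method was designed for.
#'
#' @param pixels numeric matrix, rows indexed top to bottom (image row y),
#'   columns left to right (image column x).
#' @param pixel_size physical size of one pixel in microns.
#' @return an object of class `intensity_image` with elements `pixels`
#'   and `pixel_size`.
#' @export
intensity_image <- function(pixels, pixel_size = 180 / 512) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (!all(is.finite(pixels)))
    stop("all pixel values must be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/px)")
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size)),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d px, %.6g um/px (%.4g x %.4g um)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              ncol(x$pixels) * x$pixel_size, nrow(x$pixels) * x$pixel_size))
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(x$pixels), max(x$pixels), mean(x$pixels)))
  invisible(x)
}

#' @export
dim.intensity_image <- function(x) dim(x$pixels)

as_intensity_image <- function(x, pixel_size = 180 / 512) {
  if (inherits(x, "intensity_image")) return(x)
  intensity_image(x, pixel_size)
}

#' Read a grayscale image from TIFF or PNG
#'
#' Reads a single-channel image into an [intensity_image()].  Multi-channel
#' files are reduced to their first channel.  The physical pixel size is
#' taken from `pixel_size` when given, otherwise from a YAML sidecar file
#' `<path>.yaml` with a `pixel_size` entry, otherwise from the 180/512
#' um/px default.
#'
#' 16-bit TIFFs written by [write_image_tiff()] store intensities scaled
#' by 1/65535; reading restores the original scale.
#'
#' @param path path to a `.tif`, `.tiff` or `.png` file.
#' @param pixel_size optional pixel size in um/px, overriding any sidecar.
#' @return an [intensity_image()].
#' @export
read_intensity_image <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext))
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  arr <- arr * 65535
  if (is.null(pixel_size)) {
    sidecar <- paste0(path, ".yaml")
    if (file.exists(sidecar)) {
      meta <- yaml::read_yaml(sidecar)
      if (!is.null(meta$pixel_size)) pixel_size <- as.numeric(meta$pixel_size)
    }
  }
  if (is.null(pixel_size)) pixel_size <- 180 / 512
  intensity_image(arr, pixel_size)
}

#' Write an intensity image as 16-bit grayscale TIFF
#'
#' Intensities are stored divided by 65535, so values up to 65535 survive
#' the round trip exactly to 16-bit precision.  A YAML sidecar
#' `<path>.yaml` recording the pixel size is written alongside.
#'
#' @param image an [intensity_image()].
#' @param path output path ending in `.tif` or `.tiff`.
#' @param sidecar write the pixel-size sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, sidecar = TRUE) {
  image <- as_intensity_image(image)
  px <- image$pixels
  if (max(px) > 65535)
    warning("intensities above 65535 are clipped in 16-bit TIFF output")
  px <- round(pmin(pmax(px, 0), 65535)) / 65535
  tiff::writeTIFF(px, path, bits.per.sample = 16L, compression = "none")
  if (sidecar)
    yaml::write_yaml(list(pixel_size = image$pixel_size),
                     paste0(path, ".yaml"))
  invisible(path)
}
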