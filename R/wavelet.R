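#' Wavelet analysis configuration
#'
#' Settings for the continuous wavelet transform and the modulus-maxima
#' detector.  The smoothing function is the isotropic 2D Gaussian; the
#' analyzing wavelets are its partial derivatives, so the transform at
#' scale `a` is the intensity gradient of the image smoothed at that
#' scale.  The scale parameter is interpreted as the standard deviation
#' of the Gaussian, in pixels, after conversion from microns.
#'
#' @param scales numeric vector of scales in microns, strictly
#'   increasing.  Defaults to the 40-scale ladder of [scale_ladder()].
#' @param n_bins number of angle-histogram bins over (-pi, pi] used by
#'   downstream [angle_pdf()] calls routed through [multiscale_profile()].
#'   Default 72 (5 degree bins).
#' @param border_factor maxima closer than `border_factor * a` pixels to
#'   any image edge are discarded, neutralizing the periodic wrap-around
#'   of the FFT convolution.  Default 2.
#' @param border_cap_frac upper cap on the exclusion margin as a
#'   fraction of the shorter image side (default 1/8).  Without the cap,
#'   scales beyond 1/4 of the image side would lose every pixel to the
#'   margin and the largest analysis scales would be unmeasurable; with
#'   it, large scales trade some residual wrap-around contamination for
#'   a usable interior.
#' @param modulus_floor maxima with modulus below `modulus_floor` times
#'   the maximum modulus of the response are discarded, suppressing
#'   floating-point plateaus on flat backgrounds.  Default 1e-6.
#' @param truncate kernel support half-width in units of `a` (default 4);
#'   the Gaussian is sampled on `|x| <= truncate * a`.
#' @return an object of class `wavelet_config`.
#' @export
wavelet_config <- function(scales = scale_ladder(), n_bins = 72L,
                           border_factor = 2, border_cap_frac = 1 / 8,
                           modulus_floor = 1e-6, truncate = 4) {
  scales <- as.numeric(scales)
  if (length(scales) < 1L || any(!is.finite(scales)) || any(scales <= 0))
    stop("`scales` must be positive and finite")
  if (is.unsorted(scales, strictly = TRUE))
    stop("`scales` must be strictly increasing")
  if (border_factor < 0) stop("`border_factor` must be >= 0")
  if (border_cap_frac <= 0 || border_cap_frac >= 0.5)
    stop("`border_cap_frac` must be in (0, 0.5)")
  if (n_bins < 8L) stop("`n_bins` must be at least 8")
  structure(list(smoothing_kernel = "gaussian", scales = scales,
                 boundary_mode = "periodic", n_bins = as.integer(n_bins),
                 border_factor = border_factor,
                 border_cap_frac = border_cap_frac,
                 modulus_floor = modulus_floor, truncate = truncate),
            class = "wavelet_config")
}

#' Default scale ladders
#'
#' `scale_ladder()` returns `n` geometrically spaced scales spanning 7 to
#' 112 px (2.46 to 39.4 um at the default pixel size), the four-octave
#' range used for multiscale profiles.  `key_scales()` returns the five
#' octave-spaced scales 7, 14, 28, 56, 112 px -- approximately 2.5, 4.9,
#' 9.8, 19.7 and 39.4 um -- at which headline results are reported.
#'
#' @param n number of scales (default 40).
#' @param pixel_size um/px used to convert the pixel-defined ladder to
#'   microns (default 180/512).
#' @return numeric vector of scales in microns.
#' @export
scale_ladder <- function(n = 40L, pixel_size = 180 / 512) {
  exp(seq(log(7), log(112), length.out = n)) * pixel_size
}

#' @rdname scale_ladder
#' @export
key_scales <- function(pixel_size = 180 / 512) {
  c(7, 14, 28, 56, 112) * pixel_size
}

# Cache of kernel spectra keyed by (nr, nc, a_px, truncate): building and
# Fourier-transforming the two derivative-of-Gaussian kernels dominates
# the per-scale cost, and cohort runs reuse the same image geometry.
.kernel_cache <- new.env(parent = emptyenv())

# conj(fft(k1)) + i * conj(fft(k2)) for the sampled wavelets at scale
# a_px on an nr x nc periodic grid, so that a single complex inverse FFT
# yields both gradient components of the smoothed image.
#
# The kernels are sampled on the square support |dx|, |dy| <= 4a and are
# separable, so each 1D factor is alias-summed around the periodic
# domain; without the wrap summation, scales with 4a beyond half the
# image side would carry a spurious kernel discontinuity at the domain
# edge that contaminates large-scale maxima.
gradient_kernel_spectrum <- function(nr, nc, a_px, truncate = 4) {
  key <- sprintf("%d_%d_%.10g_%g", nr, nc, a_px, truncate)
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  h <- as.integer(ceiling(truncate * a_px))
  offs <- (-h):h
  g <- exp(-offs^2 / (2 * a_px^2))
  wrap_sum <- function(vals, n) {
    idx <- (offs %% n) + 1L
    out <- numeric(n)
    agg <- rowsum(vals, idx)
    out[as.integer(rownames(agg))] <- agg
    out
  }
  gy <- wrap_sum(g, nr)
  gx <- wrap_sum(g, nc)
  dgy <- wrap_sum(offs * g, nr)
  dgx <- wrap_sum(offs * g, nc)
  # k1 ~ d/dx, k2 ~ d/dy; sign chosen so the response is the ascending
  # gradient of the smoothed image (vectors point toward brighter pixels)
  norm <- 1 / (2 * pi * a_px^3)
  k1 <- outer(gy, dgx) * norm
  k2 <- outer(dgy, gx) * norm
  spec <- Conj(stats::fft(k1)) + 1i * Conj(stats::fft(k2))
  .kernel_cache[[key]] <- spec
  spec
}

#' Continuous 2D wavelet transform at one scale
#'
#' Computes the wavelet transform of an image with the two
#' first-derivative-of-Gaussian wavelets at scale `a`: the result is the
#' gradient vector field of the image smoothed by the Gaussian dilated to
#' that scale, with the `1/a^2` integral normalization applied so that
#' responses are comparable across scales.  Convolution is FFT-based with
#' periodic boundaries; kernels are truncated at `truncate * a` and their
#' spectra cached per image geometry and scale.
#'
#' @param image an [intensity_image()] (or bare matrix).
#' @param scale analyzing scale in microns; must resolve to at least
#'   2 px at the image's pixel size.
#' @param config a [wavelet_config()].
#' @return an object of class `wavelet_response` with elements `scale`
#'   (um), `scale_px`, `t1`, `t2` (gradient component matrices),
#'   `modulus`, `argument` (radians in (-pi, pi]) and `pixel_size`.
#' @export
continuous_wavelet_transform <- function(image, scale,
                                         config = wavelet_config()) {
  image <- as_intensity_image(image)
  px <- image$pixels
  if (nrow(px) < 16L || ncol(px) < 16L)
    stop("image must be at least 16x16 pixels")
  a_px <- scale / image$pixel_size
  if (a_px < 2)
    stop(sprintf(
      "degenerate scale: %.4g um is %.3g px at %.4g um/px (minimum 2 px)",
      scale, a_px, image$pixel_size))
  spec <- gradient_kernel_spectrum(nrow(px), ncol(px), a_px,
                                   config$truncate)
  tt <- fft_corr_pair(px, spec)
  t1 <- Re(tt)
  t2 <- Im(tt)
  structure(list(scale = scale, scale_px = a_px, t1 = t1, t2 = t2,
                 modulus = sqrt(t1^2 + t2^2),
                 argument = atan2(t2, t1),
                 pixel_size = image$pixel_size),
            class = "wavelet_response")
}

#' @export
print.wavelet_response <- function(x, ...) {
  cat(sprintf(
    "<wavelet_response> a = %.4g um (%.3g px), %d x %d, max modulus %.4g\n",
    x$scale, x$scale_px, nrow(x$modulus), ncol(x$modulus), max(x$modulus)))
  invisible(x)
}

#' Detect wavelet transform modulus maxima
#'
#' A pixel is a WTMM point when its modulus is locally maximal along the
#' direction of the argument: strictly greater than the bilinearly
#' interpolated modulus one pixel forward along the gradient unit vector
#' and no smaller than the value one pixel backward (the strict /
#' non-strict pair resolves plateau ties deterministically).  Maxima
#' within `border_factor * a` pixels of any edge, or with modulus below
#' `modulus_floor` times the response maximum, are discarded.
#'
#' @param response a `wavelet_response` from
#'   [continuous_wavelet_transform()].
#' @param config a [wavelet_config()].
#' @return an object of class `maxima_set`: a list with `scale` (um),
#'   `scale_px`, and `points`, a data frame with columns `row`, `col`
#'   (1-based pixel coordinates), `modulus` and `angle` (radians in
#'   (-pi, pi]).  An empty set (e.g. on a constant image) is valid.
#' @export
detect_maxima <- function(response, config = wavelet_config()) {
  if (!inherits(response, "wavelet_response"))
    stop("`response` must be a wavelet_response")
  nr <- nrow(response$modulus)
  cap <- floor(config$border_cap_frac * min(nr, ncol(response$modulus)))
  border <- max(2L, min(as.integer(ceiling(config$border_factor *
                                             response$scale_px)),
                        as.integer(cap)))
  floor_value <- config$modulus_floor * max(response$modulus)
  if (2L * border + 1L >= nr || 2L * border + 1L >= ncol(response$modulus)) {
    idx <- integer(0)
  } else {
    idx <- wtmm_points(response$modulus, response$argument, border,
                       floor_value)
  }
  pts <- data.frame(
    row = ((idx - 1L) %% nr) + 1L,
    col = ((idx - 1L) %/% nr) + 1L,
    modulus = response$modulus[idx],
    angle = response$argument[idx])
  structure(list(scale = response$scale, scale_px = response$scale_px,
                 points = pts, chains = NULL),
            class = "maxima_set")
}

#' @export
print.maxima_set <- function(x, ...) {
  cat(sprintf("<maxima_set> a = %.4g um: %d maxima%s\n", x$scale,
              nrow(x$points),
              if (is.null(x$chains)) "" else
                sprintf(" in %d chains", max(x$chains))))
  invisible(x)
}

#' Group maxima into edge-detection chains
#'
#' Partitions the WTMM points of one scale into connected contour groups
#' using 8-neighborhood connectivity on the pixel grid.  Singleton chains
#' are allowed.  Chain membership is stored in `$chains` (an integer
#' label per point) and mirrored into a `chain_id` column of `$points`.
#'
#' @param maxima a `maxima_set` from [detect_maxima()].
#' @return the same `maxima_set` with chain labels filled in.
#' @export
chain_maxima <- function(maxima) {
  if (!inherits(maxima, "maxima_set")) stop("`maxima` must be a maxima_set")
  pts <- maxima$points
  n <- nrow(pts)
  if (n == 0L) {
    maxima$chains <- integer(0)
    maxima$points$chain_id <- integer(0)
    return(maxima)
  }
  # union-find over the 4 backward 8-neighbors, located by hashed keys
  nr <- max(pts$row) + 1L
  key <- pts$row + nr * pts$col
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (off in list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L))) {
    nb <- match(key + off[1L] + nr * off[2L], key)
    hit <- which(!is.na(nb))
    for (i in hit) {
      ri <- find(i); rj <- find(nb[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))
  maxima$chains <- labels
  maxima$points$chain_id <- labels
  maxima
}

#' Write a maxima set as CSV
#'
#' Columns: `scale_um`, `row`, `col`, `modulus`, `angle_rad` and
#' `chain_id` (`NA` when [chain_maxima()] has not been run).  Pixel
#' coordinates are 0-based, row-major with the origin at the top-left
#' corner of the image.
#'
#' @param maxima a `maxima_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_maxima_csv <- function(maxima, path) {
  pts <- maxima$points
  out <- data.frame(
    scale_um = rep(maxima$scale, nrow(pts)),
    row = pts$row - 1L, col = pts$col - 1L,
    modulus = pts$modulus, angle_rad = pts$angle,
    chain_id = if (is.null(maxima$chains)) rep(NA_integer_, nrow(pts)) else
      maxima$chains - 1L)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
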