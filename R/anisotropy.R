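#' Angle probability density of a maxima set
#'
#' Bins the WTMM vector angles of one scale into `n_bins` equal bins over
#' (-pi, pi] and normalizes to a probability density (units 1/radian).
#' Angles enter unweighted by default, one count per maxima point; set
#' `weight_by_modulus = TRUE` to weight each angle by its gradient
#' modulus instead.
#'
#' @param maxima a `maxima_set` from [detect_maxima()]; must be nonempty.
#' @param n_bins number of histogram bins (>= 8, default 72, i.e. 5
#'   degree bins).
#' @param weight_by_modulus weight angles by modulus (default `FALSE`).
#' @return an object of class `angle_distribution`: list with `scale`
#'   (um), `bin_edges` (length `n_bins + 1`), `density` (length
#'   `n_bins`), `n_angles`.
#' @export
angle_pdf <- function(maxima, n_bins = 72L, weight_by_modulus = FALSE) {
  if (!inherits(maxima, "maxima_set")) stop("`maxima` must be a maxima_set")
  n_bins <- as.integer(n_bins)
  if (n_bins < 8L) stop("`n_bins` must be at least 8")
  angles <- maxima$points$angle
  if (length(angles) == 0L)
    stop("empty maxima set: the angle pdf (and hence Fa) is undefined")
  width <- 2 * pi / n_bins
  # atan2 yields (-pi, pi]; map exact -pi (possible for signed zeros) up
  angles[angles <= -pi] <- angles[angles <= -pi] + 2 * pi
  bin <- ceiling((angles + pi) / width)
  bin[bin < 1L] <- 1L
  bin[bin > n_bins] <- n_bins
  if (weight_by_modulus) {
    w <- maxima$points$modulus
    counts <- vapply(split(w, factor(bin, levels = seq_len(n_bins))), sum,
                     numeric(1))
    density <- counts / (sum(w) * width)
  } else {
    density <- tabulate(bin, nbins = n_bins) / (length(angles) * width)
  }
  structure(list(scale = maxima$scale,
                 bin_edges = seq(-pi, pi, length.out = n_bins + 1L),
                 density = as.numeric(density),
                 n_angles = length(angles)),
            class = "angle_distribution")
}

#' Construct an angle distribution from explicit bin densities
#'
#' Builds an `angle_distribution` over equal bins of (-pi, pi] directly
#' from per-bin density values (units 1/radian), e.g. to evaluate
#' [anisotropy_factor()] on analytic shapes such as the perfectly flat
#' isotropic density `1/(2 pi)`.
#'
#' @param density numeric vector of `n_bins` non-negative densities;
#'   must integrate to 1 over (-pi, pi].
#' @param scale optional scale annotation in microns.
#' @param n_angles optional count of contributing angles.
#' @return an `angle_distribution`.
#' @export
angle_distribution <- function(density, scale = NA_real_,
                               n_angles = NA_integer_) {
  n <- length(density)
  if (n < 8L) stop("need at least 8 bins")
  if (any(density < 0)) stop("densities must be non-negative")
  width <- 2 * pi / n
  if (abs(sum(density * width) - 1) > 1e-8)
    stop(sprintf("density must integrate to 1 (got %.6g)",
                 sum(density * width)))
  structure(list(scale = scale,
                 bin_edges = seq(-pi, pi, length.out = n + 1L),
                 density = as.numeric(density),
                 n_angles = n_angles),
            class = "angle_distribution")
}

#' @export
print.angle_distribution <- function(x, ...) {
  cat(sprintf(
    "<angle_distribution> a = %.4g um, %d bins, n = %d, Fa = %.4f\n",
    x$scale, length(x$density), x$n_angles, anisotropy_factor(x)))
  invisible(x)
}

#' Anisotropy factor of an angle distribution
#'
#' The anisotropy factor Fa is the L1 distance between the observed angle
#' density and the flat isotropic density 1/(2 pi):
#' `Fa = integral over (-pi, pi] of |P(A) - 1/(2 pi)| dA`.
#' Since the binned density is piecewise constant the integral is the
#' exact Riemann sum over bins.  Fa = 0 for a perfectly flat pdf
#' (isotropy); the supremum 2 is approached as all mass concentrates in a
#' vanishingly narrow bin.
#'
#' @param pdf an `angle_distribution` from [angle_pdf()].
#' @return Fa, a dimensionless value in `[0, 2]`.
#' @export
anisotropy_factor <- function(pdf) {
  if (!inherits(pdf, "angle_distribution"))
    stop("`pdf` must be an angle_distribution")
  width <- diff(pdf$bin_edges)
  total <- sum(pdf$density * width)
  if (abs(total - 1) > 1e-8)
    stop(sprintf("pdf is not normalized (integral = %.6g)", total))
  sum(abs(pdf$density - 1 / (2 * pi)) * width)
}

#' Multiscale anisotropy profile of an image
#'
#' Runs the full per-image pipeline -- wavelet transform, maxima
#' detection, angle pdf, anisotropy factor -- at every scale of the
#' configuration.  Scales at which no maxima survive border exclusion
#' and the modulus floor are reported as `NA` (missing), not zero.
#'
#' @param image an [intensity_image()] (or bare matrix).
#' @param config a [wavelet_config()]; its `scales` and `n_bins` drive
#'   the profile.
#' @param label identifier attached to the profile (default "").
#' @return an object of class `anisotropy_profile`: list with `scales`
#'   (um), `fa`, `n_maxima`, `label`.
#' @export
multiscale_profile <- function(image, config = wavelet_config(),
                               label = "") {
  image <- as_intensity_image(image)
  n <- length(config$scales)
  fa <- rep(NA_real_, n)
  n_max <- integer(n)
  for (i in seq_len(n)) {
    a <- config$scales[i]
    resp <- tryCatch(continuous_wavelet_transform(image, a, config),
                     error = function(e) NULL)
    if (is.null(resp)) {
      warning(sprintf("scale %.4g um skipped: not resolvable", a))
      next
    }
    mx <- detect_maxima(resp, config)
    n_max[i] <- nrow(mx$points)
    if (n_max[i] > 0L)
      fa[i] <- anisotropy_factor(angle_pdf(mx, config$n_bins))
    else
      warning(sprintf("scale %.4g um: no maxima after border exclusion", a))
  }
  structure(list(scales = config$scales, fa = fa, n_maxima = n_max,
                 label = label),
            class = "anisotropy_profile")
}

#' @export
print.anisotropy_profile <- function(x, ...) {
  cat(sprintf("<anisotropy_profile> %s%d scales, %.4g - %.4g um\n",
              if (nzchar(x$label)) paste0(x$label, ": ") else "",
              length(x$scales), min(x$scales), max(x$scales)))
  print(data.frame(scale_um = signif(x$scales, 4), fa = signif(x$fa, 4),
                   n_maxima = x$n_maxima), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.anisotropy_profile <- function(x, ...) {
  data.frame(label = x$label, scale_um = x$scales, fa = x$fa,
             n_maxima = x$n_maxima)
}

#' Normalize cohort profiles by a control group
#'
#' Divides the per-scale median anisotropy factor of a cohort by that of
#' a control cohort, giving a relative multiscale signature (ratio 1 at a
#' scale means the cohort is indistinguishable from control there).
#' Medians ignore images whose Fa is missing at a scale.
#'
#' @param cohort list of `anisotropy_profile` objects.
#' @param control list of `anisotropy_profile` objects sharing the same
#'   scale ladder.
#' @param label label for the returned ratio profile.
#' @return an `anisotropy_profile` whose `fa` holds the per-scale
#'   median ratio.
#' @export
normalize_profiles <- function(cohort, control, label = "normalized") {
  med <- function(profiles) {
    scales <- profiles[[1L]]$scales
    for (p in profiles)
      if (length(p$scales) != length(scales) ||
          any(abs(p$scales - scales) > 1e-9))
        stop("profiles do not share a common scale ladder")
    list(scales = scales,
         m = apply(do.call(rbind, lapply(profiles, `[[`, "fa")), 2,
                   stats::median, na.rm = TRUE))
  }
  a <- med(cohort)
  b <- med(control)
  if (length(a$scales) != length(b$scales) ||
      any(abs(a$scales - b$scales) > 1e-9))
    stop("cohort and control do not share a common scale ladder")
  if (any(!is.finite(b$m)) || any(b$m <= 0))
    stop("control median Fa must be positive at every scale")
  structure(list(scales = a$scales, fa = a$m / b$m,
                 n_maxima = rep(NA_integer_, length(a$scales)),
                 label = label),
            class = "anisotropy_profile")
}

#' Write per-image multiscale results as tidy CSV
#'
#' One row per image and scale with columns `image_id`, `scale_um`,
#' `n_maxima`, `fa`.
#'
#' @param profiles list of `anisotropy_profile` objects (labels become
#'   `image_id`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(image_id = p$label, scale_um = p$scales,
               n_maxima = p$n_maxima, fa = p$fa)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Summarize a cohort of profiles per scale
#'
#' @param profiles list of `anisotropy_profile` objects on one ladder.
#' @return data frame with `scale_um`, `median_fa`, `q1`, `q3`,
#'   `n_images` (images with a defined Fa at that scale).
#' @export
summarize_profiles <- function(profiles) {
  scales <- profiles[[1L]]$scales
  mat <- do.call(rbind, lapply(profiles, `[[`, "fa"))
  data.frame(
    scale_um = scales,
    median_fa = apply(mat, 2, stats::median, na.rm = TRUE),
    q1 = apply(mat, 2, stats::quantile, probs = 0.25, na.rm = TRUE,
               names = FALSE),
    q3 = apply(mat, 2, stats::quantile, probs = 0.75, na.rm = TRUE,
               names = FALSE),
    n_images = colSums(!is.na(mat)))
}
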