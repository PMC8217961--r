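#' Synthetic fiber image configuration
#'
#' Parameters of the calibration phantom: straight fibers drawn as
#' anti-aliased rectangles with centers uniform over the full frame
#' (fibers may be clipped at the border), lengths uniform in
#' `length_range_um`, and orientations uniform in `angle_range_deg`.
#' An angle of 90 degrees is a vertical fiber (angles are measured from
#' the image x axis), so the narrow range `c(85, 95)` is the most
#' aligned, near-vertical group.  Fibers may intersect; overlaps
#' composite by maximum.  After rendering, the image is degraded by a
#' pillbox blur followed by a linear motion blur (see [degrade()]).
#'
#' @param n_fibers number of fibers (default 50).
#' @param diameter_um fiber diameter in microns (calibration uses 2, 4,
#'   6 or 8).
#' @param length_range_um fiber length range in microns (default
#'   `c(40, 60)`).
#' @param angle_range_deg orientation range `c(theta_min, theta_max)` in
#'   degrees, `0 <= theta_min <= theta_max <= 180`.  Equal bounds give
#'   perfectly parallel fibers.
#' @param image_px image side length in pixels (default 512).
#' @param fov_um field of view in microns (default 180).
#' @param foreground,background fiber and background intensities
#'   (defaults 255 and 0; downstream anisotropy is invariant to this
#'   choice).
#' @param blur_radius_px radius of the circular averaging filter
#'   (default 3).
#' @param motion_len_px length of the linear motion-blur kernel
#'   (default 5); its direction is drawn uniformly per image.
#' @param seed integer seed making the image reproducible; `NULL` uses
#'   the current RNG state.
#' @return an object of class `fiber_sim_config`.
#' @export
fiber_sim_config <- function(n_fibers = 50L, diameter_um = 2,
                             length_range_um = c(40, 60),
                             angle_range_deg = c(0, 180),
                             image_px = 512L, fov_um = 180,
                             foreground = 255, background = 0,
                             blur_radius_px = 3, motion_len_px = 5,
                             seed = NULL) {
  if (diameter_um <= 0) stop("`diameter_um` must be positive")
  if (length(length_range_um) != 2L || any(length_range_um <= 0) ||
      length_range_um[1L] > length_range_um[2L])
    stop("`length_range_um` must be positive and ordered")
  if (length(angle_range_deg) != 2L || angle_range_deg[1L] < 0 ||
      angle_range_deg[2L] > 180 ||
      angle_range_deg[1L] > angle_range_deg[2L])
    stop("`angle_range_deg` must satisfy 0 <= min <= max <= 180")
  if (n_fibers < 0L) stop("`n_fibers` must be >= 0")
  structure(list(n_fibers = as.integer(n_fibers),
                 diameter_um = diameter_um,
                 length_range_um = length_range_um,
                 angle_range_deg = angle_range_deg,
                 image_px = as.integer(image_px), fov_um = fov_um,
                 foreground = foreground, background = background,
                 blur_radius_px = blur_radius_px,
                 motion_len_px = motion_len_px, seed = seed),
            class = "fiber_sim_config")
}

#' Simulate a synthetic fiber image
#'
#' Renders `n_fibers` anti-aliased rectangles per the configuration and
#' applies the degradation pipeline (pillbox blur then motion blur).
#' The per-fiber ground truth (angle, length, center) and the motion
#' direction are attached as attributes `"fibers"` and
#' `"motion_angle_deg"`; a fixed seed gives a bit-identical image.
#'
#' @param config a [fiber_sim_config()].
#' @param degrade_image apply the blur + motion degradation (default
#'   `TRUE`).
#' @return an [intensity_image()] with ground-truth attributes.
#' @export
simulate_fiber_image <- function(config = fiber_sim_config(),
                                 degrade_image = TRUE) {
  if (!inherits(config, "fiber_sim_config"))
    stop("`config` must be a fiber_sim_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_fibers
  px_size <- config$fov_um / config$image_px
  npx <- config$image_px
  if (n > 0L) {
    cx <- runif(n, 0.5, npx + 0.5)
    cy <- runif(n, 0.5, npx + 0.5)
    theta_deg <- runif(n, config$angle_range_deg[1L],
                       config$angle_range_deg[2L])
    len_um <- runif(n, config$length_range_um[1L],
                    config$length_range_um[2L])
    canvas <- render_fibers(npx, npx, cx, cy, theta_deg * pi / 180,
                            len_um / px_size,
                            rep(config$diameter_um / px_size, n),
                            config$foreground - config$background)
    fibers <- data.frame(angle_deg = theta_deg, length_um = len_um,
                         center_row = cy, center_col = cx)
  } else {
    canvas <- matrix(0, npx, npx)
    fibers <- data.frame(angle_deg = numeric(0), length_um = numeric(0),
                         center_row = numeric(0), center_col = numeric(0))
  }
  canvas <- canvas + config$background
  motion_angle <- runif(1, 0, 180)
  img <- intensity_image(canvas, px_size)
  if (degrade_image)
    img <- degrade(img, config, motion_angle_deg = motion_angle)
  attr(img, "fibers") <- fibers
  attr(img, "motion_angle_deg") <- motion_angle
  img
}

#' Pillbox (circular averaging) kernel
#'
#' Uniform disk kernel of the given radius with fractional pixel
#' coverage at the rim (16x16 subpixel sampling), normalized to sum to
#' exactly 1.
#'
#' @param radius_px disk radius in pixels (>= 1).
#' @return a square numeric matrix of odd side length.
#' @export
pillbox_kernel <- function(radius_px = 3) {
  if (radius_px < 1) stop("`radius_px` must be >= 1")
  h <- ceiling(radius_px)
  d <- seq(-h, h)
  sub <- (seq_len(16) - 8.5) / 16
  cover <- outer(d, d, function(x, y) {
    vapply(seq_along(x), function(i) {
      mean(outer(x[i] + sub, y[i] + sub,
                 function(a, b) a^2 + b^2 <= radius_px^2))
    }, numeric(1))
  })
  cover / sum(cover)
}

#' Linear motion-blur kernel
#'
#' `len_px` unit-spaced points along a line through the kernel center at
#' the given angle, deposited with bilinear weights and normalized to
#' sum to exactly 1.
#'
#' @param len_px motion length in pixels (>= 1).
#' @param angle_deg motion direction in degrees from the x axis.
#' @return a square numeric matrix of odd side length.
#' @export
motion_kernel <- function(len_px = 5, angle_deg = 0) {
  if (len_px < 1) stop("`len_px` must be >= 1")
  t <- seq(-(len_px - 1) / 2, (len_px - 1) / 2, length.out = len_px)
  a <- angle_deg * pi / 180
  x <- t * cos(a)
  y <- t * sin(a)
  h <- max(1L, ceiling(max(abs(c(x, y)))))
  side <- 2L * h + 1L
  k <- matrix(0, side, side)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  add <- function(r, cc, w) if (w > 0) k[r, cc] <<- k[r, cc] + w
  for (i in seq_along(t)) {
    r <- y0[i] + h + 1L; cc <- x0[i] + h + 1L
    add(r, cc, (1 - fy[i]) * (1 - fx[i]))
    add(r, cc + 1L, (1 - fy[i]) * fx[i])
    add(r + 1L, cc, fy[i] * (1 - fx[i]))
    add(r + 1L, cc + 1L, fy[i] * fx[i])
  }
  k / sum(k)
}

#' Degrade an image with pillbox and motion blur
#'
#' Applies the normalized circular averaging filter of radius
#' `blur_radius_px` followed by a normalized linear motion-blur kernel
#' of length `motion_len_px`.  Convolution replicates edge pixels, so a
#' constant image passes through unchanged and the image mean is
#' preserved up to boundary effects.
#'
#' @param image an [intensity_image()] (or bare matrix).
#' @param config a [fiber_sim_config()] providing the kernel sizes.
#' @param motion_angle_deg motion direction; drawn uniformly from
#'   `[0, 180)` when `NULL`.
#' @return the degraded [intensity_image()].
#' @export
degrade <- function(image, config = fiber_sim_config(),
                    motion_angle_deg = NULL) {
  image <- as_intensity_image(image)
  if (is.null(motion_angle_deg)) motion_angle_deg <- runif(1, 0, 180)
  out <- conv2_replicate(image$pixels,
                         pillbox_kernel(config$blur_radius_px))
  if (config$motion_len_px > 1)
    out <- conv2_replicate(out, motion_kernel(config$motion_len_px,
                                              motion_angle_deg))
  intensity_image(out, image$pixel_size)
}

#' Add non-negative white noise at a multiple of the image mean
#'
#' Adds an independent pixelwise uniform white-noise field on
#' `[0, 2 k mu]`, where `mu` is the mean intensity of the input, so the
#' added noise has mean `k * mu` (e.g. `multiple = 20` on an image of
#' mean 100 adds noise of mean 2000).  `multiple = 0` returns the image
#' unchanged.
#'
#' @param image an [intensity_image()] (or bare matrix).
#' @param multiple noise mean as a multiple of the image mean (the
#'   robustness experiment uses 1, 2, 5, 10, 20).
#' @param seed optional integer seed for the noise field.
#' @return the noisy [intensity_image()].
#' @export
add_white_noise <- function(image, multiple, seed = NULL) {
  image <- as_intensity_image(image)
  if (multiple < 0) stop("`multiple` must be >= 0")
  if (multiple == 0) return(image)
  mu <- mean(image$pixels)
  if (mu <= 0)
    stop("image mean is not positive; noise target mean is undefined")
  if (!is.null(seed)) set.seed(seed)
  noise <- matrix(runif(length(image$pixels), 0, 2 * multiple * mu),
                  nrow(image$pixels))
  intensity_image(image$pixels + noise, image$pixel_size)
}

#' Pure white-noise image
#'
#' Pixelwise uniform noise on `[0, 2 * mean_value]` (mean `mean_value`),
#' the isotropic reference field of the noise-robustness experiment.
#'
#' @param mean_value target mean intensity (default 100).
#' @param image_px side length in pixels (default 512).
#' @param pixel_size um/px (default 180/512).
#' @param seed optional integer seed.
#' @return an [intensity_image()].
#' @export
simulate_noise_image <- function(mean_value = 100, image_px = 512L,
                                 pixel_size = 180 / 512, seed = NULL) {
  if (mean_value <= 0) stop("`mean_value` must be positive")
  if (!is.null(seed)) set.seed(seed)
  intensity_image(matrix(runif(image_px^2, 0, 2 * mean_value), image_px),
                  pixel_size)
}

#' The 19 calibration angle ranges
#'
#' Nested ranges centered on 90 degrees, from perfectly parallel
#' vertical fibers `[90, 90]` through the most aligned sampled range
#' `[85, 95]` to the fully unaligned `[0, 180]`, in 5 degree increments
#' of the half-width.  19 ranges give the 18 consecutive pairs of the
#' sensitivity analysis and, with 4 diameters and 100 images per cell,
#' the 7600-image calibration design.
#'
#' @return data frame with columns `theta_min`, `theta_max` (degrees),
#'   ordered from narrowest to widest.
#' @export
calibration_angle_ranges <- function() {
  hw <- seq(0, 90, by = 5)
  data.frame(theta_min = 90 - hw, theta_max = 90 + hw)
}

# Deterministic per-image seed stream below 2^31, derived from a master
# seed; 104729 is prime and coprime to 2^31 - 1, so seeds are distinct
# within any design of realistic size.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) + 104729 * as.numeric(index)) %%
               2147483647)
}

#' Generate the calibration design manifest (and optionally its images)
#'
#' Builds the full factorial design of the calibration study --
#' `diameters` x `angle_ranges` x `n_per_cell` images, the default being
#' the 4 x 19 x 100 = 7600-image set -- with a deterministic per-image
#' seed derived from the master seed.  With `dir = NULL` only the
#' manifest is returned (images are simulated on demand from their
#' manifest row via [simulate_manifest_image()]); with a directory,
#' 16-bit TIFFs, a per-image manifest CSV, a per-fiber ground-truth CSV
#' and a YAML copy of the design are written.
#'
#' @param diameters fiber diameters in microns (default `c(2, 4, 6, 8)`).
#' @param angle_ranges data frame with `theta_min`, `theta_max` columns
#'   (default [calibration_angle_ranges()]).
#' @param n_per_cell images per diameter x range cell (default 100).
#' @param seed master seed (default 1).
#' @param dir output directory, or `NULL` for a manifest-only run.
#' @param force overwrite an existing non-empty output directory.
#' @param ... further arguments passed to [fiber_sim_config()].
#' @return the manifest data frame (columns `image_id`, `seed`,
#'   `diameter_um`, `theta_min`, `theta_max`), invisibly when writing.
#' @export
generate_calibration_set <- function(diameters = c(2, 4, 6, 8),
                                     angle_ranges =
                                       calibration_angle_ranges(),
                                     n_per_cell = 100L, seed = 1L,
                                     dir = NULL, force = FALSE, ...) {
  if (n_per_cell < 1L) stop("`n_per_cell` must be >= 1")
  design <- expand.grid(i = seq_len(n_per_cell),
                        range_idx = seq_len(nrow(angle_ranges)),
                        diameter_um = diameters)
  manifest <- data.frame(
    image_id = sprintf("d%g_r%02d_i%03d", design$diameter_um,
                       design$range_idx, design$i),
    seed = derive_seed(seed, seq_len(nrow(design))),
    diameter_um = design$diameter_um,
    theta_min = angle_ranges$theta_min[design$range_idx],
    theta_max = angle_ranges$theta_max[design$range_idx])
  if (is.null(dir)) return(manifest)
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force)
    stop("output directory ", dir, " is not empty; use force = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fiber_rows <- vector("list", nrow(manifest))
  for (k in seq_len(nrow(manifest))) {
    img <- simulate_manifest_image(manifest[k, ], ...)
    write_image_tiff(img, file.path(dir,
                                    paste0(manifest$image_id[k], ".tif")))
    fb <- attr(img, "fibers")
    fiber_rows[[k]] <- cbind(image_id = manifest$image_id[k], fb)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, fiber_rows),
                   file.path(dir, "fibers.csv"), row.names = FALSE)
  yaml::write_yaml(list(diameters = diameters,
                        n_per_cell = as.integer(n_per_cell),
                        master_seed = as.integer(seed),
                        n_images = nrow(manifest)),
                   file.path(dir, "design.yaml"))
  invisible(manifest)
}

#' Simulate one image from a manifest row
#'
#' @param row one row of a [generate_calibration_set()] manifest.
#' @param ... overrides passed to [fiber_sim_config()].
#' @return an [intensity_image()] with ground-truth attributes.
#' @export
simulate_manifest_image <- function(row, ...) {
  cfg <- fiber_sim_config(diameter_um = row$diameter_um,
                          angle_range_deg = c(row$theta_min,
                                              row$theta_max),
                          seed = row$seed, ...)
  simulate_fiber_image(cfg)
}
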