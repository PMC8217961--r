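test_that("fiber-free config yields a uniform background", {
  img <- simulate_fiber_image(fiber_sim_config(n_fibers = 0, seed = 1,
                                               image_px = 64, fov_um = 64,
                                               background = 10))
  expect_equal(max(abs(img$pixels - 10)), 0)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- fiber_sim_config(seed = 77, angle_range_deg = c(30, 150))
  a <- simulate_fiber_image(cfg)
  b <- simulate_fiber_image(cfg)
  expect_identical(a$pixels, b$pixels)
  expect_identical(attr(a, "fibers"), attr(b, "fibers"))
})

test_that("ground-truth fiber angles are uniform over the requested range", {
  angles <- numeric(0)
  for (i in 1:20) {
    img <- simulate_fiber_image(fiber_sim_config(
      seed = 1000 + i, angle_range_deg = c(30, 150)),
      degrade_image = FALSE)
    angles <- c(angles, attr(img, "fibers")$angle_deg)
  }
  expect_identical(length(angles), 1000L)
  expect_true(all(angles >= 30 & angles <= 150))
  ks <- suppressWarnings(ks.test(angles, "punif", 30, 150))
  expect_gt(ks$p.value, 0.01)
})

test_that("degradation kernels are normalized and shaped correctly", {
  pk <- pillbox_kernel(3)
  expect_equal(sum(pk), 1, tolerance = 1e-15)
  expect_identical(dim(pk), c(7L, 7L))
  # center of the disk is interior, corners are outside radius 3
  expect_gt(pk[4, 4], 0)
  expect_identical(pk[1, 1], 0)
  for (ang in c(0, 30, 90, 117)) {
    mk <- motion_kernel(5, ang)
    expect_equal(sum(mk), 1, tolerance = 1e-15)
  }
  # horizontal motion kernel is a single row of 5 equal taps
  mk0 <- motion_kernel(5, 0)
  expect_equal(max(mk0), 1 / 5, tolerance = 1e-12)
})

test_that("an impulse spreads into the pillbox footprint before motion", {
  px <- matrix(0, 33, 33); px[17, 17] <- 1
  cfg <- fiber_sim_config(motion_len_px = 1)
  out <- degrade(intensity_image(px, 1), cfg, motion_angle_deg = 0)
  expect_equal(sum(out$pixels), 1, tolerance = 1e-12)
  on <- which(out$pixels > 0, arr.ind = TRUE)
  d <- sqrt((on[, 1] - 17)^2 + (on[, 2] - 17)^2)
  expect_lte(max(d), 3 + 0.75)   # fractional rim pixels allowed
  expect_gte(max(d), 2.5)
})

test_that("degradation preserves constants and matches a direct oracle", {
  cfg <- fiber_sim_config()
  const <- degrade(intensity_image(matrix(4.2, 40, 40), 1), cfg,
                   motion_angle_deg = 33)
  expect_equal(max(abs(const$pixels - 4.2)), 0, tolerance = 1e-12)
  # step edge: compare against an explicit replicate-padded convolution
  img <- step_image(40)
  out <- degrade(img, cfg, motion_angle_deg = 25)
  k <- pillbox_kernel(3)
  m <- motion_kernel(5, 25)
  direct <- function(px, kern) {
    h <- (nrow(kern) - 1) / 2
    res <- matrix(0, nrow(px), ncol(px))
    for (dr in -h:h) for (dc in -h:h) {
      w <- kern[dr + h + 1, dc + h + 1]
      if (w == 0) next
      rows <- pmin(pmax(seq_len(nrow(px)) + dr, 1), nrow(px))
      cols <- pmin(pmax(seq_len(ncol(px)) + dc, 1), ncol(px))
      res <- res + w * px[rows, cols]
    }
    res
  }
  expect_equal(out$pixels, direct(direct(img$pixels, k), m),
               tolerance = 1e-12)
  # the 10-90% edge width must widen relative to the sharp input
  mid <- colMeans(out$pixels[15:25, ])
  width_out <- sum(mid > 0.1 & mid < 0.9)
  expect_gte(width_out, 4)
})

test_that("white noise adds the requested multiple of the image mean", {
  img <- intensity_image(matrix(100, 512, 512), 1)
  expect_identical(add_white_noise(img, 0)$pixels, img$pixels)
  noisy <- add_white_noise(img, 20, seed = 9)
  expect_equal(mean(noisy$pixels), 2100, tolerance = 0.01 * 2100)
  expect_gte(min(noisy$pixels), 100)  # noise field is non-negative
  expect_error(add_white_noise(intensity_image(matrix(0, 16, 16), 1), 2),
               "mean")
  # reproducible field
  expect_identical(add_white_noise(img, 5, seed = 4)$pixels,
                   add_white_noise(img, 5, seed = 4)$pixels)
})

test_that("pure white noise is near-isotropic at well-sampled scales", {
  img <- simulate_noise_image(seed = 5)
  # dense maxima at small scales: Fa sits at its finite-sample floor
  expect_lt(fa_at_scale(img, key_scales()[1]), 0.15)
  expect_lt(fa_at_scale(img, key_scales()[2]), 0.25)
})

test_that("calibration manifest enumerates the full factorial design", {
  m <- generate_calibration_set()
  expect_identical(nrow(m), 7600L)
  expect_identical(length(unique(m$image_id)), 7600L)
  expect_identical(nrow(calibration_angle_ranges()), 19L)
  small <- generate_calibration_set(diameters = 4,
                                    angle_ranges = data.frame(
                                      theta_min = c(85, 0),
                                      theta_max = c(95, 180)),
                                    n_per_cell = 3, seed = 2)
  expect_identical(nrow(small), 6L)
  expect_identical(small, generate_calibration_set(
    diameters = 4,
    angle_ranges = data.frame(theta_min = c(85, 0),
                              theta_max = c(95, 180)),
    n_per_cell = 3, seed = 2))
})

test_that("writing a calibration set produces images and refuses overwrite", {
  dir <- withr::local_tempdir()
  m <- generate_calibration_set(diameters = 2,
                                angle_ranges = data.frame(theta_min = 85,
                                                          theta_max = 95),
                                n_per_cell = 2, seed = 3, dir = dir,
                                image_px = 64L, fov_um = 22.5)
  expect_setequal(list.files(dir, pattern = "\\.tif$"),
                  paste0(m$image_id, ".tif"))
  fib <- read.csv(file.path(dir, "fibers.csv"))
  expect_identical(nrow(fib), 2L * 50L)
  expect_error(generate_calibration_set(diameters = 2,
                                        angle_ranges = data.frame(
                                          theta_min = 85, theta_max = 95),
                                        n_per_cell = 2, seed = 3, dir = dir),
               "force")
})

test_that("TIFF round trip preserves intensities and pixel size", {
  img <- simulate_fiber_image(fiber_sim_config(seed = 31, image_px = 64,
                                               fov_um = 22.5))
  path <- file.path(withr::local_tempdir(), "img.tif")
  write_image_tiff(img, path)
  back <- read_intensity_image(path)
  expect_equal(back$pixel_size, img$pixel_size, tolerance = 1e-9)
  expect_lt(max(abs(back$pixels - img$pixels)), 0.51)  # 16-bit quantization
  # explicit pixel_size overrides the sidecar
  expect_equal(read_intensity_image(path, pixel_size = 2)$pixel_size, 2)
})
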