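test_that("FFT transform matches the brute-force spatial oracle", {
  set.seed(42)
  px <- matrix(runif(64 * 64), 64)
  img <- intensity_image(px, 1)
  for (a in c(4, 5.5, 7)) {
    resp <- continuous_wavelet_transform(img, a, wavelet_config(scales = a))
    orc <- oracle_gradient_cwt(px, a)
    h <- ceiling(4 * a)
    inner <- (h + 1):(64 - h)
    scale_ref <- max(abs(orc$t1[inner, inner]))
    expect_lt(max(abs(resp$t1[inner, inner] - orc$t1[inner, inner])),
              1e-6 * scale_ref)
    expect_lt(max(abs(resp$t2[inner, inner] - orc$t2[inner, inner])),
              1e-6 * scale_ref)
  }
})

test_that("constant image has zero modulus and a valid empty maxima set", {
  img <- intensity_image(matrix(5.5, 48, 48), 1)
  cfg <- wavelet_config(scales = 4)
  resp <- continuous_wavelet_transform(img, 4, cfg)
  expect_equal(max(resp$modulus), 0)
  mx <- detect_maxima(resp, cfg)
  expect_s3_class(mx, "maxima_set")
  expect_identical(nrow(mx$points), 0L)
  expect_error(angle_pdf(mx), "empty")
})

test_that("ramp image gives constant interior modulus and zero argument", {
  a <- 5
  resp <- continuous_wavelet_transform(ramp_image(64), a,
                                       wavelet_config(scales = a))
  ctr <- 28:36
  expect_lt(max(abs(resp$argument[ctr, ctr])), 1e-12)
  # unit slope: scale-normalized gradient modulus approaches a
  expect_equal(unname(resp$modulus[32, 32]), a, tolerance = 0.01)
  expect_lt(diff(range(resp$modulus[ctr, ctr])), 1e-9)
})

test_that("intensity scaling and offsets transform the response correctly", {
  set.seed(7)
  px <- matrix(runif(48 * 48), 48)
  cfg <- wavelet_config(scales = 4)
  base <- continuous_wavelet_transform(intensity_image(px, 1), 4, cfg)
  lam <- 3.7
  scaled <- continuous_wavelet_transform(intensity_image(lam * px, 1), 4, cfg)
  expect_equal(scaled$modulus, lam * base$modulus, tolerance = 1e-12)
  expect_equal(scaled$argument, base$argument, tolerance = 1e-9)
  offset <- continuous_wavelet_transform(intensity_image(px + 11, 1), 4, cfg)
  expect_equal(offset$t1, base$t1, tolerance = 1e-8)
  expect_equal(offset$t2, base$t2, tolerance = 1e-8)
  mx_base <- detect_maxima(base, cfg)
  mx_scaled <- detect_maxima(scaled, cfg)
  expect_identical(mx_base$points[c("row", "col")],
                   mx_scaled$points[c("row", "col")])
})

test_that("vertical step edge yields one column of maxima pointing +x", {
  cfg <- wavelet_config(scales = 4)
  resp <- continuous_wavelet_transform(step_image(64), 4, cfg)
  mx <- detect_maxima(resp, cfg)
  expect_gt(nrow(mx$points), 0)
  expect_identical(unique(mx$points$col), 33L)
  expect_lt(max(abs(mx$points$angle)), 1e-9)
  ch <- chain_maxima(mx)
  expect_identical(max(ch$chains), 1L)
})

test_that("Gaussian bump maxima form a ring with inward radial angles", {
  sigma <- 6; a <- 5
  cfg <- wavelet_config(scales = a)
  resp <- continuous_wavelet_transform(bump_image(96, sigma), a, cfg)
  mx <- detect_maxima(resp, cfg)
  expect_gt(nrow(mx$points), 20)
  ctr <- (96 + 1) / 2
  r <- sqrt((mx$points$row - ctr)^2 + (mx$points$col - ctr)^2)
  # smoothing a Gaussian of width sigma with a Gaussian of width a gives
  # width sqrt(sigma^2 + a^2); the gradient modulus peaks at that radius
  expect_equal(median(r), sqrt(sigma^2 + a^2), tolerance = 0.1)
  # ascending gradient points toward the bump center
  inward <- atan2(ctr - mx$points$row, ctr - mx$points$col)
  dev <- abs(Arg(exp(1i * (mx$points$angle - inward))))
  expect_lt(max(dev), 0.15)
})

test_that("90-degree rotation permutes maxima and shifts angles by pi/2", {
  img <- simulate_fiber_image(fiber_sim_config(
    seed = 21, n_fibers = 12, image_px = 160, fov_um = 160,
    angle_range_deg = c(80, 100), length_range_um = c(30, 50),
    diameter_um = 4))
  cfg <- wavelet_config(scales = 5)
  rot <- intensity_image(t(img$pixels)[nrow(img$pixels):1, ],
                         img$pixel_size)
  mx <- detect_maxima(continuous_wavelet_transform(img, 5, cfg), cfg)
  mxr <- detect_maxima(continuous_wavelet_transform(rot, 5, cfg), cfg)
  expect_equal(nrow(mx$points), nrow(mxr$points), tolerance = 0.02)
  fa <- anisotropy_factor(angle_pdf(mx, 72))
  far <- anisotropy_factor(angle_pdf(mxr, 72))
  # pi/2 is a whole number of 5-degree bins, so Fa shifts bins exactly
  expect_equal(fa, far, tolerance = 0.02)
})

test_that("chaining partitions points and separates distant contours", {
  # two distant parallel fibers -> >= 2 chains, conservation of points
  cfg0 <- fiber_sim_config(n_fibers = 0, image_px = 128, fov_um = 128,
                           seed = 1, motion_len_px = 1)
  px <- matrix(0, 128, 128)
  px[20:108, 30:34] <- 255
  px[20:108, 90:94] <- 255
  img <- degrade(intensity_image(px, 1), cfg0, motion_angle_deg = 0)
  cfg <- wavelet_config(scales = 4)
  mx <- detect_maxima(continuous_wavelet_transform(img, 4, cfg), cfg)
  ch <- chain_maxima(mx)
  expect_gte(max(ch$chains), 2)
  expect_identical(length(ch$chains), nrow(mx$points))
  # chains partition: labels contiguous and every point labelled
  expect_setequal(unique(ch$chains), seq_len(max(ch$chains)))
})

test_that("degenerate scales and invalid pixels are rejected", {
  img <- intensity_image(matrix(runif(256), 16), pixel_size = 1)
  expect_error(continuous_wavelet_transform(img, 1.5,
                                            wavelet_config(scales = 1.5)),
               "degenerate")
  expect_error(intensity_image(matrix(c(NA, runif(255)), 16)), "finite")
  expect_error(intensity_image(matrix(1, 4, 4), pixel_size = -1),
               "positive")
  expect_error(wavelet_config(scales = c(3, 2)), "increasing")
})

test_that("maxima CSV export writes 0-based coordinates", {
  cfg <- wavelet_config(scales = 4)
  mx <- detect_maxima(continuous_wavelet_transform(step_image(64), 4, cfg),
                      cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_maxima_csv(chain_maxima(mx), path)
  out <- read.csv(path)
  expect_named(out, c("scale_um", "row", "col", "modulus", "angle_rad",
                      "chain_id"))
  expect_identical(unique(out$col), 32L)
  expect_identical(unique(out$chain_id), 0L)
})
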