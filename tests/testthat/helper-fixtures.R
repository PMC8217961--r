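# Fixture builders shared across test files.  All images are generated
# in code; pixel_size = 1 um/px unless physical units matter.

# f(x = col, y = row) = col: a unit ramp along +x (column-major fill
# makes column j constant at j)
ramp_image <- function(n = 64) {
  intensity_image(matrix(rep(seq_len(n), each = n), n), 1)
}

# left half 0, right half 1, step between columns n/2 and n/2 + 1
step_image <- function(n = 64) {
  px <- matrix(0, n, n)
  px[, (n / 2 + 1):n] <- 1
  intensity_image(px, 1)
}

# isotropic Gaussian bump of width sigma centered mid-image
bump_image <- function(n = 96, sigma = 6) {
  ctr <- (n + 1) / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
  intensity_image(exp(-d2 / (2 * sigma^2)), 1)
}

# brute-force spatial cross-correlation with sampled derivative-of-
# Gaussian kernels: the independent oracle for the FFT transform path.
# Offsets d run over the truncated square support; T(b) = sum k(d) f(b+d).
oracle_gradient_cwt <- function(px, a, truncate = 4) {
  h <- ceiling(truncate * a)
  d <- -h:h
  r2 <- outer(d^2, d^2, "+") / a^2
  g <- exp(-r2 / 2) / (2 * pi)
  k1 <- sweep(g, 2, d, `*`) / a^3  # columns scaled by dx
  k2 <- sweep(g, 1, d, `*`) / a^3  # rows scaled by dy
  nr <- nrow(px); nc <- ncol(px)
  t1 <- matrix(NA_real_, nr, nc); t2 <- t1
  for (r in (h + 1):(nr - h)) {
    for (c in (h + 1):(nc - h)) {
      sub <- px[(r - h):(r + h), (c - h):(c + h)]
      t1[r, c] <- sum(k1 * sub)
      t2[r, c] <- sum(k2 * sub)
    }
  }
  list(t1 = t1, t2 = t2)
}

# build a maxima_set directly from a vector of angles (for pdf tests)
maxima_from_angles <- function(angles, scale = 1) {
  structure(list(scale = scale, scale_px = scale,
                 points = data.frame(row = seq_along(angles),
                                     col = seq_along(angles),
                                     modulus = 1, angle = angles),
                 chains = NULL),
            class = "maxima_set")
}

# angle distribution with an explicit density vector (already normalized)
pdf_from_density <- function(density) {
  n <- length(density)
  structure(list(scale = 1,
                 bin_edges = seq(-pi, pi, length.out = n + 1L),
                 density = density, n_angles = 1000L),
            class = "angle_distribution")
}

# hand-built anisotropy profile
profile_from_fa <- function(scales, fa, label = "p") {
  structure(list(scales = scales, fa = fa,
                 n_maxima = rep(NA_integer_, length(scales)),
                 label = label),
            class = "anisotropy_profile")
}

fa_at_scale <- function(image, scale_um, n_bins = 72L) {
  cfg <- wavelet_config(scales = scale_um, n_bins = n_bins)
  mx <- detect_maxima(continuous_wavelet_transform(image, scale_um, cfg),
                      cfg)
  anisotropy_factor(angle_pdf(mx, n_bins))
}
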