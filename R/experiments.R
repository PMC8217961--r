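#' Wilcoxon rank-sum comparison of two score samples
#'
#' Two-sided nonparametric comparison of two samples of per-image scores
#' (anisotropy factors or Fourier alignment scores).  The exact
#' permutation distribution is used for combined sample sizes up to 20
#' without ties; otherwise the normal approximation with continuity and
#' tie correction.  Identical pooled samples give p = 1 by convention.
#'
#' @param a,b numeric score samples (each of size >= 2).
#' @param alpha significance level (default 0.05).
#' @param scale optional scale (um) annotation.
#' @return an object of class `group_comparison`: list with `p_value`,
#'   `significant`, `alpha`, `n_a`, `n_b`, `median_a`, `median_b`,
#'   `scale`.
#' @export
compare_groups <- function(a, b, alpha = 0.05, scale = NA_real_) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples must have at least 2 non-missing values")
  pooled <- c(a, b)
  if (all(pooled == pooled[1L])) {
    p <- 1
  } else {
    exact <- (length(pooled) <= 20L) && !anyDuplicated(pooled)
    p <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                         correct = TRUE)$p.value)
  }
  structure(list(p_value = p, significant = p < alpha, alpha = alpha,
                 n_a = length(a), n_b = length(b),
                 median_a = stats::median(a), median_b = stats::median(b),
                 scale = scale),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> n = %d vs %d, medians %.4g vs %.4g, p = %.3g%s\n",
    x$n_a, x$n_b, x$median_a, x$median_b, x$p_value,
    if (x$significant) sprintf(" (significant at %.3g)", x$alpha) else ""))
  invisible(x)
}

#' Consecutive-pair discrimination count
#'
#' Given score samples for the 19 calibration angle ranges ordered from
#' narrowest to widest, runs a two-sided Wilcoxon rank-sum test on each
#' of the 18 consecutive pairs and counts how many reach `p < alpha`.
#' No multiple-testing correction is applied -- the count is the
#' sensitivity readout of the calibration study.
#'
#' @param groups list of numeric score samples, ordered by angle-range
#'   width (length 19 for the standard design, but any length >= 2 is
#'   accepted).
#' @param alpha significance level (default 0.05).
#' @return an object of class `discrimination_result`: list with
#'   `n_pairs`, `n_discriminated`, `p_values`, `alpha`.
#' @export
discrimination_count <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 ordered groups")
  sizes <- vapply(groups, function(g) sum(!is.na(g)), integer(1))
  if (any(sizes < 2L))
    stop("every group needs at least 2 non-missing scores")
  n_pairs <- length(groups) - 1L
  p <- vapply(seq_len(n_pairs), function(i)
    compare_groups(groups[[i]], groups[[i + 1L]], alpha)$p_value,
    numeric(1))
  structure(list(n_pairs = n_pairs, n_discriminated = sum(p < alpha),
                 p_values = p, alpha = alpha),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("<discrimination_result> %d/%d pairs at p < %.3g\n",
              x$n_discriminated, x$n_pairs, x$alpha))
  invisible(x)
}

# Score one image at several scales: anisotropy factor and angle
# density per scale and, optionally, the Fourier baseline.
score_image <- function(image, scales, config, fourier = TRUE) {
  n <- length(scales)
  fa <- rep(NA_real_, n)
  n_max <- integer(n)
  dens <- matrix(NA_real_, n, config$n_bins)
  for (i in seq_len(n)) {
    resp <- continuous_wavelet_transform(image, scales[i], config)
    mx <- detect_maxima(resp, config)
    n_max[i] <- nrow(mx$points)
    if (n_max[i] > 0L) {
      pdf <- angle_pdf(mx, config$n_bins)
      fa[i] <- anisotropy_factor(pdf)
      dens[i, ] <- pdf$density
    }
  }
  list(fa = fa, n_maxima = n_max, density = dens,
       r = if (fourier) r_computed(image) else NA_real_)
}

# Accumulator for group-averaged angle pdfs: the group pdf is the mean
# of per-image densities, scale by scale.
new_pdf_accumulator <- function() {
  acc <- new.env(parent = emptyenv())
  acc$sums <- list()
  acc$counts <- list()
  acc
}

pdf_accumulate <- function(acc, group, scales, density) {
  key <- as.character(group)
  if (is.null(acc$sums[[key]])) {
    acc$sums[[key]] <- matrix(0, length(scales), ncol(density))
    acc$counts[[key]] <- integer(length(scales))
  }
  ok <- !is.na(density[, 1L])
  acc$sums[[key]][ok, ] <- acc$sums[[key]][ok, , drop = FALSE] +
    density[ok, , drop = FALSE]
  acc$counts[[key]][ok] <- acc$counts[[key]][ok] + 1L
  invisible(acc)
}

pdf_table <- function(acc, scales, n_bins) {
  centers <- -pi + (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  do.call(rbind, lapply(names(acc$sums), function(key) {
    do.call(rbind, lapply(seq_along(scales), function(si) {
      cnt <- acc$counts[[key]][si]
      data.frame(group = key, scale_um = scales[si],
                 angle_rad = centers,
                 density = if (cnt > 0L) acc$sums[[key]][si, ] / cnt
                           else NA_real_,
                 n_images = cnt)
    }))
  }))
}

#' Run the calibration experiment on synthetic fiber cohorts
#'
#' Simulates `n_per_group` images for every fiber diameter and angle
#' range of the design, scores each image with the wavelet anisotropy
#' factor at the requested scales (and the Fourier baseline when
#' `fourier = TRUE`), and counts consecutive-range discriminations per
#' diameter, scale and method.
#'
#' @param diameters fiber diameters in microns (default `c(2, 4, 6, 8)`).
#' @param angle_ranges data frame of `theta_min`/`theta_max`
#'   (default [calibration_angle_ranges()]), ordered narrow to wide.
#' @param n_per_group images per diameter x range cell (default 100).
#' @param scales analysis scales in microns (default the 2.46 um key
#'   scale, i.e. 7 px).
#' @param seed master seed (default 1).
#' @param fourier also score the Fourier baseline (default `TRUE`).
#' @param n_bins angle histogram bins (default 72).
#' @param alpha significance level for discrimination (default 0.05).
#' @param out_dir optional directory for tidy CSV output (`scores.csv`,
#'   `summary.csv`, `discrimination.csv`).
#' @param verbose log progress to stderr.
#' @return an object of class `calibration_result`: list with `scores`
#'   (per-image data frame), `summary` (per-group quartiles),
#'   `discrimination` (per diameter x scale x method counts) and
#'   `mean_pdfs` (group-averaged angle densities per scale).
#' @export
run_calibration <- function(diameters = c(2, 4, 6, 8),
                            angle_ranges = calibration_angle_ranges(),
                            n_per_group = 100L,
                            scales = key_scales()[1L], seed = 1L,
                            fourier = TRUE, n_bins = 72L, alpha = 0.05,
                            out_dir = NULL, verbose = FALSE) {
  config <- wavelet_config(scales = scales, n_bins = n_bins)
  manifest <- generate_calibration_set(diameters, angle_ranges,
                                       n_per_group, seed)
  rows <- vector("list", nrow(manifest))
  acc <- new_pdf_accumulator()
  for (k in seq_len(nrow(manifest))) {
    img <- simulate_manifest_image(manifest[k, ])
    sc <- score_image(img, scales, config, fourier)
    pdf_accumulate(acc, sprintf("d%g_[%g,%g]", manifest$diameter_um[k],
                                manifest$theta_min[k],
                                manifest$theta_max[k]),
                   scales, sc$density)
    rows[[k]] <- data.frame(
      image_id = manifest$image_id[k],
      diameter_um = manifest$diameter_um[k],
      theta_min = manifest$theta_min[k],
      theta_max = manifest$theta_max[k],
      scale_um = scales, n_maxima = sc$n_maxima, fa = sc$fa,
      r_computed = sc$r)
    if (verbose && k %% 100L == 0L)
      message(sprintf("calibration: %d / %d images", k, nrow(manifest)))
  }
  scores <- do.call(rbind, rows)
  width <- scores$theta_max - scores$theta_min

  summary_df <- do.call(rbind, lapply(
    split(scores, list(scores$diameter_um, width, scores$scale_um),
          drop = TRUE),
    function(g) data.frame(
      diameter_um = g$diameter_um[1L], theta_min = g$theta_min[1L],
      theta_max = g$theta_max[1L], scale_um = g$scale_um[1L],
      median_fa = stats::median(g$fa, na.rm = TRUE),
      q1_fa = stats::quantile(g$fa, 0.25, na.rm = TRUE, names = FALSE),
      q3_fa = stats::quantile(g$fa, 0.75, na.rm = TRUE, names = FALSE),
      median_r = stats::median(g$r_computed),
      n_images = nrow(g))))
  ord <- order(summary_df$diameter_um, summary_df$scale_um,
               summary_df$theta_max - summary_df$theta_min)
  summary_df <- summary_df[ord, ]
  rownames(summary_df) <- NULL

  widths <- sort(unique(width))
  disc <- list()
  for (d in diameters) for (a in scales) {
    sub <- scores[scores$diameter_um == d & scores$scale_um == a, ]
    subw <- sub$theta_max - sub$theta_min
    fa_groups <- lapply(widths, function(w) sub$fa[subw == w])
    disc[[length(disc) + 1L]] <- data.frame(
      diameter_um = d, scale_um = a, method = "wavelet",
      n_pairs = length(widths) - 1L,
      n_discriminated =
        discrimination_count(fa_groups, alpha)$n_discriminated)
    if (fourier) {
      r_groups <- lapply(widths, function(w) sub$r_computed[subw == w])
      disc[[length(disc) + 1L]] <- data.frame(
        diameter_um = d, scale_um = a, method = "fourier",
        n_pairs = length(widths) - 1L,
        n_discriminated =
          discrimination_count(r_groups, alpha)$n_discriminated)
    }
  }
  disc <- do.call(rbind, disc)

  mean_pdfs <- pdf_table(acc, scales, config$n_bins)
  result <- structure(list(scores = scores, summary = summary_df,
                           discrimination = disc, mean_pdfs = mean_pdfs,
                           alpha = alpha, seed = seed),
                      class = "calibration_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(disc, file.path(out_dir, "discrimination.csv"),
                     row.names = FALSE)
    utils::write.csv(mean_pdfs, file.path(out_dir, "mean_pdfs.csv"),
                     row.names = FALSE)
  }
  result
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  print(x$discrimination, row.names = FALSE)
  invisible(x)
}

#' Run the white-noise robustness experiment
#'
#' Builds the seven image groups of the noise study -- clean fibers with
#' orientations in `angle_range`, the same images with additive white
#' noise at each multiple of the image mean, and a pure white-noise
#' group -- scores every image at the requested scales, and compares the
#' heaviest-noise group against the noise-only group at the largest
#' scale.
#'
#' @param n_per_group images per group (default 100).
#' @param scales analysis scales in microns (default the five key
#'   scales).
#' @param multiples noise multiples (default `c(1, 2, 5, 10, 20)`).
#' @param angle_range fiber orientation range in degrees (default
#'   `c(60, 120)`).
#' @param diameter_um fiber diameter (default 2).
#' @param seed master seed (default 1).
#' @param n_bins angle histogram bins (default 72).
#' @param alpha significance level (default 0.05).
#' @param out_dir optional directory for CSV output.
#' @param verbose log progress to stderr.
#' @return an object of class `noise_result`: list with `scores`
#'   (per-image rows with `group`, `multiple`, `scale_um`, `fa`),
#'   `summary` (per group x scale medians and quartiles), `mean_pdfs`
#'   (group-averaged angle densities) and `top_vs_noise` (the rank-sum
#'   comparison of the heaviest-noise group against noise-only at the
#'   largest scale).
#' @export
run_noise_experiment <- function(n_per_group = 100L,
                                 scales = key_scales(),
                                 multiples = c(1, 2, 5, 10, 20),
                                 angle_range = c(60, 120),
                                 diameter_um = 2, seed = 1L,
                                 n_bins = 72L, alpha = 0.05,
                                 out_dir = NULL, verbose = FALSE) {
  config <- wavelet_config(scales = scales, n_bins = n_bins)
  groups <- c("clean", paste0("noise", multiples, "x"), "noise_only")
  rows <- list()
  acc <- new_pdf_accumulator()
  for (i in seq_len(n_per_group)) {
    base <- simulate_fiber_image(fiber_sim_config(
      diameter_um = diameter_um, angle_range_deg = angle_range,
      seed = derive_seed(seed, i)))
    imgs <- c(list(clean = base),
              stats::setNames(lapply(seq_along(multiples), function(j)
                add_white_noise(base, multiples[j],
                                seed = derive_seed(seed,
                                                   i + n_per_group * j))),
                paste0("noise", multiples, "x")),
              list(noise_only = simulate_noise_image(
                mean_value = 100, image_px = nrow(base$pixels),
                pixel_size = base$pixel_size,
                seed = derive_seed(seed,
                                   i + n_per_group * (length(multiples) + 1L)))))
    for (g in names(imgs)) {
      sc <- score_image(imgs[[g]], scales, config, fourier = FALSE)
      pdf_accumulate(acc, g, scales, sc$density)
      rows[[length(rows) + 1L]] <- data.frame(
        image_idx = i, group = g,
        multiple = c(clean = 0, stats::setNames(multiples,
                                                paste0("noise", multiples, "x")),
                     noise_only = NA_real_)[[g]],
        scale_um = scales, n_maxima = sc$n_maxima, fa = sc$fa)
    }
    if (verbose && i %% 10L == 0L)
      message(sprintf("noise experiment: %d / %d base images", i,
                      n_per_group))
  }
  scores <- do.call(rbind, rows)
  scores$group <- factor(scores$group, levels = groups)

  summary_df <- do.call(rbind, lapply(
    split(scores, list(scores$group, scores$scale_um), drop = TRUE),
    function(g) data.frame(
      group = g$group[1L], multiple = g$multiple[1L],
      scale_um = g$scale_um[1L],
      median_fa = stats::median(g$fa, na.rm = TRUE),
      q1_fa = stats::quantile(g$fa, 0.25, na.rm = TRUE, names = FALSE),
      q3_fa = stats::quantile(g$fa, 0.75, na.rm = TRUE, names = FALSE),
      n_images = nrow(g))))
  summary_df <- summary_df[order(summary_df$scale_um,
                                 as.integer(summary_df$group)), ]
  rownames(summary_df) <- NULL

  a_max <- max(scales)
  top <- paste0("noise", max(multiples), "x")
  cmp <- compare_groups(
    scores$fa[scores$group == top & scores$scale_um == a_max],
    scores$fa[scores$group == "noise_only" & scores$scale_um == a_max],
    alpha, scale = a_max)

  mean_pdfs <- pdf_table(acc, scales, config$n_bins)
  result <- structure(list(scores = scores, summary = summary_df,
                           mean_pdfs = mean_pdfs, top_vs_noise = cmp,
                           seed = seed),
                      class = "noise_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scores, file.path(out_dir, "noise_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_df, file.path(out_dir, "noise_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(mean_pdfs, file.path(out_dir, "noise_pdfs.csv"),
                     row.names = FALSE)
  }
  result
}

#' @export
print.noise_result <- function(x, ...) {
  cat("<noise_result>\n")
  print(x$summary, row.names = FALSE)
  cat("heaviest noise vs noise-only at largest scale: ")
  print(x$top_vs_noise)
  invisible(x)
}

#' Multiscale cohort comparison against a control group
#'
#' Computes per-image anisotropy profiles for labeled image cohorts,
#' runs all pairwise per-scale rank-sum comparisons, normalizes each
#' cohort's median profile by the control cohort, and reports crossover
#' scales where the ordering of two cohorts' normalized medians
#' reverses.
#'
#' @param cohorts named list; each element a list of
#'   [intensity_image()] objects (>= 3 images per cohort).
#' @param control name of the control cohort (must match a name of
#'   `cohorts`).
#' @param config a [wavelet_config()] defining the scale ladder.
#' @param alpha significance level (default 0.05).
#' @param out_dir optional directory for CSV output.
#' @param verbose log progress to stderr.
#' @return an object of class `cohort_result`: list with `profiles`
#'   (per-cohort lists of `anisotropy_profile`), `summary`,
#'   `comparisons` (per scale and cohort pair), `normalized` (one ratio
#'   profile per cohort, control included as a reference of ones) and
#'   `crossovers` (data frame of cohort pairs and bracketing scales).
#' @export
analyze_cohorts <- function(cohorts, control, config = wavelet_config(),
                            alpha = 0.05, out_dir = NULL,
                            verbose = FALSE) {
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts))))
    stop("`cohorts` must be a named list")
  if (length(cohorts) < 2L) stop("need at least 2 cohorts")
  if (!control %in% names(cohorts))
    stop("control cohort '", control, "' not found")
  sizes <- vapply(cohorts, length, integer(1))
  if (any(sizes < 3L))
    stop("every cohort needs at least 3 images (got: ",
         paste(sizes, collapse = ", "), ")")

  profiles <- lapply(names(cohorts), function(nm) {
    if (verbose) message("profiling cohort ", nm)
    lapply(seq_along(cohorts[[nm]]), function(i)
      multiscale_profile(cohorts[[nm]][[i]], config,
                         label = sprintf("%s_%03d", nm, i)))
  })
  names(profiles) <- names(cohorts)

  scales <- config$scales
  fa_mat <- lapply(profiles, function(ps)
    do.call(rbind, lapply(ps, `[[`, "fa")))

  pairs <- utils::combn(names(cohorts), 2L, simplify = FALSE)
  comparisons <- do.call(rbind, lapply(pairs, function(pr) {
    do.call(rbind, lapply(seq_along(scales), function(si) {
      cmp <- compare_groups(fa_mat[[pr[1L]]][, si],
                            fa_mat[[pr[2L]]][, si], alpha,
                            scale = scales[si])
      data.frame(cohort_a = pr[1L], cohort_b = pr[2L],
                 scale_um = scales[si], p_value = cmp$p_value,
                 significant = cmp$significant,
                 median_a = cmp$median_a, median_b = cmp$median_b)
    }))
  }))

  normalized <- lapply(names(cohorts), function(nm)
    normalize_profiles(profiles[[nm]], profiles[[control]], label = nm))
  names(normalized) <- names(cohorts)

  noncontrol <- setdiff(names(cohorts), control)
  cross_pairs <- if (length(noncontrol) >= 2L)
    utils::combn(noncontrol, 2L, simplify = FALSE) else list()
  crossovers <- do.call(rbind, c(list(
    data.frame(cohort_a = character(0), cohort_b = character(0),
               scale_below_um = numeric(0), scale_above_um = numeric(0))),
    lapply(cross_pairs, function(pr) {
      cr <- detect_crossovers(normalized[[pr[1L]]], normalized[[pr[2L]]])
      if (nrow(cr) == 0L) return(NULL)
      cbind(cohort_a = pr[1L], cohort_b = pr[2L], cr)
    })))

  summary_df <- do.call(rbind, lapply(names(cohorts), function(nm)
    cbind(cohort = nm, summarize_profiles(profiles[[nm]]))))

  result <- structure(list(profiles = profiles, summary = summary_df,
                           comparisons = comparisons,
                           normalized = normalized,
                           crossovers = crossovers, control = control),
                      class = "cohort_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary_df, file.path(out_dir, "cohort_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons,
                     file.path(out_dir, "cohort_comparisons.csv"),
                     row.names = FALSE)
    norm_df <- do.call(rbind, lapply(normalized, function(p)
      data.frame(cohort = p$label, scale_um = p$scales,
                 normalized_median_fa = p$fa)))
    utils::write.csv(norm_df, file.path(out_dir, "cohort_normalized.csv"),
                     row.names = FALSE)
  }
  result
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> control = %s\n", x$control))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Detect crossover scales between two profiles
#'
#' Reports every pair of consecutive ladder scales between which the
#' sign of `a$fa - b$fa` reverses (ties do not count as reversals).
#'
#' @param a,b `anisotropy_profile` objects on the same scale ladder.
#' @return data frame with columns `scale_below_um`, `scale_above_um`
#'   bracketing each crossover.
#' @export
detect_crossovers <- function(a, b) {
  if (length(a$scales) != length(b$scales) ||
      any(abs(a$scales - b$scales) > 1e-9))
    stop("profiles do not share a common scale ladder")
  d <- a$fa - b$fa
  ok <- which(!is.na(d) & d != 0)
  out <- data.frame(scale_below_um = numeric(0),
                    scale_above_um = numeric(0))
  if (length(ok) < 2L) return(out)
  s <- sign(d[ok])
  flips <- which(s[-1L] != s[-length(s)])
  if (length(flips) > 0L)
    out <- data.frame(scale_below_um = a$scales[ok[flips]],
                      scale_above_um = a$scales[ok[flips + 1L]])
  out
}
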