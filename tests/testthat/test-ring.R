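test_that("Gaussian smoothing: identity cases and kernel oracle", {
  img <- matrix(0.5, 41, 41)
  expect_equal(smooth_image(img, 14.4, 1.3), img, tolerance = 1e-9)
  noisy <- withr::with_seed(1, matrix(runif(41 * 41), 41))
  expect_identical(smooth_image(noisy, 0, 1.3), noisy)
  # delta spike reproduces the sampled separable Gaussian kernel
  delta <- matrix(0, 41, 41); delta[21, 21] <- 1
  sm <- smooth_image(delta, sigma_um = 2, pixel_size_um = 1)
  h <- ceiling(4 * 2)
  k <- stats::dnorm(-h:h, sd = 2); k <- k / sum(k)
  expect_equal(sm[(21 - h):(21 + h), (21 - h):(21 + h)],
               outer(k, k), tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(smooth_image(matrix(c(1, NA, 1, 1), 2), 1, 1),
               "non-finite")
})

test_that("radial profiles: constants, disc geometry oracle, and
          symmetry", {
  img <- matrix(2.5, 61, 61)
  p <- radial_profile(img, c(31, 31), max_radius_um = 20,
                      bin_width_um = 1, pixel_size_um = 1)
  expect_true(all(p$mean_intensity[!p$empty] == 2.5))
  # disc: brute-force per-bin means agree exactly
  d <- aedscreen:::.radial_distance(61, 61, c(31, 31))
  disc <- (d <= 12) * 1.0 + 0.1
  p2 <- radial_profile(disc, c(31, 31), max_radius_um = 25,
                       bin_width_um = 1.5, pixel_size_um = 1)
  oracle <- brute_force_bin_means(disc, c(31, 31), 25, 1.5, 1)
  expect_equal(p2$mean_intensity, oracle)
  # step falls at the disc radius bin
  expect_equal(p2$mean_intensity[p2$r_mid_um < 11],
               rep(1.1, sum(p2$r_mid_um < 11)))
  expect_equal(p2$mean_intensity[p2$r_mid_um > 14],
               rep(0.1, sum(p2$r_mid_um > 14)))
  # rotation and reflection invariance about the centre
  asym <- withr::with_seed(4, disc + matrix(runif(61 * 61, 0, 0.2), 61))
  rot90 <- t(asym)[, rev(seq_len(61))]
  refl <- asym[rev(seq_len(61)), ]
  pa <- radial_profile(asym, c(31, 31), 20, 1, 1)
  expect_equal(radial_profile(rot90, c(31, 31), 20, 1, 1)$mean_intensity,
               pa$mean_intensity)
  expect_equal(radial_profile(refl, c(31, 31), 20, 1, 1)$mean_intensity,
               pa$mean_intensity)
  expect_error(radial_profile(img, c(100, 31), 10, 1, 1), "centre")
  # truncation is flagged, not fatal
  expect_true(attr(radial_profile(img, c(31, 31), 60, 1, 1),
                   "truncated"))
})

test_that("normalisation and subtraction: identities, reversal, and
          degenerate profiles", {
  prof <- seq(1, 0, length.out = 20)
  same <- normalize_and_subtract(prof, prof)
  expect_true(all(same$difference == 0))
  expect_equal(same$max_intensity_difference, 0)
  # bf = reversed monotone fl: statistic 1 at the far bin
  rv <- normalize_and_subtract(rev(prof), prof)
  expect_equal(rv$max_intensity_difference, 1)
  expect_equal(rv$argmax_bin, 19L)
  # constant profile flagged degenerate
  dg <- normalize_and_subtract(rep(1, 20), prof)
  expect_true(dg$degenerate)
  expect_error(normalize_and_subtract(prof, prof[-1]), "bin counts")
})

test_that("synthetic pairs: noise-free argmax at the ring centre and
          amplitude monotonicity", {
  pair <- generate_cluster_image(noise_sd = 0, seed = 1)
  cp <- cluster_profile(pair, sigma_um = 0, centre = pair$centre_px)
  expect_lte(abs(cp$r_argmax_um - pair$ring_radius_um), 1.3)
  # ring amplitude 0 vs > 0: strictly larger statistic, every seed
  stats_by_amp <- sapply(c(0, 0.3, 0.6), function(a) {
    vapply(1:20, function(seed) {
      p <- generate_cluster_image(ring_amplitude = a, seed = seed,
                                  size_px = 192)
      cluster_profile(p)$max_intensity_difference
    }, numeric(1))
  })
  expect_true(all(stats_by_amp[, 3] > stats_by_amp[, 1]))
  m <- colMeans(stats_by_amp)
  expect_true(m[1] < m[2] && m[2] < m[3])
  expect_error(generate_cluster_image(cluster_radius_um = -1), "radius")
  expect_error(generate_cluster_image(cluster_radius_um = 500),
               "fit")
})

test_that("cluster centre detection", {
  d <- aedscreen:::.radial_distance(101, 101, c(40, 60))
  img <- 0.05 + (d <= 15) * 0.8
  ctr <- detect_cluster_centre(img)
  expect_lte(max(abs(ctr - c(40, 60))), 1)
  # two discs: centroid of the larger (twice the area) is returned
  d2 <- aedscreen:::.radial_distance(101, 101, c(70, 25))
  img2 <- img + (d2 <= 10) * 0.8
  ctr2 <- detect_cluster_centre(img2)
  expect_lte(max(abs(ctr2 - c(40, 60))), 1)
  expect_error(detect_cluster_centre(matrix(0, 50, 50)), "no cluster")
})

test_that("one-way ANOVA matches the manual sum-of-squares oracle and
          degenerate definitions", {
  g <- list(a = c(3, 5, 7, 9), b = c(2, 4, 6, 8), c = c(10, 12, 14, 16))
  r <- compare_groups(g)
  # independent oracle: direct between/within mean squares
  x <- unlist(g); gm <- mean(x)
  ssb <- 4 * sum((sapply(g, mean) - gm)^2)
  ssw <- sum((g$a - mean(g$a))^2) + sum((g$b - mean(g$b))^2) +
    sum((g$c - mean(g$c))^2)
  expect_equal(r$F, (ssb / 2) / (ssw / 9), tolerance = 1e-10)
  expect_equal(r$p, stats::pf((ssb / 2) / (ssw / 9), 2, 9,
                              lower.tail = FALSE))
  # Tukey adjustment equals stats::TukeyHSD
  f <- factor(rep(names(g), lengths(g)))
  tk <- stats::TukeyHSD(stats::aov(x ~ f))$f
  expect_equal(unname(r$pairwise$p_adj), unname(tk[, "p adj"]),
               tolerance = 1e-8)
  # degenerate cases
  same <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$F, 0); expect_equal(same$p, 1)
  const <- compare_groups(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(const$F, 0); expect_equal(const$p, 1)
  sep <- compare_groups(list(a = c(1, 1), b = c(2, 2)))
  expect_equal(sep$F, Inf); expect_equal(sep$p, 0)
  expect_error(compare_groups(list(a = 1, b = c(1, 2))), ">= 2")
  expect_error(compare_groups(list(a = c(1, 2))), "groups")
})

test_that("PNG image round trip", {
  img <- withr::with_seed(2, matrix(runif(32 * 32), 32))
  f <- withr::local_tempfile(fileext = ".png")
  write_image_png(img, f)
  back <- read_image_png(f)
  expect_equal(dim(back), c(32, 32))
  expect_lte(max(abs(back - img)), 1 / 255)
})
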