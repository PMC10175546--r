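test_that("generator places the ridge at the rim and is reproducible", {
  img <- generate_spheroid_image(radius_um = 200, rim_peak_um = 150,
                                 core_amplitude = 0, noise_sd = 0,
                                 pixel_size = 2)
  peak <- which(img$pixels == max(img$pixels), arr.ind = TRUE)[1, ]
  center <- dim(img$pixels) / 2 * img$pixel_size
  r_peak <- sqrt(sum(((peak - 0.5) * img$pixel_size - center)^2))
  expect_lt(abs(r_peak - 150), 2 * img$pixel_size)
  zero <- generate_spheroid_image(rim_amplitude = 0, core_amplitude = 0,
                                  noise_sd = 0)
  expect_true(all(zero$pixels == 0))
  a <- generate_spheroid_image(seed = 5)
  b <- generate_spheroid_image(seed = 5)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, generate_spheroid_image(seed = 6)$pixels))
  expect_error(generate_spheroid_image(radius_um = 500, size_px = 100,
                                       pixel_size = 2), "bounds")
})

test_that("radial profile of a uniform disk is flat at the disk value", {
  ps <- 2
  n <- 128
  center <- rep(n / 2 * ps, 2)
  r <- sqrt(outer(((1:n - 0.5) * ps - center[1])^2,
                  ((1:n - 0.5) * ps - center[2])^2, `+`))
  img <- spheroid_image(matrix(5 * (r <= 100), n, n), ps)
  prof <- radial_profile(img, annulus_width_um = 10, center = center,
                         max_radius_um = 90)
  expect_true(all(abs(prof$mean_intensity - 5) < 1e-9))
  expect_true(all(diff(prof$radii) > 0))
  expect_equal(length(prof$radii), length(prof$sem))
  expect_true(all(prof$n_pixels >= 1))
})

test_that("profile recovers the generator ring peak within one annulus", {
  img <- generate_spheroid_image(radius_um = 200, rim_peak_um = 150,
                                 rim_amplitude = 1, core_amplitude = 0.2,
                                 noise_sd = 0.05, pixel_size = 2, seed = 3)
  prof <- radial_profile(img, annulus_width_um = 10)
  peak_r <- prof$radii[which.max(prof$mean_intensity)]
  expect_lte(abs(peak_r - 150), 10)
})

test_that("profiles are linear in intensity and rotation-invariant", {
  img <- generate_spheroid_image(noise_sd = 0.02, seed = 8)
  prof <- radial_profile(img, annulus_width_um = 10)
  img2 <- spheroid_image(2 * img$pixels, img$pixel_size)
  prof2 <- radial_profile(img2, annulus_width_um = 10,
                          center = prof$center)
  expect_equal(prof2$mean_intensity, 2 * prof$mean_intensity)
  rot <- spheroid_image(t(img$pixels[nrow(img$pixels):1, ]), img$pixel_size)
  prof_rot <- radial_profile(rot, annulus_width_um = 10)
  expect_equal(prof_rot$mean_intensity, prof$mean_intensity,
               tolerance = 1e-6)
})

test_that("region statistics use disjoint half-open core and rim", {
  img <- generate_spheroid_image(noise_sd = 0, seed = 1)
  prof <- radial_profile(img, annulus_width_um = 10)
  rs <- region_stats(prof)
  expect_s3_class(rs, "region_stats")
  # an annulus mid-radius cannot satisfy both [50,100) and [100,200)
  in_core <- prof$radii >= 50 & prof$radii < 100
  in_rim <- prof$radii >= 100 & prof$radii < 200
  expect_false(any(in_core & in_rim))
  # constant profile: core and rim agree
  ps <- 2; n <- 256
  center <- rep(n / 2 * ps, 2)
  flat <- spheroid_image(matrix(5, n, n), ps)
  prof_flat <- radial_profile(flat, annulus_width_um = 10, center = center)
  rs_flat <- region_stats(prof_flat)
  expect_equal(rs_flat$core_mean, 5)
  expect_equal(rs_flat$rim_mean, 5)
  # monotone profile: rim exceeds core
  r <- sqrt(outer(((1:n - 0.5) * ps - center[1])^2,
                  ((1:n - 0.5) * ps - center[2])^2, `+`))
  lin <- spheroid_image(r, ps)
  rs_lin <- region_stats(radial_profile(lin, annulus_width_um = 10,
                                        center = center))
  expect_gt(rs_lin$rim_mean, rs_lin$core_mean)
})

test_that("bright rim vs dark core shows up in the region contrast", {
  img <- generate_spheroid_image(radius_um = 220, rim_peak_um = 150,
                                 rim_amplitude = 1, core_amplitude = 0.1,
                                 noise_sd = 0, pixel_size = 2)
  rs <- region_stats(radial_profile(img, annulus_width_um = 10))
  # closed-form annulus averages put the rim/core ratio above 80% of the
  # configured amplitude ratio only after accounting for ridge width; the
  # qualitative contrast is what the assay relies on
  expect_gt(rs$rim_mean / rs$core_mean, 2)
})

test_that("partial radial coverage is flagged", {
  img <- generate_spheroid_image(radius_um = 100, rim_peak_um = 70,
                                 noise_sd = 0, pixel_size = 2, size_px = 110)
  expect_warning(rs <- region_stats(radial_profile(img,
                                                   annulus_width_um = 10)),
                 "available range")
  expect_true(rs$partial)
})

test_that("compare_regions is a Welch test with an exact-equality shortcut", {
  mk <- function(core, rim) {
    structure(list(core_mean = core, rim_mean = rim, core_um = c(50, 100),
                   rim_um = c(100, 200), partial = FALSE),
              class = "region_stats")
  }
  a <- lapply(c(10, 10, 10), function(v) mk(1, v))
  expect_equal(compare_regions(a, a, "rim")$p, 1)
  expect_equal(compare_regions(a, a, "rim")$difference, 0)
  set.seed(42)
  b1 <- lapply(rnorm(20, 10, 1), function(v) mk(1, v))
  b2 <- lapply(rnorm(20, 12, 1), function(v) mk(1, v))
  res <- compare_regions(b1, b2, "rim")
  expect_lt(res$p, 0.01)
  flipped <- compare_regions(b2, b1, "rim")
  expect_equal(flipped$difference, -res$difference)
  expect_equal(flipped$p, res$p)
  expect_error(compare_regions(b1[1], b2, "rim"), "at least 2")
})

test_that("a two-sigma effect is detected with high power at n = 20", {
  mk <- function(v) {
    structure(list(core_mean = 1, rim_mean = v, core_um = c(50, 100),
                   rim_um = c(100, 200), partial = FALSE),
              class = "region_stats")
  }
  hits <- 0L
  set.seed(7)
  for (trial in 1:100) {
    a <- lapply(rnorm(20, 10, 1), mk)
    b <- lapply(rnorm(20, 12, 1), mk)
    if (compare_regions(a, b, "rim")$p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})
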