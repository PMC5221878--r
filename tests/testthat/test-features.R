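test_that("area is pixel count times physical pixel area", {
  m <- matrix(FALSE, 20, 20); m[5:14, 5:14] <- TRUE
  roi <- roi_mask(m, c(7, 7))
  expect_equal(roi_area(roi, flat_slice(20, spacing = 1)), 100)
  expect_equal(roi_area(roi, flat_slice(20, spacing = 0.7)), 49)
  empty <- roi_mask(matrix(FALSE, 20, 20) | FALSE, c(1, 1))
  expect_error(roi_area(empty, flat_slice(20)), "empty mask")
})

test_that("perimeter approximates true boundary lengths under the corner convention", {
  # axis-aligned square: within the documented corner tolerance of 4*n*s
  n <- 12
  m <- matrix(FALSE, 24, 24); m[6:(5 + n), 6:(5 + n)] <- TRUE
  p_sq <- roi_perimeter(roi_mask(m, c(8, 8)), flat_slice(24, spacing = 1))
  expect_lt(abs(p_sq - 4 * n), 8)
  # digitized disk of radius 50 px: within 3% of the true circumference
  d <- raster_disk(128, 50)
  p_d <- roi_perimeter(roi_mask(d, c(64, 64)), flat_slice(128, spacing = 1))
  expect_lt(abs(p_d - 2 * pi * 50) / (2 * pi * 50), 0.03)
  # spacing scales the perimeter linearly
  p_d2 <- roi_perimeter(roi_mask(d, c(64, 64)), flat_slice(128, spacing = 0.7))
  expect_equal(p_d2, 0.7 * p_d)
  # 90-degree rotation leaves the perimeter unchanged
  p_rot <- roi_perimeter(roi_mask(rot90cw(d), c(64, 64)), flat_slice(128, spacing = 1))
  expect_equal(p_rot, p_d)
})

test_that("interior holes do not contribute to the outside boundary", {
  solid <- raster_disk(64, 20)
  holed <- solid & !raster_disk(64, 5)
  s <- flat_slice(64)
  p_solid <- roi_perimeter(roi_mask(solid, c(32, 12)), s)
  p_holed <- roi_perimeter(roi_mask(holed, c(32, 12)), s)
  expect_equal(p_holed, p_solid)
})

test_that("Feret diameter equals the brute-force all-pairs maximum", {
  # two isolated pixels 10 px apart
  m <- matrix(FALSE, 16, 16); m[3, 3] <- TRUE; m[3, 13] <- TRUE
  expect_equal(feret_diameter(roi_mask(m, c(3, 3)), flat_slice(16)), 10)
  # disk: diameter 2r within one pixel
  d <- raster_disk(64, 25)
  fd <- feret_diameter(roi_mask(d, c(32, 32)), flat_slice(64))
  expect_lt(abs(fd - 50), 1.5)
  # hull-based result equals brute force on assorted small phantoms
  for (seed in 1:4) {
    sp <- nodule_spec(shape = c("disk", "ellipse", "lobulated")[1 + seed %% 3],
                      target_area_mm2 = 150, fov_px = 64, seed = seed,
                      noise_sd_sharp = 0, noise_sd_smooth = 0)
    mask <- generate_nodule_pair(sp)$truth$mask
    got <- feret_diameter(roi_mask(mask, c(32, 32)), flat_slice(64, spacing = 0.7))
    expect_equal(got, brute_feret(mask, 0.7, 0.7))
  }
})

test_that("mean attenuation is the plain ROI mean", {
  m <- matrix(FALSE, 10, 10); m[1:10, 1:2] <- TRUE
  px <- matrix(-800, 10, 10); px[1:10, 1] <- 40; px[1:10, 2] <- -450
  s <- ct_slice(px, 1)
  expect_equal(mean_attenuation(roi_mask(m, c(1, 1)), s), -205)
  sp <- nodule_spec(target_area_mm2 = 400, ggo_fraction = 0.35,
                    noise_sd_sharp = 0, noise_sd_smooth = 0, seed = 3)
  pair <- generate_nodule_pair(sp)
  got <- mean_attenuation(pair$truth, pair$sharp)
  # exact mixture mean from the rasterized component pixel counts
  n_solid <- sum(pair$sharp$pixels[pair$truth$mask] == 40)
  n_all <- sum(pair$truth$mask)
  expect_equal(got, (n_solid * 40 + (n_all - n_solid) * -450) / n_all)
  # and close to the idealized closed form f*ggo + (1-f)*solid, up to the
  # sub-pixel-row rasterization of the solid core
  expect_lt(abs(got - (0.35 * -450 + 0.65 * 40)), 20)
})

test_that("circularity follows 4*pi*A/P^2 with clipping at 1", {
  expect_equal(circularity(pi * 5^2, 2 * pi * 5), 1) # perfect circle
  expect_equal(round(circularity(1020.79, 159.02), 2), 0.51)
  expect_lt(abs(circularity(409.96, 95.50) - 0.5649), 5e-4)
  expect_error(circularity(0, 10), "positive")
})

test_that("the area-preserving ellipse fit recovers constructed axes", {
  g_r <- matrix(seq_len(128), 128, 128)
  g_c <- matrix(seq_len(128), 128, 128, byrow = TRUE)
  e <- ((g_r - 64.5)^2 / 20^2 + (g_c - 64.5)^2 / 40^2) <= 1
  fit <- fit_ellipse(roi_mask(e, c(64, 64)), flat_slice(128))
  expect_equal(fit$major_mm, 80, tolerance = 0.02)
  expect_equal(fit$minor_mm, 40, tolerance = 0.02)
  # disk: isotropic
  d <- raster_disk(64, 20)
  fd <- fit_ellipse(roi_mask(d, c(32, 32)), flat_slice(64))
  expect_equal(fd$major_mm / fd$minor_mm, 1, tolerance = 0.01)
  # area preservation
  area <- roi_area(roi_mask(e, c(64, 64)), flat_slice(128))
  expect_equal(pi * fit$major_mm * fit$minor_mm / 4, area, tolerance = 0.005)
  # collinear mask is degenerate
  line <- matrix(FALSE, 10, 10); line[5, 2:9] <- TRUE
  expect_error(fit_ellipse(roi_mask(line, c(5, 2)), flat_slice(10)), "degenerate")
})

test_that("aspect ratio and roundness satisfy the area-preserving identity", {
  expect_equal(aspect_ratio(10, 10), 1)
  expect_equal(roundness(pi * 25, 10), 1) # circle of radius 5
  expect_equal(round(1 / 1.15, 2), 0.87)  # worked-example identity
  expect_gte(round(1 / 1.48, 2), 0.67)
  expect_error(aspect_ratio(1, 2), "major >= minor")
  for (seed in 1:5) {
    sp <- nodule_spec(shape = "lobulated", target_area_mm2 = 250, seed = seed,
                      noise_sd_sharp = 0, noise_sd_smooth = 0)
    pair <- generate_nodule_pair(sp)
    s <- pair$sharp
    a <- roi_area(pair$truth, s)
    f <- fit_ellipse(pair$truth, s)
    rnd <- roundness(a, f$major_mm)
    asp <- aspect_ratio(f$major_mm, f$minor_mm)
    expect_equal(rnd * asp, 1, tolerance = 0.01)
  }
})

test_that("histogram statistics match their defining moments and entropy form", {
  expect_equal(histogram_stats(c(-3, 0, 3) + 100)$skewness, 0)
  # population normalization: frozen small-sample check
  x <- c(1, 2, 2, 3, 7)
  mu <- mean(x); sg <- sqrt(mean((x - mu)^2))
  hs <- histogram_stats(x)
  expect_equal(hs$skewness, mean(((x - mu) / sg)^3))
  expect_equal(hs$kurtosis, mean(((x - mu) / sg)^4) - 3)
  # uniform histogram over 128 equally filled 1-HU bins -> exactly 7 bits
  expect_equal(histogram_stats(0:127 + 0.5, bin_width = 1)$entropy, 7)
  # natural-log base option
  expect_equal(histogram_stats(0:127 + 0.5, entropy_base = exp(1))$entropy,
               log(128))
  # Gaussian excess kurtosis tends to 0
  set.seed(99)
  z <- rnorm(1e5)
  expect_equal(histogram_stats(z, bin_width = 0.05)$kurtosis, 0, tolerance = 0.05)
  expect_error(histogram_stats(rep(5, 10)), "degenerate distribution")
  expect_error(histogram_stats(numeric(0)), "non-empty")
})

test_that("extract_features composes the ten features consistently", {
  sp <- nodule_spec(shape = "disk", target_area_mm2 = 408, noise_sd_sharp = 5,
                    noise_sd_smooth = 0, seed = 8)
  pair <- generate_nodule_pair(sp)
  fv <- extract_features(pair$sharp, pair$truth)
  expect_named(fv, feature_names())
  expect_equal(fv$area_mm2, 408, tolerance = 0.02)
  expect_gte(fv$circularity, 0.98)
  expect_equal(fv$aspect_ratio, 1, tolerance = 0.02)
  expect_equal(fv$mean_attenuation_hu, 40, tolerance = 0.1)
  # shifting the image by +100 HU moves only the mean attenuation
  shifted <- ct_slice(pair$sharp$pixels + 100, 0.7, 0.7, 1, "sharp")
  fv2 <- extract_features(shifted, pair$truth)
  expect_equal(fv2$mean_attenuation_hu, fv$mean_attenuation_hu + 100)
  geom <- c("diameter_mm", "perimeter_mm", "area_mm2", "circularity",
            "aspect_ratio", "roundness")
  expect_equal(fv2[geom], fv[geom])
  expect_equal(fv2$skewness, fv$skewness)
  expect_equal(fv2$kurtosis, fv$kurtosis)
})

test_that("all ten features are invariant to 90-degree rotation and mirroring", {
  sp <- nodule_spec(shape = "lobulated", target_area_mm2 = 300,
                    noise_sd_sharp = 30, seed = 17)
  pair <- generate_nodule_pair(sp)
  s <- pair$sharp
  roi <- pair$truth
  fv <- extract_features(s, roi)
  rot_slice <- ct_slice(rot90cw(s$pixels), 0.7, 0.7, 1, "sharp")
  rot_roi <- roi_mask(rot90cw(roi$mask), c(roi$seed[2], nrow(roi$mask) + 1 - roi$seed[1]))
  fv_rot <- extract_features(rot_slice, rot_roi)
  expect_equal(unlist(fv_rot), unlist(fv), tolerance = 1e-12)
  mir_slice <- ct_slice(s$pixels[, ncol(s$pixels):1], 0.7, 0.7, 1, "sharp")
  mir_roi <- roi_mask(roi$mask[, ncol(roi$mask):1],
                      c(roi$seed[1], ncol(roi$mask) + 1 - roi$seed[2]))
  fv_mir <- extract_features(mir_slice, mir_roi)
  expect_equal(unlist(fv_mir), unlist(fv), tolerance = 1e-12)
})

test_that("size features agree across the reconstruction pair more than texture does", {
  sp <- nodule_spec(shape = "ellipse", target_area_mm2 = 400, seed = 23)
  pair <- generate_nodule_pair(sp)
  b1 <- grow_bounds_from_seed(pair$sharp, pair$truth$seed)
  b5 <- grow_bounds_from_seed(pair$smooth, pair$truth$seed)
  f1 <- extract_features(pair$sharp, region_grow(pair$sharp, pair$truth$seed, b1[1], b1[2]))
  f5 <- extract_features(pair$smooth, region_grow(pair$smooth, pair$truth$seed, b5[1], b5[2]))
  for (col in c("diameter_mm", "area_mm2")) {
    expect_lt(abs(f1[[col]] - f5[[col]]) / f1[[col]], 0.05)
  }
})
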