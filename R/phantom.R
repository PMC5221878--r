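# Synthetic nodule phantoms: a controllable lesion (solid and/or ground-glass
# components, optional air-bronchogram hole) on lung background, rendered as a
# matched reconstruction pair — a sharp, noisy "1-mm" slice and a smooth,
# low-noise "5-mm" slice of the same scene — with the ground-truth mask.

#' Specify a nodule phantom
#'
#' Default tissue values: solid component 40 HU, ground-glass component
#' -450 HU, lung background -800 HU. `ggo_fraction` is the fraction of the
#' nodule area rendered at the ground-glass value (0 = solid nodule, values in
#' between = part-solid with a central solid core). Noise defaults follow the
#' sharp-kernel-noisier-than-smooth ordering of the paired reconstructions.
#'
#' @param shape One of `"disk"`, `"ellipse"`, `"lobulated"`.
#' @param target_area_mm2 Nodule area in mm^2 (> 0).
#' @param aspect Major/minor axis ratio for `"ellipse"` (>= 1).
#' @param solid_hu,ggo_hu,background_hu Tissue attenuations, HU.
#' @param ggo_fraction Fraction of the area rendered at `ggo_hu`, in `[0, 1]`.
#' @param bronchogram `NULL`, or a list `list(area_mm2=, offset_mm=c(dr, dc))`
#'   describing an internal air hole (-1000 HU) excluded from the truth mask.
#' @param lobulation Relative amplitude of the boundary lobulation for
#'   `"lobulated"` (default 0.15).
#' @param noise_sd_sharp,noise_sd_smooth Gaussian noise SD in HU for the sharp
#'   and smooth reconstructions (sharp is the noisier, high-frequency kernel).
#' @param smooth_sigma_px Gaussian blur sigma in pixels emulating the smooth
#'   reconstruction (default 1.5).
#' @param spacing_mm Isotropic pixel spacing, mm (default 0.7).
#' @param fov_px Image side length in pixels (default 128).
#' @param seed Integer RNG seed.
#' @return A `nodule_spec` list.
#' @export
nodule_spec <- function(shape = c("disk", "ellipse", "lobulated"),
                        target_area_mm2 = 400, aspect = 1.5,
                        solid_hu = 40, ggo_hu = -450, background_hu = -800,
                        ggo_fraction = 0, bronchogram = NULL,
                        lobulation = 0.15,
                        noise_sd_sharp = 40, noise_sd_smooth = 15,
                        smooth_sigma_px = 1.5,
                        spacing_mm = 0.7, fov_px = 128, seed = 1) {
  shape <- match.arg(shape)
  stop_if_not_scalar(target_area_mm2, "target_area_mm2")
  if (target_area_mm2 <= 0) stop("target_area_mm2 must be > 0", call. = FALSE)
  stop_if_not_scalar(aspect, "aspect")
  if (aspect < 1) stop("aspect must be >= 1", call. = FALSE)
  stop_if_not_scalar(ggo_fraction, "ggo_fraction")
  if (ggo_fraction < 0 || ggo_fraction > 1) {
    stop("ggo_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd_sharp < 0 || noise_sd_smooth < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  structure(list(shape = shape, target_area_mm2 = target_area_mm2,
                 aspect = aspect, solid_hu = solid_hu, ggo_hu = ggo_hu,
                 background_hu = background_hu, ggo_fraction = ggo_fraction,
                 bronchogram = bronchogram, lobulation = lobulation,
                 noise_sd_sharp = noise_sd_sharp,
                 noise_sd_smooth = noise_sd_smooth,
                 smooth_sigma_px = smooth_sigma_px,
                 spacing_mm = spacing_mm, fov_px = fov_px,
                 seed = as.integer(seed)),
            class = "nodule_spec")
}

# Logical mask of the spec's shape scaled to enclose `area_mm2`, pixel-center
# rasterization. `phase` fixes the lobulation harmonics (drawn from the seed).
rasterize_shape <- function(spec, area_mm2, fov, s) {
  ctr <- (fov + 1) / 2
  g_r <- matrix(seq_len(fov), fov, fov)
  g_c <- matrix(seq_len(fov), fov, fov, byrow = TRUE)
  y <- (g_r - ctr) * s
  x <- (g_c - ctr) * s
  if (spec$shape == "disk") {
    r <- sqrt(area_mm2 / pi)
    return(x^2 + y^2 <= r^2)
  }
  if (spec$shape == "ellipse") {
    a <- sqrt(area_mm2 * spec$aspect / pi) # semi-major (along columns)
    b <- a / spec$aspect
    return(x^2 / a^2 + y^2 / b^2 <= 1)
  }
  # lobulated: star-convex boundary r(theta) = r0 (1 + sum_k a_k cos(k theta + phi_k)),
  # harmonics fixed by the spec seed; r0 iterated so the pixel count hits the target
  harm <- with_seed(spec$seed + 7L, list(
    k = 3:6,
    amp = stats::runif(4, 0.2, 1),
    phi = stats::runif(4, 0, 2 * pi)
  ))
  harm$amp <- harm$amp / sum(harm$amp) * spec$lobulation
  theta <- atan2(y, x)
  mod <- matrix(1, fov, fov)
  for (i in seq_along(harm$k)) {
    mod <- mod + harm$amp[i] * cos(harm$k[i] * theta + harm$phi[i])
  }
  r0 <- sqrt(area_mm2 / pi)
  rad2 <- x^2 + y^2
  target_px <- area_mm2 / s^2
  mask <- rad2 <= (r0 * mod)^2
  for (it in 1:8) {
    npx <- sum(mask)
    if (npx == 0) break
    r0 <- r0 * sqrt(target_px / npx)
    mask <- rad2 <= (r0 * mod)^2
    if (abs(sum(mask) - target_px) <= 1) break
  }
  mask
}

#' Generate a matched sharp/smooth nodule slice pair with ground truth
#'
#' Renders the specified nodule on lung background and returns two
#' reconstructions of the same scene: a `sharp` slice (1-mm thickness tag,
#' high-frequency kernel: the clean scene plus Gaussian noise of SD
#' `noise_sd_sharp`) and a `smooth` slice (5-mm thickness tag, standard kernel:
#' the scene blurred with a Gaussian of `smooth_sigma_px` pixels, then noise of
#' the smaller SD `noise_sd_smooth`), plus the ground-truth `roi_mask` (the
#' nodule pixels, with any air-bronchogram hole excluded). Deterministic in
#' `(spec, seed)`.
#'
#' @param spec A `nodule_spec`.
#' @return List with elements `sharp`, `smooth` (both `ct_slice`) and `truth`
#'   (`roi_mask`, seed at the nodule center).
#' @export
generate_nodule_pair <- function(spec) {
  stopifnot(inherits(spec, "nodule_spec"))
  s <- spec$spacing_mm
  fov <- spec$fov_px
  fov_area <- (fov * s)^2
  if (spec$target_area_mm2 > 0.25 * fov_area) {
    stop("nodule larger than the field of view allows", call. = FALSE)
  }
  shape <- rasterize_shape(spec, spec$target_area_mm2, fov, s)
  if (!any(shape)) stop("nodule rasterized to zero pixels", call. = FALSE)
  scene <- matrix(spec$background_hu, fov, fov)
  if (spec$ggo_fraction > 0) {
    core <- rasterize_shape(spec, spec$target_area_mm2 * (1 - spec$ggo_fraction),
                            fov, s)
    scene[shape] <- spec$ggo_hu
    scene[core & shape] <- spec$solid_hu
  } else {
    scene[shape] <- spec$solid_hu
  }
  truth <- shape
  if (!is.null(spec$bronchogram)) {
    bg <- spec$bronchogram
    ctr <- (fov + 1) / 2
    g_r <- matrix(seq_len(fov), fov, fov)
    g_c <- matrix(seq_len(fov), fov, fov, byrow = TRUE)
    off <- bg$offset_mm %||% c(0, 0)
    rr <- sqrt(bg$area_mm2 / pi)
    hole <- ((g_r - ctr) * s - off[1])^2 + ((g_c - ctr) * s - off[2])^2 <= rr^2
    hole <- hole & shape
    scene[hole] <- -1000
    truth <- truth & !hole
  }
  pair <- with_seed(spec$seed, {
    sharp_px <- scene +
      if (spec$noise_sd_sharp > 0) {
        matrix(stats::rnorm(fov^2, 0, spec$noise_sd_sharp), fov, fov)
      } else 0
    smooth_scene <- if (spec$smooth_sigma_px > 0) {
      EBImage::gblur(scene, sigma = spec$smooth_sigma_px, boundary = "replicate")
    } else scene
    smooth_px <- smooth_scene +
      if (spec$noise_sd_smooth > 0) {
        matrix(stats::rnorm(fov^2, 0, spec$noise_sd_smooth), fov, fov)
      } else 0
    list(sharp = sharp_px, smooth = smooth_px)
  })
  ctr_px <- as.integer(round((fov + 1) / 2))
  seed_px <- c(ctr_px, ctr_px)
  if (!truth[seed_px[1], seed_px[2]]) {
    # center may fall in a bronchogram hole; move the seed to the nearest truth pixel
    pts <- which(truth, arr.ind = TRUE)
    d2 <- (pts[, 1] - seed_px[1])^2 + (pts[, 2] - seed_px[2])^2
    seed_px <- as.integer(pts[which.min(d2), ])
  }
  list(
    sharp = ct_slice(pair$sharp, s, s, thickness_mm = 1, kernel = "sharp",
                     id = sprintf("phantom-%d-sharp", spec$seed)),
    smooth = ct_slice(pair$smooth, s, s, thickness_mm = 5, kernel = "standard",
                      id = sprintf("phantom-%d-smooth", spec$seed)),
    truth = roi_mask(truth, seed_px)
  )
}
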