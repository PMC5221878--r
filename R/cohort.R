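# Simulated patient cohort with the statistical structure the recurrence
# analysis assumes: tumor area and mean attenuation drive recurrence through a
# logistic model (default log-odds ln 1.002 per mm^2 and ln 1.005 per HU, the
# multivariable estimates of the source analysis), correlated geometry features
# are derived from area through shape draws, and a paired "5-mm" feature set is
# produced by ICC-targeted perturbation.

#' Specify a cohort simulation
#'
#' Feature marginals default to the observed 1-mm cohort summaries: area
#' lognormal with mean ~287 mm^2 and SD ~280 mm^2, mean attenuation normal with
#' mean -154 HU and SD 225 HU (truncated to plausible HU), circularity
#' beta-distributed around 0.475 +/- 0.15, aspect ratio 1 + gamma around
#' 1.46 +/- 0.34. The intercept `beta0`, when `NULL`, is calibrated so the
#' expected recurrence prevalence equals `target_prevalence` (default 25/194,
#' the source cohort's rate) under the feature distribution; the calibration is
#' deterministic and independent of `seed`.
#'
#' @param n Number of patients (>= 2).
#' @param beta_area Log-odds of recurrence per mm^2 of area
#'   (default `log(1.002)`).
#' @param beta_att Log-odds per HU of mean attenuation (default `log(1.005)`).
#' @param beta0 Intercept on the log-odds scale, or `NULL` to calibrate to
#'   `target_prevalence`.
#' @param target_prevalence Expected recurrence fraction used when `beta0` is
#'   `NULL`.
#' @param area_meanlog,area_sdlog Lognormal parameters of the area marginal.
#' @param att_mean,att_sd Normal parameters of the attenuation marginal (HU).
#' @param icc_targets Named numeric vector of per-feature ICC targets used to
#'   derive the 5-mm feature set (defaults to the thickness-agreement profile
#'   of the source analysis).
#' @param seed Integer RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 194,
                        beta_area = log(1.002), beta_att = log(1.005),
                        beta0 = NULL, target_prevalence = 25 / 194,
                        area_meanlog = 5.325, area_sdlog = 0.818,
                        att_mean = -154, att_sd = 225,
                        icc_targets = default_icc_targets(),
                        seed = 1) {
  stop_if_not_scalar(n, "n")
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  stop_if_not_scalar(beta_area, "beta_area")
  stop_if_not_scalar(beta_att, "beta_att")
  if (!is.null(beta0)) stop_if_not_scalar(beta0, "beta0")
  spec <- structure(
    list(n = as.integer(n), beta_area = beta_area, beta_att = beta_att,
         beta0 = beta0, target_prevalence = target_prevalence,
         area_meanlog = area_meanlog, area_sdlog = area_sdlog,
         att_mean = att_mean, att_sd = att_sd,
         icc_targets = icc_targets, seed = as.integer(seed)),
    class = "cohort_spec")
  if (is.null(spec$beta0)) spec$beta0 <- calibrate_intercept(spec)
  spec
}

#' Per-feature ICC targets of the thickness-agreement profile
#'
#' The default agreement profile used to derive the simulated 5-mm feature set:
#' size and attenuation features agree excellently, shape features substantially
#' and the histogram-shape features (skewness, kurtosis) only moderately.
#'
#' @return Named numeric vector over [feature_names()].
#' @export
default_icc_targets <- function() {
  c(diameter_mm = 0.98, perimeter_mm = 0.95, area_mm2 = 0.99,
    mean_attenuation_hu = 0.96, circularity = 0.71, aspect_ratio = 0.81,
    roundness = 0.80, skewness = 0.60, kurtosis = 0.53, entropy_bits = 0.85)
}

# Deterministic intercept calibration: solve E[plogis(b0 + beta.x)] = target
# over a fixed low-discrepancy sample of the feature marginals.
calibrate_intercept <- function(spec) {
  u <- (seq_len(4096) - 0.5) / 4096
  # independent quasi-random pairing via a fixed decorrelating permutation
  v <- (((seq_len(4096) * 2654435761) %% 2^32) + 0.5) / 2^32
  area <- stats::qlnorm(u, spec$area_meanlog, spec$area_sdlog)
  att <- pmax(-1000, pmin(150, stats::qnorm(v, spec$att_mean, spec$att_sd)))
  lp_part <- spec$beta_area * area + spec$beta_att * att
  f <- function(b0) mean(stats::plogis(b0 + lp_part)) - spec$target_prevalence
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Simulate a patient cohort
#'
#' Draws per-patient 1-mm features (area and mean attenuation from their
#' marginals; perimeter, diameter, aspect ratio and roundness derived from area
#' through circularity/ellipse-shape draws so the geometry is internally
#' consistent; skewness, kurtosis, entropy from their marginals), generates
#' recurrence as `Bernoulli(plogis(beta0 + beta_area*area + beta_att*att))`,
#' derives the paired 5-mm features with [perturb_for_thickness()] using the
#' spec's ICC targets, attaches follow-up times (recurrence times uniform on
#' 0.5-2.6 years, censoring on 0.6-3.5 years) and clinical covariates (age,
#' sex, smoking, stage, maxSUV). Fully reproducible from the spec seed.
#'
#' @param spec A `cohort_spec`.
#' @return A `data.frame`, one row per patient: `id`, `<feature>_1mm`,
#'   `<feature>_5mm`, `recurrence`, `time_years`, `event_observed`, and the
#'   clinical covariates.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  with_seed(spec$seed, {
    area <- stats::rlnorm(n, spec$area_meanlog, spec$area_sdlog)
    att <- pmax(-1000, pmin(150, stats::rnorm(n, spec$att_mean, spec$att_sd)))
    circ <- pmin(0.98, pmax(0.05, stats::rbeta(n, 4.79, 5.29)))
    aspect <- 1 + stats::rgamma(n, shape = 1.83, rate = 3.98)
    perimeter <- sqrt(4 * pi * area / circ)
    major <- 2 * sqrt(area * aspect / pi)
    diameter <- 1.10 * major # Feret slightly exceeds the ellipse major axis
    f1 <- data.frame(
      diameter_mm = diameter,
      perimeter_mm = perimeter,
      area_mm2 = area,
      mean_attenuation_hu = att,
      circularity = circ,
      aspect_ratio = aspect,
      roundness = 1 / aspect,
      skewness = stats::rnorm(n, -0.11, 0.90),
      kurtosis = pmax(-1.9, stats::rnorm(n, 1.2, 3.4)),
      entropy_bits = pmax(0.5, stats::rnorm(n, 6.78, 0.45))
    )
    lp <- spec$beta0 + spec$beta_area * area + spec$beta_att * att
    recurrence <- stats::rbinom(n, 1, stats::plogis(lp))
    f5 <- perturb_for_thickness(f1, spec$icc_targets)
    time_years <- ifelse(recurrence == 1,
                         stats::runif(n, 0.5, 2.6),
                         stats::runif(n, 0.6, 3.5))
    cohort <- data.frame(
      id = sprintf("P%04d", seq_len(n)),
      stats::setNames(f1, paste0(names(f1), "_1mm")),
      stats::setNames(f5, paste0(names(f5), "_5mm")),
      recurrence = recurrence,
      time_years = time_years,
      event_observed = recurrence,
      age = round(stats::rnorm(n, 61.3, 8.9), 1),
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(81, 113)),
      smoking = sample(c("never_ex", "current"), n, replace = TRUE,
                       prob = c(64, 130)),
      stage = sample(c(1L, 2L), n, replace = TRUE, prob = c(175, 19)),
      max_suv = pmax(0.5, stats::rnorm(n, 4.3, 2.9))
    )
    class(cohort) <- c("ct_cohort", "data.frame")
    cohort
  })
}

#' Perturb features to a target thickness-agreement profile
#'
#' Produces a "5-mm" feature set correlated with the input so that, over a
#' cohort, the per-feature ICC approaches its target. The additive noise
#' variance follows the variance-components identity
#' `ICC = var_between / (var_between + var_noise)`, i.e.
#' `var_noise = var_between * (1 - ICC) / ICC` with `var_between` estimated
#' from the input column. A target of 1 returns the column unchanged.
#'
#' @param features Data frame of feature columns (e.g. the ten canonical
#'   features), or a numeric vector.
#' @param icc_targets Named numeric vector of targets in `(0, 1]`; names must
#'   cover the feature columns (a single unnamed value is recycled for a
#'   vector input).
#' @return Object of the same shape as `features`.
#' @export
perturb_for_thickness <- function(features, icc_targets) {
  if (any(icc_targets <= 0 | icc_targets > 1)) {
    stop("ICC targets must lie in (0, 1]", call. = FALSE)
  }
  perturb_col <- function(x, target) {
    if (target == 1) return(x)
    v_between <- stats::var(x)
    x + stats::rnorm(length(x), 0, sqrt(v_between * (1 - target) / target))
  }
  if (is.numeric(features)) {
    stopifnot(length(icc_targets) == 1)
    return(perturb_col(features, icc_targets))
  }
  out <- features
  for (nm in names(features)) {
    if (!nm %in% names(icc_targets)) {
      stop("no ICC target supplied for feature '", nm, "'", call. = FALSE)
    }
    out[[nm]] <- perturb_col(features[[nm]], icc_targets[[nm]])
  }
  out
}

#' Read a cohort table from delimited text (or XLSX)
#'
#' Reads a per-patient cohort table and optionally renames columns through a
#' mapping, so an external patient-level file can be fed to the statistical
#' stage. CSV/TSV are read with base R; `.xlsx` requires the readxl package.
#'
#' @param path File path (`.csv`, `.tsv`/`.txt`, or `.xlsx`).
#' @param column_map Optional named character vector `c(internal = "external")`
#'   renaming external columns to the internal names.
#' @return A `data.frame`.
#' @export
read_cohort <- function(path, column_map = NULL) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = utils::read.csv(path),
    tsv = ,
    txt = utils::read.delim(path),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading .xlsx requires the 'readxl' package", call. = FALSE)
      }
      as.data.frame(readxl::read_excel(path))
    },
    stop("unsupported cohort file extension: ", ext, call. = FALSE)
  )
  if (!is.null(column_map)) {
    for (internal in names(column_map)) {
      ext_name <- column_map[[internal]]
      if (!ext_name %in% names(df)) {
        stop("column '", ext_name, "' not found in ", path, call. = FALSE)
      }
      names(df)[names(df) == ext_name] <- internal
    }
  }
  df
}
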