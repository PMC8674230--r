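#' Robust summary of a peak-intensity distribution
#'
#' Median, interquartile range, spread and saturation bookkeeping for the
#' spike-height distribution of one sample.  Saturated peaks are counted
#' (and a warning raised when they dominate, since a clipped distribution
#' is skewed) but retained here; size statistics exclude them via
#' [relative_diameters()].
#'
#' @param peaks A `cap_peaks` tibble.
#' @return One-row tibble: `median_fu`, `iqr_fu`, `sd_fu`, `n`,
#'   `saturated_fraction`.  All-NA sentinel (with `n = 0`) for an empty
#'   table.
#' @export
intensity_stats <- function(peaks) {
  if (nrow(peaks) == 0) {
    return(tibble::tibble(median_fu = NA_real_, iqr_fu = NA_real_,
                          sd_fu = NA_real_, n = 0L,
                          saturated_fraction = NA_real_))
  }
  h <- peaks$height_fu
  sat <- if ("saturated" %in% names(peaks)) {
    mean(peaks$saturated %in% TRUE)
  } else 0
  if (sat > 0.5) {
    warn("More than half of the peaks are saturated; the intensity distribution is clipped and skewed.")
  }
  tibble::tibble(
    median_fu = median(h),
    iqr_fu = unname(diff(quantile(h, c(0.25, 0.75), type = 7))),
    sd_fu = if (length(h) > 1) sd(h) else 0,
    n = length(h),
    saturated_fraction = sat
  )
}

#' Relative droplet diameters from spike heights
#'
#' Peak intensity scales with droplet volume, so relative diameters follow
#' as `height^(1/3)`, normalized to a median of 1.  Only relative (never
#' absolute) sizes are reported; saturated peaks are excluded (their true
#' height is unknown) with the excluded count recorded as an attribute.
#'
#' @param peaks A `cap_peaks` tibble.
#' @return Numeric vector of relative diameters (attribute
#'   `n_saturated_excluded`).
#' @export
relative_diameters <- function(peaks) {
  keep <- if ("saturated" %in% names(peaks)) !(peaks$saturated %in% TRUE)
          else rep(TRUE, nrow(peaks))
  h <- peaks$height_fu[keep]
  d <- h^(1 / 3)
  out <- if (length(d) > 0) d / median(d) else numeric(0)
  attr(out, "n_saturated_excluded") <- sum(!keep)
  out
}

#' Predicted relative signal-intensity distribution of monodisperse particles
#'
#' In laminar flow, a particle's integrated signal is proportional to its
#' residence time in the detection window, i.e. to the reciprocal of its
#' local velocity.  Taking the relative intensity `s = u_max / u(r) =
#' 1 / (1 - (r/R)^2)` (so the fastest, centreline particles have s = 1) and
#' pushing the radial density of [radial_pdf()] through this map gives the
#' relative intensity density of a monodisperse particle population:
#' a hard lower bound at s = 1, a mode just above it and a long right tail
#' from slow near-wall particles.
#'
#' @param mode `"empirical"` or `"poiseuille"` radial density.
#' @param n_grid Number of grid points (>= 100, default 512).
#' @param s_max Upper truncation of the relative intensity grid; the mass
#'   beyond it is returned as attribute `tail_mass`.
#' @return A tibble `s` (relative intensity), `density`; attributes
#'   `tail_mass`, `mode`.
#' @export
predicted_intensity_distribution <- function(mode = c("empirical", "poiseuille"),
                                             n_grid = 512, s_max = 20) {
  mode <- match.arg(mode)
  if (n_grid < 100) {
    warn("n_grid < 100 gives a coarse intensity grid; results may be inaccurate.")
  }
  s <- seq(1, s_max, length.out = n_grid)
  tibble::tibble(s = s, density = intensity_pdf(s, mode)) |>
    structure(tail_mass = 1 - intensity_cdf(s_max, mode), mode = mode)
}

# density of s = 1/(1 - x^2) under the radial density; change of variables
# x = sqrt(1 - 1/s), dx/ds = 1 / (2 x s^2)
intensity_pdf <- function(s, mode) {
  out <- numeric(length(s))
  ok <- s > 1
  x <- sqrt(1 - 1 / s[ok])
  out[ok] <- radial_pdf(x, mode) / (2 * x * s[ok]^2)
  out
}

#' @rdname predicted_intensity_distribution
#' @param s Relative intensity values (>= 1).
#' @return `intensity_cdf()`: `P(S <= s)`.
#' @export
intensity_cdf <- function(s, mode = c("empirical", "poiseuille")) {
  mode <- match.arg(mode)
  ifelse(s <= 1, 0, radial_cdf(sqrt(pmax(1 - 1 / s, 0)), mode))
}

# draw relative intensities from the flow model
sample_relative_intensity <- function(n, mode) {
  x <- sample_relative_radius(n, mode)
  1 / (1 - x^2)
}

#' Fit the flow model to monodisperse-sphere calibration heights
#'
#' Observed spike heights of monodisperse calibration spheres are modelled
#' as `h = scale * s * b`, where `s` follows the flow-model intensity
#' distribution ([predicted_intensity_distribution()]) and `b` is a
#' lognormal intrinsic-brightness factor with mean 1 and coefficient of
#' variation `brightness_cv` (accounting for sphere-to-sphere fluorescence
#' variability; with `brightness_cv = 0` the pure flow model is used and
#' no observation can fall below `scale`).  The single intensity scale is
#' fitted by maximum likelihood; goodness of fit is reported as the
#' Kolmogorov-Smirnov distance between the observed heights and the fitted
#' model CDF.
#'
#' @param observed_heights_fu At least 50 observed spike heights, FU.
#' @param brightness_cv Coefficient of variation of intrinsic brightness
#'   (>= 0).
#' @param mode Radial density mode.
#' @param s_max Truncation of the intensity grid used for the likelihood.
#' @return A list: `scale_fu`, `loglik`, `ks_statistic`, `ks_p_value`,
#'   `n`, `brightness_cv`, `mode`, and `cdf` (the fitted model CDF
#'   function).
#' @export
fit_sphere_calibration <- function(observed_heights_fu, brightness_cv,
                                   mode = c("empirical", "poiseuille"),
                                   s_max = 30) {
  mode <- match.arg(mode)
  h <- observed_heights_fu
  if (length(h) < 50) {
    abort("At least 50 observed heights are required.",
          class = "capflowr_insufficient_data_error")
  }
  if (diff(range(h)) == 0) {
    abort("Degenerate observations: all heights equal.",
          class = "capflowr_fit_error")
  }
  if (brightness_cv < 0) {
    abort("brightness_cv must be >= 0.", class = "capflowr_validation_error")
  }
  # quadrature grid over s with analytic bin masses
  edges <- exp(seq(log(1 + 1e-9), log(s_max), length.out = 601))
  mass <- diff(intensity_cdf(edges, mode))
  mass <- c(mass, 1 - intensity_cdf(s_max, mode)) # lump the tail
  s_mid <- c(sqrt(edges[-1] * edges[-length(edges)]), s_max)
  sdlog <- sqrt(log(1 + brightness_cv^2))
  meanlog <- -sdlog^2 / 2 # brightness has mean 1

  density_h <- function(hv, scale) {
    if (brightness_cv == 0) {
      d <- intensity_pdf(hv / scale, mode) / scale
    } else {
      d <- vapply(hv, function(hi) {
        sum(mass * stats::dlnorm(hi / (scale * s_mid), meanlog, sdlog) /
              (scale * s_mid))
      }, numeric(1))
    }
    pmax(d, 1e-300)
  }
  cdf_h <- function(q, scale) {
    if (brightness_cv == 0) {
      intensity_cdf(q / scale, mode)
    } else {
      vapply(q, function(qi) {
        sum(mass * stats::plnorm(qi / (scale * s_mid), meanlog, sdlog))
      }, numeric(1))
    }
  }
  nll <- function(log_scale) -sum(log(density_h(h, exp(log_scale))))
  # h = scale * s * b with s >= 1, so scale is at most min(h) / min(b)-ish
  lo <- log(min(h) / 10)
  hi <- log(max(h))
  opt <- optimize(nll, c(lo, hi), tol = 1e-8)
  scale <- exp(opt$minimum)
  ks <- suppressWarnings(stats::ks.test(h, function(q) cdf_h(q, scale)))
  list(scale_fu = scale, loglik = -opt$objective,
       ks_statistic = unname(ks$statistic), ks_p_value = ks$p.value,
       n = length(h), brightness_cv = brightness_cv, mode = mode,
       cdf = function(q) cdf_h(q, scale))
}
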