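# Synthetic single-plane-wave channel-data simulator.
#
# Provides realistic inputs (point targets, diffuse speckle, electronic
# noise) for the removal sweep and the mock networks without external
# datasets. Scattering is linear single-scattering; the impulse response is
# a Gaussian-windowed sinusoid; element directivity and attenuation are not
# modeled.

#' Scatterer phantom
#'
#' @param scatterers data frame with columns `x`, `z` (meters, `z > 0`) and
#'   `amplitude` (unitless reflectivity).
#' @param pulse_center_freq transmit pulse center frequency in Hz.
#' @param pulse_fractional_bandwidth -6 dB fractional bandwidth of the
#'   Gaussian pulse envelope (0 < bw < 2, default 0.6).
#' @param noise_std standard deviation of additive i.i.d. Gaussian
#'   electronic noise per sample (>= 0).
#' @return an object of class `phantom`.
#' @export
phantom <- function(scatterers, pulse_center_freq = 5.208e6,
                    pulse_fractional_bandwidth = 0.6, noise_std = 0) {
  sc <- as.data.frame(scatterers)
  if (!all(c("x", "z", "amplitude") %in% names(sc))) {
    stop_validation("scatterers needs columns x, z, amplitude")
  }
  if (nrow(sc) > 0) {
    if (any(!is.finite(sc$x)) || any(!is.finite(sc$z)) ||
        any(!is.finite(sc$amplitude))) {
      stop_validation("scatterer fields must be finite")
    }
    if (any(sc$z <= 0)) stop_validation("scatterer depths must be > 0")
  }
  bw <- pulse_fractional_bandwidth
  if (!is_scalar_number(bw) || bw <= 0 || bw >= 2) {
    stop_validation("pulse_fractional_bandwidth must be in (0, 2)")
  }
  if (!is_scalar_number(noise_std) || noise_std < 0) {
    stop_validation("noise_std must be >= 0")
  }
  structure(
    list(scatterers = sc, pulse_center_freq = pulse_center_freq,
         pulse_fractional_bandwidth = bw, noise_std = noise_std),
    class = "phantom"
  )
}

#' Point-target phantom
#'
#' @param positions matrix or data frame of `(x, z)` positions in meters;
#'   all scatterers get unit amplitude.
#' @param ... passed on to [phantom()].
#' @return a [phantom()].
#' @export
make_point_phantom <- function(positions, ...) {
  p <- as.data.frame(positions)
  if (nrow(p) == 0L) stop_validation("positions must be nonempty")
  names(p)[1:2] <- c("x", "z")
  phantom(data.frame(x = p$x, z = p$z, amplitude = 1), ...)
}

#' Diffuse speckle phantom
#'
#' Fills a rectangular region with sub-resolution scatterers whose
#' amplitudes are i.i.d. standard normal, at a density of at least
#' `density` scatterers per resolution cell so that the beamformed envelope
#' is fully developed speckle (Rayleigh statistics, std/mean about 0.52).
#'
#' @param region `c(xmin, xmax, zmin, zmax)` in meters, nonempty, `z > 0`.
#' @param density scatterers per resolution cell (default 10).
#' @param seed RNG seed; identical seeds give identical scatterer sets.
#' @param cell nominal resolution-cell dimensions `c(lateral, axial)` in
#'   meters used to convert `density` to a count. The default
#'   `c(0.3e-3, 0.2e-3)` matches a 5.2 MHz array: one wavelength laterally
#'   and the two-way FWHM of the default 0.6-fractional-bandwidth pulse
#'   axially.
#' @param ... passed on to [phantom()].
#' @return a [phantom()].
#' @export
make_speckle_phantom <- function(region, density = 10, seed = 0L,
                                 cell = c(0.3e-3, 0.2e-3), ...) {
  region <- as.double(region)
  if (length(region) != 4L || region[2] <= region[1] ||
      region[4] <= region[3]) {
    stop_validation("region must be c(xmin, xmax, zmin, zmax) with positive area")
  }
  if (region[3] <= 0) stop_validation("region depths must be > 0")
  area <- (region[2] - region[1]) * (region[4] - region[3])
  n <- ceiling(density * area / (cell[1] * cell[2]))
  sc <- with_seed(seed, {
    data.frame(x = stats::runif(n, region[1], region[2]),
               z = stats::runif(n, region[3], region[4]),
               amplitude = stats::rnorm(n))
  })
  phantom(sc, ...)
}

#' Simulate single 0-degree plane-wave channel data
#'
#' For each element `e` the received signal is the superposition
#' `sum_k a_k p(t - tau_ke)` of Gaussian-windowed sinusoid echoes, where
#' `tau_ke` is the same two-way delay used by [compute_delays()] (the
#' simulator and beamformer share one delay routine), plus optional i.i.d.
#' Gaussian electronic noise. Reproducible given `seed`.
#'
#' The pulse is `p(t) = exp(-t^2 / (2 sigma^2)) cos(2 pi fc t)` with
#' `sigma = sqrt(2 log 2) / (pi bw fc)`, which gives the requested -6 dB
#' fractional bandwidth `bw`.
#'
#' @param phantom a [phantom()].
#' @param geom an [array_geometry()].
#' @param fs sampling frequency in Hz.
#' @param c sound speed in m/s.
#' @param n_samples recorded samples per element; should cover the deepest
#'   scatterer's round trip (a warning and a `truncated` attribute are
#'   raised otherwise).
#' @param seed RNG seed for the noise draw.
#' @param t0 time of the first sample (s).
#' @param tx_angle plane-wave steering angle in radians.
#' @return a [channel_data()] object; attribute `truncated` is `TRUE` when
#'   an echo ran off the end of the recording window.
#' @export
simulate_channel_data <- function(phantom, geom, fs = 20.832e6, c = 1540,
                                  n_samples = 2048, seed = 0L, t0 = 0,
                                  tx_angle = 0) {
  stopifnot(inherits(phantom, "phantom"))
  validate_array_geometry(geom)
  n_el <- geom$n_elements
  n_samples <- as.integer(n_samples)
  s <- matrix(0, n_el, n_samples)
  sc <- phantom$scatterers
  truncated <- FALSE

  if (nrow(sc) > 0) {
    fc <- phantom$pulse_center_freq
    sigma <- sqrt(2 * log(2)) / (pi * phantom$pulse_fractional_bandwidth * fc)
    half <- 4 * sigma
    L <- ceiling(2 * half * fs) + 1L
    tau <- delay_point(sc$x, sc$z, geom$element_x, tx_angle, c)
    t_end <- t0 + (n_samples - 1) / fs
    if (any(tau + half > t_end)) {
      truncated <- TRUE
      warning("echo round trip exceeds the recording window; truncated")
    }
    offs <- 0:(L - 1L)
    for (k in seq_len(nrow(sc))) {
      tk <- tau[k, ]                       # per-element delay
      s0 <- ceiling((tk - half - t0) * fs) # first support sample, 0-based
      idx <- outer(s0, offs, `+`)          # [n_el, L] sample indices
      tt <- t0 + idx / fs - tk             # time relative to echo center
      val <- sc$amplitude[k] * exp(-tt^2 / (2 * sigma^2)) * cospi(2 * fc * tt)
      keep <- idx >= 0L & idx <= (n_samples - 1L)
      if (any(keep)) {
        lin <- row(idx)[keep] + idx[keep] * n_el  # column-major linear index
        s[lin] <- s[lin] + val[keep]
      }
    }
  }

  if (phantom$noise_std > 0) {
    s <- s + with_seed(seed, {
      matrix(stats::rnorm(n_el * n_samples, 0, phantom$noise_std),
             n_el, n_samples)
    })
  }

  out <- channel_data(s, sampling_rate = fs, sound_speed = c,
                      demod_freq = 0, tx_angle = tx_angle, t0 = t0)
  attr(out, "truncated") <- truncated
  out
}
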