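# Reference 0-degree plane-wave delay-and-sum (DAS) beamformer.
#
# This is the ground-truth image generator: every network-under-test is
# judged against its output on the identical input data.

#' Beamformer configuration
#'
#' @param apodization `"uniform"` (all-ones receive weighting, the default)
#'   or `"fnumber-masked"` (elements outside the f-number aperture get zero
#'   weight).
#' @param f_number depth-to-aperture ratio used when
#'   `apodization = "fnumber-masked"` (> 0).
#' @param interpolation sampling rule at delayed times; only `"linear"` is
#'   provided.
#' @param out_of_bounds_value contribution of delays falling outside the
#'   recording window (0).
#' @return an object of class `beamform_config`.
#' @export
beamform_config <- function(apodization = c("uniform", "fnumber-masked"),
                            f_number = 1, interpolation = "linear",
                            out_of_bounds_value = 0) {
  apodization <- match.arg(apodization)
  if (apodization == "fnumber-masked" &&
      (!is_scalar_number(f_number) || f_number <= 0)) {
    stop_validation("f_number must be > 0 when apodization is fnumber-masked")
  }
  interpolation <- match.arg(interpolation)
  structure(
    list(apodization = apodization, f_number = f_number,
         interpolation = interpolation,
         out_of_bounds_value = out_of_bounds_value),
    class = "beamform_config"
  )
}

# Two-way plane-wave travel time from the transmit wavefront to point
# (x, z) and back to element xe: (z cos(th) + x sin(th) + sqrt((x-xe)^2 +
# z^2)) / c. Vectorized over points; one column per element. Shared by the
# beamformer and the simulator so the two can never disagree.
delay_point <- function(x, z, element_x, angle, c) {
  if (!is_scalar_number(c) || c <= 0) stop_validation("sound speed must be > 0")
  tx <- z * cos(angle) + x * sin(angle)
  n_el <- length(element_x)
  d <- matrix(0, length(x), n_el)
  for (e in seq_len(n_el)) {
    d[, e] <- (tx + sqrt((x - element_x[e])^2 + z^2)) / c
  }
  d
}

#' Per-pixel-per-element DAS delay table
#'
#' Computes the two-way travel time for a 0-degree-capable plane-wave
#' transmit: the wavefront reaches pixel `(x, z)` at
#' `(z cos(theta) + x sin(theta)) / c` and the echo returns to element `e`
#' after `sqrt((x - x_e)^2 + z^2) / c`.
#'
#' Pixels are flattened column-major from the `[row = z, column = x]` image
#' layout, i.e. depth varies fastest.
#'
#' @param grid an [imaging_grid()].
#' @param geom an [array_geometry()].
#' @param angle plane-wave steering angle in radians (default 0).
#' @param c sound speed in m/s (> 0).
#' @return numeric matrix `[n_pixels, n_elements]` of delays in seconds.
#' @export
compute_delays <- function(grid, geom, angle = 0, c = 1540) {
  nz <- length(grid$z); nx <- length(grid$x)
  Z <- rep(grid$z, times = nx)
  X <- rep(grid$x, each = nz)
  delay_point(X, Z, geom$element_x, angle, c)
}

#' Delay-and-sum beamforming of plane-wave channel data
#'
#' Forms the analytic signal of each channel (Hilbert transform along time
#' for RF; complex IQ is used directly with a `demod_freq` phase rotation),
#' samples each channel at its per-pixel delay with linear interpolation
#' (delays outside the recording window contribute 0), applies the receive
#' apodization, sums across elements, takes the magnitude, and normalizes
#' by the global maximum. If the pre-normalization image is numerically
#' zero everywhere (max <= 1e-30) the image is returned as zeros with the
#' `degenerate` flag set rather than dividing by zero.
#'
#' @param data a [channel_data()] object.
#' @param geom the matching [array_geometry()].
#' @param grid the reconstruction [imaging_grid()].
#' @param cfg a [beamform_config()].
#' @param delays optional precomputed [compute_delays()] table (reused
#'   across calls that share `grid`, `geom`, angle and sound speed).
#' @return an [envelope_image()] with values in `[0, 1]`.
#' @examples
#' cfg <- default_config(n_elements = 16, n_samples = 512,
#'                       z_range = c(5e-3, 15e-3))
#' probe <- make_zeros_input(artificial_input_spec("zeros", c(16, 512)))
#' env <- beamform_das(probe, cfg$geom, cfg$grid)
#' @export
beamform_das <- function(data, geom, grid, cfg = beamform_config(),
                         delays = NULL) {
  validate_channel_data(data, geom)
  s <- data$samples
  n_el <- nrow(s); n_t <- ncol(s)
  if (is.null(delays)) {
    delays <- compute_delays(grid, geom, data$tx_angle, data$sound_speed)
  }
  nz <- length(grid$z); nx <- length(grid$x)
  n_px <- nz * nx
  if (nrow(delays) != n_px || ncol(delays) != n_el) {
    stop_validation("delay table shape does not match grid/geometry")
  }

  iq <- is.complex(s)
  fs <- data$sampling_rate

  # apodization weights [n_pixels, n_elements]
  if (cfg$apodization == "fnumber-masked") {
    Z <- rep(grid$z, times = nx)
    X <- rep(grid$x, each = nz)
  }

  acc <- complex(real = numeric(n_px), imaginary = numeric(n_px))
  for (e in seq_len(n_el)) {
    ch <- if (iq) s[e, ] else analytic_signal(s[e, ])
    # fractional sample position of the delayed time
    pos <- (delays[, e] - data$t0) * fs
    i0 <- floor(pos)
    w <- pos - i0
    inb <- i0 >= 0 & i0 <= (n_t - 2)
    v <- complex(real = numeric(n_px))
    if (any(inb)) {
      ii <- i0[inb] + 1L
      v[inb] <- ch[ii] * (1 - w[inb]) + ch[ii + 1L] * w[inb]
      if (iq && data$demod_freq > 0) {
        v[inb] <- v[inb] * exp(2i * pi * data$demod_freq * delays[inb, e])
      }
    }
    if (cfg$apodization == "fnumber-masked") {
      apod <- as.numeric(abs(X - geom$element_x[e]) <=
                           Z / (2 * cfg$f_number))
      v <- v * apod
    }
    acc <- acc + v
  }

  env <- matrix(Mod(acc), nz, nx)
  m <- max(env)
  if (m <= 1e-30) {
    envelope_image(matrix(0, nz, nx), normalization_max = m,
                   degenerate = TRUE)
  } else {
    envelope_image(env / m, normalization_max = m, degenerate = FALSE)
  }
}

#' Log compression of a normalized envelope image
#'
#' `db = 20 log10(max(values, 10^(-DR/20)))`, clipped to
#' `[-dynamic_range, 0]`; a pixel of value 1 maps to 0 dB.
#'
#' @param env an [envelope_image()].
#' @param dynamic_range displayed dynamic range in dB (> 0, default 60).
#' @return a [bmode_image()].
#' @export
log_compress <- function(env, dynamic_range = 60) {
  if (!is_scalar_number(dynamic_range) || dynamic_range <= 0) {
    stop_validation("dynamic_range must be > 0")
  }
  v <- if (inherits(env, "envelope_image")) env$values else env
  floor_lin <- 10^(-dynamic_range / 20)
  db <- 20 * log10(pmax(v, floor_lin))
  bmode_image(db, dynamic_range)
}
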