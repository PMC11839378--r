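# Artificial channel-data probes: zeros, ones, Gaussian noise, custom.
#
# These inputs are intentionally unrealistic: a network that truly
# beamforms must map them to the predictable images a conventional
# delay-and-sum beamformer produces, while a memorizing network betrays
# itself by reproducing training imagery instead.

#' Specification of an artificial channel-data probe
#'
#' @param kind one of `"zeros"`, `"ones"`, `"gaussian"`, `"custom"`.
#' @param shape integer vector `c(n_elements, n_samples)`.
#' @param epsilon near-zero fill constant replacing exact zeros so that
#'   max-normalization of the resulting image stays well defined
#'   (default 1e-20; must be positive and < 1e-10).
#' @param seed RNG seed, used by the Gaussian probe only (default 0).
#' @param gaussian_mean,gaussian_sd parameters of the Gaussian draw before
#'   min-max normalization (defaults 0 and 1).
#' @param values user-supplied matrix for `kind = "custom"`; values must lie
#'   in `[0, 1]`.
#' @return an object of class `artificial_input_spec`.
#' @export
artificial_input_spec <- function(kind = c("zeros", "ones", "gaussian", "custom"),
                                  shape, epsilon = 1e-20, seed = 0L,
                                  gaussian_mean = 0, gaussian_sd = 1,
                                  values = NULL) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(is.na(shape)) || any(shape < 1L)) {
    stop_validation("shape must be two integers >= 1")
  }
  if (!is_scalar_number(epsilon) || epsilon <= 0 || epsilon >= 1e-10) {
    stop_validation("epsilon must satisfy 0 < epsilon < 1e-10")
  }
  if (kind == "custom") {
    if (is.null(values) || !is.matrix(values)) {
      stop_validation("custom probe requires a values matrix")
    }
    if (!all(dim(values) == shape)) {
      stop_validation("custom values shape does not match spec shape")
    }
    if (any(!is.finite(values)) || any(values < 0) || any(values > 1)) {
      stop_validation("custom values must be finite and in [0, 1]")
    }
  }
  structure(
    list(kind = kind, shape = shape, epsilon = epsilon,
         seed = as.integer(seed), gaussian_mean = gaussian_mean,
         gaussian_sd = gaussian_sd, values = values),
    class = "artificial_input_spec"
  )
}

# Wrap a probe matrix in a channel_data object with the given acquisition
# constants (defaults mirror default_config()).
probe_channel_data <- function(samples, sampling_rate = 20.832e6,
                               sound_speed = 1540, t0 = 0) {
  channel_data(samples, sampling_rate = sampling_rate,
               sound_speed = sound_speed, demod_freq = 0,
               tx_angle = 0, t0 = t0)
}

#' Artificial probe generators
#'
#' `make_zeros_input()` fills the matrix with the near-zero `epsilon` and
#' sets the single center sample (index `floor(dim / 2)` on each 0-based
#' axis) to 1; the reference beamformer maps it to the point spread
#' function of that sample. `make_ones_input()` is its complement: all ones
#' with the center sample set to `epsilon`; the reference image is nearly
#' uniformly bright. `make_gaussian_input()` draws i.i.d. Gaussian samples
#' and min-max normalizes the whole matrix to `[0, 1]`, reproducibly given
#' `spec$seed`. `make_custom_input()` wraps a user-supplied matrix, letting
#' evaluators run private probe patterns.
#'
#' @param spec an [artificial_input_spec()] with the matching `kind`.
#' @param sampling_rate,sound_speed,t0 acquisition constants attached to
#'   the returned object (defaults mirror [default_config()]).
#' @return a [channel_data()] object of the requested shape.
#' @examples
#' z <- make_zeros_input(artificial_input_spec("zeros", c(8, 16)))
#' which(z$samples == 1, arr.ind = TRUE)  # the center sample
#' @export
make_zeros_input <- function(spec, sampling_rate = 20.832e6,
                             sound_speed = 1540, t0 = 0) {
  stopifnot(inherits(spec, "artificial_input_spec"))
  if (spec$kind != "zeros") stop_validation("spec kind must be \"zeros\"")
  s <- matrix(spec$epsilon, spec$shape[1], spec$shape[2])
  s[center_index(spec$shape[1]), center_index(spec$shape[2])] <- 1
  probe_channel_data(s, sampling_rate, sound_speed, t0)
}

#' @rdname make_zeros_input
#' @export
make_ones_input <- function(spec, sampling_rate = 20.832e6,
                            sound_speed = 1540, t0 = 0) {
  stopifnot(inherits(spec, "artificial_input_spec"))
  if (spec$kind != "ones") stop_validation("spec kind must be \"ones\"")
  s <- matrix(1, spec$shape[1], spec$shape[2])
  s[center_index(spec$shape[1]), center_index(spec$shape[2])] <- spec$epsilon
  probe_channel_data(s, sampling_rate, sound_speed, t0)
}

#' @rdname make_zeros_input
#' @export
make_gaussian_input <- function(spec, sampling_rate = 20.832e6,
                                sound_speed = 1540, t0 = 0) {
  stopifnot(inherits(spec, "artificial_input_spec"))
  if (spec$kind != "gaussian") stop_validation("spec kind must be \"gaussian\"")
  n <- prod(spec$shape)
  draw <- with_seed(spec$seed, {
    matrix(stats::rnorm(n, spec$gaussian_mean, spec$gaussian_sd),
           spec$shape[1], spec$shape[2])
  })
  rng <- range(draw)
  if (rng[2] - rng[1] <= 0) {
    stop_validation("degenerate all-equal Gaussian draw; cannot normalize")
  }
  s <- (draw - rng[1]) / (rng[2] - rng[1])
  probe_channel_data(s, sampling_rate, sound_speed, t0)
}

#' @rdname make_zeros_input
#' @export
make_custom_input <- function(spec, sampling_rate = 20.832e6,
                              sound_speed = 1540, t0 = 0) {
  stopifnot(inherits(spec, "artificial_input_spec"))
  if (spec$kind != "custom") stop_validation("spec kind must be \"custom\"")
  probe_channel_data(spec$values, sampling_rate, sound_speed, t0)
}

#' @rdname make_zeros_input
#' @export
make_artificial_input <- function(spec, sampling_rate = 20.832e6,
                                  sound_speed = 1540, t0 = 0) {
  switch(spec$kind,
         zeros = make_zeros_input(spec, sampling_rate, sound_speed, t0),
         ones = make_ones_input(spec, sampling_rate, sound_speed, t0),
         gaussian = make_gaussian_input(spec, sampling_rate, sound_speed, t0),
         custom = make_custom_input(spec, sampling_rate, sound_speed, t0))
}

# Evaluate expr with a local, restored RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
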