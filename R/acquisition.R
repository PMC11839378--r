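# Core data model: array geometry, channel data, imaging grid, images,
# container-file readers/writers, and the default acquisition configuration.

#' Linear-array geometry
#'
#' Describes the lateral element-center positions of a 1-D linear array.
#' Positions must be strictly increasing, uniformly spaced, and symmetric
#' about x = 0 (the array center defines the lateral origin).
#'
#' @param n_elements number of elements (>= 1). Ignored when `element_x` is
#'   given.
#' @param pitch element spacing in meters (> 0).
#' @param element_x optional explicit element positions in meters; must be
#'   uniformly spaced by `pitch` and symmetric about 0.
#' @return an object of class `array_geometry` with fields `element_x`,
#'   `n_elements`, `pitch`.
#' @examples
#' geom <- array_geometry(128, pitch = 0.3e-3)
#' range(geom$element_x)
#' @export
array_geometry <- function(n_elements, pitch, element_x = NULL) {
  if (!is_scalar_number(pitch) || pitch <= 0) {
    stop_validation("pitch must be a positive number, got %s", format(pitch))
  }
  if (is.null(element_x)) {
    n_elements <- as.integer(n_elements)
    if (is.na(n_elements) || n_elements < 1L) {
      stop_validation("n_elements must be >= 1")
    }
    element_x <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch
  }
  geom <- structure(
    list(element_x = as.double(element_x),
         n_elements = length(element_x),
         pitch = as.double(pitch)),
    class = "array_geometry"
  )
  validate_array_geometry(geom)
}

#' @rdname array_geometry
#' @param geom an `array_geometry` object.
#' @export
validate_array_geometry <- function(geom) {
  ex <- geom$element_x
  if (length(ex) < 1L) stop_validation("geometry needs >= 1 element")
  if (any(!is.finite(ex))) stop_validation("element_x must be finite")
  if (length(ex) > 1L) {
    d <- diff(ex)
    if (any(d <= 0)) stop_validation("element_x must be strictly increasing")
    if (any(abs(d - geom$pitch) > 1e-9)) {
      stop_validation("element spacing deviates from pitch by more than 1e-9 m")
    }
  }
  if (abs(ex[1] + ex[length(ex)]) > 1e-9) {
    stop_validation("element_x must be symmetric about 0 within 1e-9 m")
  }
  geom
}

#' Raw channel data from a single plane-wave transmission
#'
#' Holds the per-element received signals plus the acquisition parameters
#' needed to beamform them. Samples may be real RF (`demod_freq = 0`) or
#' complex baseband IQ (`demod_freq > 0`). Sample `k` (0-based) corresponds
#' to time `t0 + k / sampling_rate`.
#'
#' @param samples numeric or complex matrix `[n_elements, n_samples]`.
#' @param sampling_rate sampling frequency in Hz (> 0).
#' @param sound_speed assumed medium sound speed in m/s (> 0).
#' @param demod_freq demodulation frequency in Hz; 0 for RF data.
#' @param tx_angle plane-wave transmit steering angle in radians (0 here).
#' @param t0 time of the first sample in seconds.
#' @return an object of class `channel_data`.
#' @export
channel_data <- function(samples, sampling_rate, sound_speed = 1540,
                         demod_freq = 0, tx_angle = 0, t0 = 0) {
  if (!is.matrix(samples)) stop_validation("samples must be a matrix")
  cd <- structure(
    list(samples = samples,
         sampling_rate = as.double(sampling_rate),
         sound_speed = as.double(sound_speed),
         demod_freq = as.double(demod_freq),
         tx_angle = as.double(tx_angle),
         t0 = as.double(t0)),
    class = "channel_data"
  )
  validate_channel_data(cd)
}

#' @rdname channel_data
#' @param data a `channel_data` object.
#' @param geom optional `array_geometry`; when given, the first dimension of
#'   `samples` must equal `geom$n_elements`.
#' @export
validate_channel_data <- function(data, geom = NULL) {
  s <- data$samples
  if (any(!is.finite(s))) stop_validation("samples must be finite")
  if (!is_scalar_number(data$sampling_rate) || data$sampling_rate <= 0) {
    stop_validation("sampling_rate must be > 0")
  }
  if (!is_scalar_number(data$sound_speed) || data$sound_speed <= 0) {
    stop_validation("sound_speed must be > 0")
  }
  if (!is_scalar_number(data$demod_freq) || data$demod_freq < 0) {
    stop_validation("demod_freq must be >= 0")
  }
  if (!is.null(geom) && nrow(s) != geom$n_elements) {
    stop_validation("samples has %d rows but geometry has %d elements",
                    nrow(s), geom$n_elements)
  }
  data
}

#' Rectangular imaging grid
#'
#' Pixel coordinates of the reconstruction grid: `x` lateral (array axis),
#' `z` axial depth, both in meters, both strictly increasing, depths
#' positive. Images on this grid are indexed `[row = z, column = x]`.
#'
#' @param x lateral pixel coordinates (meters).
#' @param z axial pixel coordinates (meters, all > 0).
#' @return an object of class `imaging_grid`.
#' @export
imaging_grid <- function(x, z) {
  x <- as.double(x); z <- as.double(z)
  if (length(x) < 1L || length(z) < 1L) stop_validation("empty grid axis")
  if (any(!is.finite(x)) || any(!is.finite(z))) {
    stop_validation("grid coordinates must be finite")
  }
  if (length(x) > 1L && any(diff(x) <= 0)) {
    stop_validation("grid x must be strictly increasing")
  }
  if (length(z) > 1L && any(diff(z) <= 0)) {
    stop_validation("grid z must be strictly increasing")
  }
  if (any(z <= 0)) stop_validation("grid z must be positive (depth)")
  structure(list(x = x, z = z), class = "imaging_grid")
}

#' Normalized envelope image
#'
#' Envelope-detected image on an imaging grid, normalized by its global
#' maximum so values lie in `[0, 1]`. `normalization_max` records the
#' pre-normalization maximum; `degenerate` flags an all-(near-)zero image
#' that could not be normalized (returned as zeros instead of dividing by
#' zero).
#'
#' @param values nonnegative matrix `[length(z), length(x)]` with entries in
#'   `[0, 1]`.
#' @param normalization_max pre-normalization global maximum.
#' @param degenerate logical degenerate-normalization flag.
#' @return an object of class `envelope_image`.
#' @export
envelope_image <- function(values, normalization_max, degenerate = FALSE) {
  if (!is.matrix(values)) stop_validation("values must be a matrix")
  if (any(!is.finite(values))) stop_validation("envelope values must be finite")
  if (any(values < 0) || any(values > 1)) {
    stop_validation("envelope values must lie in [0, 1]")
  }
  structure(
    list(values = values,
         normalization_max = as.double(normalization_max),
         degenerate = isTRUE(degenerate)),
    class = "envelope_image"
  )
}

#' Log-compressed B-mode image
#'
#' @param db_values matrix of decibel values in `[-dynamic_range, 0]`.
#' @param dynamic_range displayed dynamic range in dB (> 0, default 60).
#' @return an object of class `bmode_image`.
#' @export
bmode_image <- function(db_values, dynamic_range = 60) {
  if (!is_scalar_number(dynamic_range) || dynamic_range <= 0) {
    stop_validation("dynamic_range must be > 0")
  }
  if (any(!is.finite(db_values))) stop_validation("db_values must be finite")
  if (any(db_values > 1e-12) || any(db_values < -dynamic_range - 1e-12)) {
    stop_validation("db_values must lie in [-dynamic_range, 0]")
  }
  structure(
    list(db_values = db_values, dynamic_range = as.double(dynamic_range)),
    class = "bmode_image"
  )
}

# Fields of the channel-data container schema, with scalar/matrix markers.
.container_fields <- c("samples", "element_x", "sampling_rate",
                       "sound_speed", "demod_freq", "tx_angle", "t0")

#' Write channel data to a container file
#'
#' Serializes a (`channel_data`, `array_geometry`) pair to a single-file
#' container with named fields `samples`, `element_x`, `sampling_rate`,
#' `sound_speed`, `demod_freq`, `tx_angle`, `t0`. The round trip through
#' [read_channel_data()] is lossless (complex IQ included).
#'
#' @param data a `channel_data` object.
#' @param geom the matching `array_geometry`.
#' @param path output file path; an existing file is overwritten (with a
#'   message).
#' @return `path`, invisibly.
#' @export
write_channel_data <- function(data, geom, path) {
  validate_channel_data(data, geom)
  validate_array_geometry(geom)
  if (file.exists(path)) message("overwriting existing file: ", path)
  obj <- list(samples = data$samples,
              element_x = geom$element_x,
              sampling_rate = data$sampling_rate,
              sound_speed = data$sound_speed,
              demod_freq = data$demod_freq,
              tx_angle = data$tx_angle,
              t0 = data$t0)
  ok <- tryCatch({ saveRDS(obj, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write channel data to '%s'", path)
  invisible(path)
}

#' Read channel data from a container file
#'
#' Validates the container schema (every named field must be present) and
#' the object invariants before returning.
#'
#' @param path path to a file written by [write_channel_data()].
#' @return a list with components `data` (`channel_data`) and `geom`
#'   (`array_geometry`).
#' @export
read_channel_data <- function(path) {
  if (!file.exists(path)) stop_io("file not found: '%s'", path)
  obj <- readRDS(path)
  for (f in .container_fields) {
    if (!f %in% names(obj)) {
      stop_schema("container file missing required field \"%s\"", f)
    }
  }
  ex <- as.double(obj$element_x)
  pitch <- if (length(ex) > 1L) ex[2] - ex[1] else 1e-3
  geom <- array_geometry(pitch = pitch, element_x = ex)
  data <- channel_data(obj$samples,
                       sampling_rate = obj$sampling_rate,
                       sound_speed = obj$sound_speed,
                       demod_freq = obj$demod_freq,
                       tx_angle = obj$tx_angle,
                       t0 = obj$t0)
  validate_channel_data(data, geom)
  list(data = data, geom = geom)
}

#' Default acquisition configuration
#'
#' A single 0-degree plane-wave acquisition on a 128-element linear array:
#' 0.30 mm pitch, 5.208 MHz center frequency sampled at 4x (20.832 MHz),
#' 1540 m/s sound speed, 2048 RF samples starting at t0 = 0. The imaging
#' grid spans the array laterally and 5-50 mm axially at 0.25 mm spacing.
#' All values are configurable; algorithms take them from this object, never
#' hard-code them.
#'
#' @param n_elements number of array elements.
#' @param pitch element spacing (m).
#' @param center_freq pulse center frequency (Hz).
#' @param sampling_rate sampling frequency (Hz); default 4x `center_freq`.
#' @param sound_speed medium sound speed (m/s).
#' @param n_samples recorded samples per element.
#' @param grid_dx lateral pixel spacing (m).
#' @param grid_dz axial pixel spacing (m).
#' @param z_range axial depth range `c(min, max)` (m).
#' @return a list with components `geom` (`array_geometry`), `grid`
#'   (`imaging_grid`), and scalars `sampling_rate`, `sound_speed`,
#'   `center_freq`, `n_samples`, `tx_angle`, `t0`.
#' @examples
#' cfg <- default_config()
#' cfg$geom$n_elements
#' @export
default_config <- function(n_elements = 128, pitch = 0.3e-3,
                           center_freq = 5.208e6,
                           sampling_rate = 4 * center_freq,
                           sound_speed = 1540, n_samples = 2048,
                           grid_dx = 0.25e-3, grid_dz = 0.25e-3,
                           z_range = c(5e-3, 50e-3)) {
  geom <- array_geometry(n_elements, pitch)
  half_span <- max(abs(geom$element_x))
  nx <- max(2L, round(2 * half_span / grid_dx) + 1L)
  x <- seq(-half_span, half_span, length.out = nx)
  z <- seq(z_range[1], z_range[2], by = grid_dz)
  list(geom = geom,
       grid = imaging_grid(x, z),
       sampling_rate = sampling_rate,
       sound_speed = sound_speed,
       center_freq = center_freq,
       n_samples = as.integer(n_samples),
       tx_angle = 0,
       t0 = 0)
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("<array_geometry> %d elements, pitch %.4g mm, span %.4g mm\n",
              x$n_elements, x$pitch * 1e3, diff(range(x$element_x)) * 1e3))
  invisible(x)
}

#' @export
print.channel_data <- function(x, ...) {
  kind <- if (x$demod_freq > 0) "IQ" else "RF"
  cat(sprintf("<channel_data> %s, %d elements x %d samples, fs %.4g MHz\n",
              kind, nrow(x$samples), ncol(x$samples),
              x$sampling_rate / 1e6))
  invisible(x)
}

#' @export
print.envelope_image <- function(x, ...) {
  cat(sprintf("<envelope_image> %d x %d, max-normalized (pre-max %.4g)%s\n",
              nrow(x$values), ncol(x$values), x$normalization_max,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
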