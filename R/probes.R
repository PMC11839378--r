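# Probe protocols: the network-under-test contract, artificial-input
# probing, the progressive channel-removal sweep, and the mock networks
# used as behavioral fixtures.

#' Network-under-test contract
#'
#' Wraps any callable mapping `(channel_data, array_geometry,
#' imaging_grid)` to an [envelope_image()] (or plain `[nz, nx]` matrix in
#' `[0, 1]`). Evaluation is pure: the probe protocols never mutate the
#' network or its inputs.
#'
#' @param fn function of `(data, geom, grid)` returning the output image.
#' @param name identifier used in reports and error messages.
#' @param declared_params optional list of layer specifications
#'   (see [layer_dense()]) describing the trainable parameters.
#' @return an object of class `network_under_test`.
#' @export
network_under_test <- function(fn, name = "network",
                               declared_params = NULL) {
  if (!is.function(fn)) stop_validation("fn must be a function")
  structure(list(fn = fn, name = name, declared_params = declared_params),
            class = "network_under_test")
}

#' Run a network-under-test with contract checking
#'
#' Calls the wrapped function and validates its output: grid-shaped,
#' finite, values in `[0, 1]`. A violation raises a contract error naming
#' the network.
#'
#' @param net a [network_under_test()].
#' @param data,geom,grid the inputs forwarded to the network.
#' @return an [envelope_image()].
#' @export
predict_network <- function(net, data, geom, grid) {
  stopifnot(inherits(net, "network_under_test"))
  out <- net$fn(data, geom, grid)
  v <- if (inherits(out, "envelope_image")) out$values else out
  nz <- length(grid$z); nx <- length(grid$x)
  if (!is.matrix(v) || nrow(v) != nz || ncol(v) != nx) {
    stop_contract("network \"%s\" violated its contract: output shape %s, expected %dx%d",
                  net$name,
                  if (is.matrix(v)) paste(dim(v), collapse = "x") else "non-matrix",
                  nz, nx)
  }
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
    stop_contract("network \"%s\" violated its contract: output values outside [0, 1]",
                  net$name)
  }
  if (inherits(out, "envelope_image")) out else {
    envelope_image(v, normalization_max = max(v))
  }
}

#' Progressive channel-removal protocol
#'
#' @param increment removal-fraction step (default 0.05, i.e. 5%
#'   increments from 0% to 100%).
#' @param replacement_value value substituted for removed element rows
#'   (near-zero, default 1e-20).
#' @param nested if `TRUE` (default) removed sets are cumulative: the
#'   elements removed at a fraction contain those removed at every smaller
#'   fraction. If `FALSE`, each fraction draws a fresh random subset.
#' @param seed RNG seed for element selection.
#' @return an object of class `removal_protocol`.
#' @export
removal_protocol <- function(increment = 0.05, replacement_value = 1e-20,
                             nested = TRUE, seed = 0L) {
  if (!is_scalar_number(increment) || increment <= 0 || increment > 1) {
    stop_validation("increment must be in (0, 1]")
  }
  if (!is_scalar_number(replacement_value) || replacement_value <= 0) {
    stop_validation("replacement_value must be > 0")
  }
  structure(
    list(increment = increment, replacement_value = replacement_value,
         nested = isTRUE(nested), seed = as.integer(seed)),
    class = "removal_protocol"
  )
}

# Seeded element-removal order: a permutation of all elements for nested
# protocols (prefixes give a chain of sets), or a fresh draw per fraction
# otherwise.
removal_set <- function(n_elements, fraction, protocol) {
  k <- as.integer(round_half_away(fraction * n_elements))
  if (k == 0L) return(integer(0))
  if (protocol$nested) {
    perm <- with_seed(protocol$seed, sample.int(n_elements))
    sort(perm[seq_len(k)])
  } else {
    # decorrelate draws across fractions while staying reproducible
    sub_seed <- protocol$seed + as.integer(round(fraction * 1e4))
    sort(with_seed(sub_seed, sample.int(n_elements, k)))
  }
}

#' Remove a fraction of channel-data elements
#'
#' Replaces `round(fraction * n_elements)` whole element rows (rounding
#' half away from zero) with the protocol's near-zero replacement value.
#' At `fraction = 1` the result is exactly the zeros artificial probe of
#' the same shape (all near-zero with a single unit center sample).
#'
#' @param data a [channel_data()] object.
#' @param fraction removal fraction in `[0, 1]`.
#' @param protocol a [removal_protocol()].
#' @return a list with components `data` (degraded [channel_data()]) and
#'   `removed` (sorted integer vector of removed element indices).
#' @export
remove_channels <- function(data, fraction, protocol = removal_protocol()) {
  stopifnot(inherits(data, "channel_data"))
  if (!is_scalar_number(fraction) || fraction < 0 || fraction > 1) {
    stop_validation("fraction must be in [0, 1]")
  }
  n_el <- nrow(data$samples)
  if (fraction >= 1) {
    spec <- artificial_input_spec("zeros", dim(data$samples),
                                  epsilon = protocol$replacement_value)
    out <- make_zeros_input(spec, sampling_rate = data$sampling_rate,
                            sound_speed = data$sound_speed, t0 = data$t0)
    return(list(data = out, removed = seq_len(n_el)))
  }
  removed <- removal_set(n_el, fraction, protocol)
  s <- data$samples
  if (length(removed) > 0) s[removed, ] <- protocol$replacement_value
  out <- channel_data(s, sampling_rate = data$sampling_rate,
                      sound_speed = data$sound_speed,
                      demod_freq = data$demod_freq,
                      tx_angle = data$tx_angle, t0 = data$t0)
  list(data = out, removed = removed)
}

#' Progressive channel-removal sweep
#'
#' Degrades the input data at fractions `0, increment, ..., 1`; at each
#' step both the reference DAS beamformer and the network-under-test are
#' applied to the *same* degraded data, and the NCC and SSIM of the network
#' output against the per-step DAS ground truth are recorded. At 100%
#' removal the input is the zeros artificial probe, so the curve ends at
#' the zeros-probe comparison. Identical seeds give identical removed sets
#' and curves.
#'
#' @param net a [network_under_test()].
#' @param data baseline (0% removal) [channel_data()].
#' @param geom,grid acquisition geometry and reconstruction grid.
#' @param protocol a [removal_protocol()].
#' @param beamform_cfg reference-beamformer [beamform_config()].
#' @param metric_cfg a [metric_config()].
#' @return an object of class `removal_sweep_result` with fields
#'   `fractions`, `removed_elements` (list of index vectors), `ncc_curve`,
#'   `ssim_curve`.
#' @export
removal_sweep <- function(net, data, geom, grid,
                          protocol = removal_protocol(),
                          beamform_cfg = beamform_config(),
                          metric_cfg = metric_config()) {
  fractions <- seq(0, 1, by = protocol$increment)
  if (abs(fractions[length(fractions)] - 1) > 1e-12) {
    fractions <- c(fractions, 1)
  }
  delays <- compute_delays(grid, geom, data$tx_angle, data$sound_speed)
  removed_elements <- vector("list", length(fractions))
  ncc_curve <- numeric(length(fractions))
  ssim_curve <- numeric(length(fractions))
  for (i in seq_along(fractions)) {
    step <- remove_channels(data, fractions[i], protocol)
    removed_elements[[i]] <- step$removed
    gt <- beamform_das(step$data, geom, grid, beamform_cfg, delays = delays)
    out <- predict_network(net, step$data, geom, grid)
    ncc_curve[i] <- ncc(gt, out)
    ssim_curve[i] <- ssim(gt, out, metric_cfg)
  }
  structure(
    list(fractions = fractions, removed_elements = removed_elements,
         ncc_curve = ncc_curve, ssim_curve = ssim_curve,
         network = net$name, protocol = protocol),
    class = "removal_sweep_result"
  )
}

#' Run the artificial-input probe battery
#'
#' For each probe specification, generates the artificial input, computes
#' the reference DAS ground truth and the network output from the
#' identical input, and attaches a full [metric_report()].
#'
#' @param net a [network_under_test()].
#' @param specs nonempty list of [artificial_input_spec()]s.
#' @param geom,grid acquisition geometry and reconstruction grid.
#' @param beamform_cfg reference-beamformer [beamform_config()].
#' @param metric_cfg a [metric_config()].
#' @param sampling_rate,sound_speed,t0 acquisition constants for the probe
#'   inputs.
#' @return a list with one entry per probe: `kind`, `input`
#'   ([channel_data()]), `net_image`, `gt_image`, `report`.
#' @export
run_artificial_probe <- function(net, specs, geom, grid,
                                 beamform_cfg = beamform_config(),
                                 metric_cfg = metric_config(),
                                 sampling_rate = 20.832e6,
                                 sound_speed = 1540, t0 = 0) {
  if (length(specs) == 0L) stop_validation("specs must be nonempty")
  delays <- compute_delays(grid, geom, 0, sound_speed)
  lapply(specs, function(spec) {
    input <- make_artificial_input(spec, sampling_rate, sound_speed, t0)
    gt <- beamform_das(input, geom, grid, beamform_cfg, delays = delays)
    out <- predict_network(net, input, geom, grid)
    list(kind = spec$kind, input = input, net_image = out, gt_image = gt,
         report = metric_report(gt, out, metric_cfg))
  })
}

#' Mock networks for protocol fixtures
#'
#' `mock_faithful_net()` emulates a well-behaved learned beamformer: it
#' wraps the reference DAS, optionally modulated by a smooth multiplicative
#' gain field with maximum deviation `perturbation` (<= 5%), then
#' re-normalized. With `perturbation = 0` it reproduces the reference DAS
#' output bitwise. `mock_memorizer_net()` emulates an overfit network: it
#' ignores its input entirely and always returns a stored image (the first
#' one, or the pixel-wise mean under `blend_rule = "mean"`), the way an
#' overfit model reproduces training imagery regardless of input.
#'
#' @param cfg reference-beamformer [beamform_config()] for the faithful
#'   mock.
#' @param perturbation maximum relative gain deviation in `[0, 0.05]`.
#' @param seed RNG seed for the gain field's phases and frequencies.
#' @return a [network_under_test()].
#' @export
mock_faithful_net <- function(cfg = beamform_config(), perturbation = 0,
                              seed = 0L) {
  if (!is_scalar_number(perturbation) || perturbation < 0 ||
      perturbation > 0.05) {
    stop_validation("perturbation must be in [0, 0.05]")
  }
  force(cfg); force(perturbation); force(seed)
  fn <- function(data, geom, grid) {
    env <- beamform_das(data, geom, grid, cfg)
    if (perturbation == 0) return(env)
    ph <- with_seed(seed, stats::runif(4, 0, 2 * pi))
    nz <- length(grid$z); nx <- length(grid$x)
    gz <- cos(2 * pi * seq_len(nz) / nz + ph[1]) +
      cos(4 * pi * seq_len(nz) / nz + ph[2])
    gx <- cos(2 * pi * seq_len(nx) / nx + ph[3]) +
      cos(4 * pi * seq_len(nx) / nx + ph[4])
    field <- outer(gz, gx, `+`)
    gain <- 1 + perturbation * field / max(abs(field))
    v <- env$values * gain
    m <- max(v)
    if (m <= 1e-30) return(env)
    envelope_image(v / m, normalization_max = env$normalization_max * m)
  }
  network_under_test(fn, name = "mock-faithful", declared_params = list())
}

#' @rdname mock_faithful_net
#' @param stored_images nonempty list of [envelope_image()]s (or matrices)
#'   the memorizer reproduces.
#' @param blend_rule `"first"` (return the first stored image) or `"mean"`
#'   (pixel-wise mean of all stored images, re-normalized).
#' @export
mock_memorizer_net <- function(stored_images,
                               blend_rule = c("first", "mean")) {
  if (length(stored_images) == 0L) {
    stop_validation("stored_images must be nonempty")
  }
  blend_rule <- match.arg(blend_rule)
  mats <- lapply(stored_images, as_pixel_matrix)
  stored <- if (blend_rule == "first") {
    mats[[1]]
  } else {
    m <- Reduce(`+`, mats) / length(mats)
    if (max(m) > 0) m / max(m) else m
  }
  fn <- function(data, geom, grid) {
    envelope_image(stored, normalization_max = max(stored))
  }
  network_under_test(fn, name = "mock-memorizer", declared_params = NULL)
}
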