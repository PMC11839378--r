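# Decision flow: thresholds, trainable-parameter counting, and the staged
# overfit verdict.

#' Detector thresholds
#'
#' Flag thresholds for the staged decision flow. Defaults reflect the
#' separations observed between well-behaved and overfit beamformers
#' (zeros-probe output mean >= 0.08 flags; ones-probe mean <= 0.07 flags;
#' probe NCC <= 0.8 or SSIM <= 0.2 flags); they are empirical, not
#' derived, and fully configurable. Comparisons are inclusive. The
#' qualitative visual checkpoint on realistic baseline data is automated
#' as an NCC floor (`baseline_ncc_min`): a baseline NCC below it raises
#' the baseline flag.
#'
#' @param zeros_mean_flag_ge flag when the zeros-probe output mean is >=
#'   this value (default 0.08; the expected mean is close to 0).
#' @param ones_mean_flag_le flag when the ones-probe output mean is <=
#'   this value (default 0.07; the expected mean is close to 1).
#' @param ncc_flag_le flag when any probe's NCC against its ground truth
#'   is <= this value (default 0.8).
#' @param ssim_flag_le flag when any probe's SSIM is <= this value
#'   (default 0.2).
#' @param baseline_ncc_min minimum NCC on realistic baseline data
#'   (default 0.8).
#' @return an object of class `detector_thresholds`.
#' @export
detector_thresholds <- function(zeros_mean_flag_ge = 0.08,
                                ones_mean_flag_le = 0.07,
                                ncc_flag_le = 0.8,
                                ssim_flag_le = 0.2,
                                baseline_ncc_min = 0.8) {
  vals <- c(zeros_mean_flag_ge, ones_mean_flag_le, ncc_flag_le,
            ssim_flag_le, baseline_ncc_min)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop_validation("thresholds must lie in [0, 1]")
  }
  structure(
    list(zeros_mean_flag_ge = zeros_mean_flag_ge,
         ones_mean_flag_le = ones_mean_flag_le,
         ncc_flag_le = ncc_flag_le, ssim_flag_le = ssim_flag_le,
         baseline_ncc_min = baseline_ncc_min),
    class = "detector_thresholds"
  )
}

#' Layer specifications for trainable-parameter counting
#'
#' `layer_dense(n_in, n_out)` has `n_in * n_out` weights plus `n_out`
#' biases; `layer_conv2d(kh, kw, c_in, c_out)` has
#' `kh * kw * c_in * c_out` weights plus `c_out` biases; `layer_other()`
#' carries an explicit count for anything else.
#'
#' @param n_in,n_out dense-layer feature counts (>= 1).
#' @param has_bias whether the layer has a bias vector (default `TRUE`).
#' @return an object of class `layer_spec`.
#' @export
layer_dense <- function(n_in, n_out, has_bias = TRUE) {
  if (n_in < 1 || n_out < 1) stop_validation("layer dims must be >= 1")
  structure(list(kind = "dense", n_in = n_in, n_out = n_out,
                 has_bias = isTRUE(has_bias)), class = "layer_spec")
}

#' @rdname layer_dense
#' @param kh,kw kernel height and width (>= 1).
#' @param c_in,c_out input and output channel counts (>= 1).
#' @export
layer_conv2d <- function(kh, kw, c_in, c_out, has_bias = TRUE) {
  if (any(c(kh, kw, c_in, c_out) < 1)) stop_validation("layer dims must be >= 1")
  structure(list(kind = "conv2d", kh = kh, kw = kw, c_in = c_in,
                 c_out = c_out, has_bias = isTRUE(has_bias)),
            class = "layer_spec")
}

#' @rdname layer_dense
#' @param param_count explicit trainable-parameter count (>= 0).
#' @export
layer_other <- function(param_count = NULL) {
  if (is.null(param_count)) {
    stop_validation("layer of kind \"other\" requires an explicit param_count")
  }
  if (param_count < 0) stop_validation("param_count must be >= 0")
  structure(list(kind = "other", param_count = param_count),
            class = "layer_spec")
}

#' Count trainable parameters (weights and biases)
#'
#' Sums the weights and biases declared layer by layer. The conventional
#' delay-and-sum beamformer has no trainable parameters: an empty layer
#' list returns 0.
#'
#' @param layers possibly empty list of [layer_dense()] /
#'   [layer_conv2d()] / [layer_other()] specifications.
#' @return total parameter count.
#' @examples
#' count_trainable_params(list())                    # DAS: 0
#' count_trainable_params(list(layer_dense(10, 5)))  # 55
#' @export
count_trainable_params <- function(layers) {
  if (length(layers) == 0L) return(0)
  sum(vapply(layers, function(l) {
    stopifnot(inherits(l, "layer_spec"))
    switch(l$kind,
           dense = l$n_in * l$n_out + if (l$has_bias) l$n_out else 0,
           conv2d = l$kh * l$kw * l$c_in * l$c_out +
             if (l$has_bias) l$c_out else 0,
           other = l$param_count)
  }, numeric(1)))
}

# Pure verdict computation from per-probe metric reports. Kept separate
# from evaluate_network so that re-running on saved reports reproduces the
# verdict exactly.
verdict_from_reports <- function(reports, thresholds, baseline_ncc = NULL,
                                 param_count = NULL, network = "network") {
  per_probe <- list()
  for (kind in names(reports)) {
    rep <- reports[[kind]]
    flags <- character(0)
    if (kind == "zeros" && rep$mean >= thresholds$zeros_mean_flag_ge) {
      flags <- c(flags, sprintf(
        "zeros-probe output mean %.4f >= %.4f (expected close to 0)",
        rep$mean, thresholds$zeros_mean_flag_ge))
    }
    if (kind == "ones" && rep$mean <= thresholds$ones_mean_flag_le) {
      flags <- c(flags, sprintf(
        "ones-probe output mean %.4f <= %.4f (expected close to 1)",
        rep$mean, thresholds$ones_mean_flag_le))
    }
    if (!is.na(rep$ncc) && rep$ncc <= thresholds$ncc_flag_le) {
      flags <- c(flags, sprintf("NCC %.4f <= %.4f vs ground truth",
                                rep$ncc, thresholds$ncc_flag_le))
    }
    if (rep$ssim <= thresholds$ssim_flag_le) {
      flags <- c(flags, sprintf("SSIM %.4f <= %.4f vs ground truth",
                                rep$ssim, thresholds$ssim_flag_le))
    }
    per_probe[[kind]] <- list(
      status = if (length(flags) > 0) "flag" else "pass",
      flags = flags, report = rep)
  }
  baseline_flag <- FALSE
  baseline_rationale <- NULL
  if (!is.null(baseline_ncc)) {
    if (baseline_ncc < thresholds$baseline_ncc_min) {
      baseline_flag <- TRUE
      baseline_rationale <- sprintf(
        "baseline NCC %.4f < %.4f", baseline_ncc,
        thresholds$baseline_ncc_min)
    }
  }
  any_flag <- baseline_flag ||
    any(vapply(per_probe, function(p) p$status == "flag", logical(1)))
  structure(
    list(network = network,
         per_probe_flags = per_probe,
         baseline_flag = baseline_flag,
         baseline_rationale = baseline_rationale,
         baseline_ncc = baseline_ncc,
         overall = if (any_flag) "overfit-suspected" else "pass",
         thresholds = thresholds,
         param_count = param_count),
    class = "overfit_verdict"
  )
}

#' Evaluate a network-under-test for overfitting
#'
#' Runs the staged decision flow. Stage 0 (optional, when `baseline_data`
#' is given): the network and the reference DAS beamform the same
#' realistic baseline data; an NCC below `baseline_ncc_min` raises the
#' baseline flag (an automated stand-in for the visual checkpoint; the
#' images themselves remain available for human review via
#' [build_report()]). Stage 1: the zeros and ones artificial probes are
#' run; a zeros-probe output mean at or above `zeros_mean_flag_ge`, or a
#' ones-probe mean at or below `ones_mean_flag_le`, flags. Stage 2: for
#' every probe (Gaussian included), an NCC at or below `ncc_flag_le` or an
#' SSIM at or below `ssim_flag_le` against the probe's DAS ground truth
#' flags. The Gaussian-probe *mean* is deliberately not a flag criterion:
#' it carries no usable expectation, while its NCC and SSIM do.
#'
#' The overall verdict is `"overfit-suspected"` iff any flag is raised.
#' Every flag's rationale quotes the metric value and the threshold that
#' tripped.
#'
#' @param net a [network_under_test()].
#' @param geom,grid acquisition geometry and reconstruction grid.
#' @param thresholds a [detector_thresholds()].
#' @param baseline_data optional realistic [channel_data()] for Stage 0.
#' @param n_samples probe time-sample count (default 2048).
#' @param probe_seed seed for the Gaussian probe.
#' @param beamform_cfg reference-beamformer [beamform_config()].
#' @param metric_cfg a [metric_config()].
#' @param sampling_rate,sound_speed acquisition constants for the probes.
#' @return an `overfit_verdict`; attribute `"probe_outputs"` holds the
#'   per-probe images for reporting.
#' @export
evaluate_network <- function(net, geom, grid,
                             thresholds = detector_thresholds(),
                             baseline_data = NULL, n_samples = 2048,
                             probe_seed = 0L,
                             beamform_cfg = beamform_config(),
                             metric_cfg = metric_config(),
                             sampling_rate = 20.832e6,
                             sound_speed = 1540) {
  stopifnot(inherits(net, "network_under_test"))
  shape <- c(geom$n_elements, n_samples)
  specs <- list(
    artificial_input_spec("zeros", shape),
    artificial_input_spec("ones", shape),
    artificial_input_spec("gaussian", shape, seed = probe_seed)
  )
  probe_outputs <- run_artificial_probe(
    net, specs, geom, grid, beamform_cfg, metric_cfg,
    sampling_rate = sampling_rate, sound_speed = sound_speed)
  reports <- stats::setNames(
    lapply(probe_outputs, `[[`, "report"),
    vapply(probe_outputs, `[[`, character(1), "kind"))

  baseline_ncc <- NULL
  if (!is.null(baseline_data)) {
    gt <- beamform_das(baseline_data, geom, grid, beamform_cfg)
    out <- predict_network(net, baseline_data, geom, grid)
    baseline_ncc <- ncc(gt, out)
  }

  param_count <- if (!is.null(net$declared_params)) {
    count_trainable_params(net$declared_params)
  } else NULL

  verdict <- verdict_from_reports(reports, thresholds,
                                  baseline_ncc = baseline_ncc,
                                  param_count = param_count,
                                  network = net$name)
  attr(verdict, "probe_outputs") <- probe_outputs
  verdict
}

#' @export
print.overfit_verdict <- function(x, ...) {
  cat(sprintf("<overfit_verdict> network \"%s\": %s\n", x$network,
              toupper(x$overall)))
  if (!is.null(x$baseline_ncc)) {
    cat(sprintf("  baseline: NCC %.4f %s\n", x$baseline_ncc,
                if (x$baseline_flag) "[FLAG]" else "[pass]"))
  }
  for (kind in names(x$per_probe_flags)) {
    p <- x$per_probe_flags[[kind]]
    cat(sprintf("  %-8s %s", kind,
                if (p$status == "flag") "[FLAG]" else "[pass]"))
    r <- p$report
    cat(sprintf("  mean %.4f +/- %.4f, NCC %s, SSIM %.4f\n",
                r$mean, r$std,
                if (is.na(r$ncc)) "NA" else sprintf("%.4f", r$ncc),
                r$ssim))
    for (f in p$flags) cat("           - ", f, "\n", sep = "")
  }
  if (!is.null(x$param_count)) {
    cat(sprintf("  trainable parameters: %s\n",
                format(x$param_count, big.mark = ",")))
  }
  invisible(x)
}
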