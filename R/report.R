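# Report bundle: JSON verdict, per-probe image pairs, metrics CSV, sweep
# outputs.

verdict_to_list <- function(verdict) {
  probes <- lapply(names(verdict$per_probe_flags), function(kind) {
    p <- verdict$per_probe_flags[[kind]]
    r <- p$report
    list(kind = kind, status = p$status, flags = as.list(p$flags),
         mean = r$mean, std = r$std, gt_mean = r$gt_mean,
         gt_std = r$gt_std, l1 = r$l1, l2 = r$l2,
         ncc = if (is.na(r$ncc)) NULL else r$ncc, ssim = r$ssim)
  })
  list(network = verdict$network,
       overall = verdict$overall,
       thresholds = unclass(verdict$thresholds),
       probes = probes,
       baseline = if (is.null(verdict$baseline_ncc)) NULL else {
         list(ncc = verdict$baseline_ncc, flag = verdict$baseline_flag,
              rationale = verdict$baseline_rationale)
       },
       param_count = verdict$param_count)
}

write_bmode_png <- function(env, path, dynamic_range = 60) {
  bm <- log_compress(env, dynamic_range)
  # map [-DR, 0] dB to [0, 1] gray
  g <- (bm$db_values + dynamic_range) / dynamic_range
  png::writePNG(g, target = path)
  invisible(path)
}

#' Write the full report bundle for an evaluation
#'
#' Writes `verdict.json` (the verdict, thresholds, and per-probe metrics),
#' `metrics.csv` (one row per probe), per-probe PNG pairs (network output
#' vs ground truth, both log-compressed at the given dynamic range), and,
#' when a sweep is given, `sweep.csv` and `sweep.png`. Re-running into the
#' same directory overwrites the same files (idempotent).
#'
#' @param verdict an `overfit_verdict` from [evaluate_network()].
#' @param probe_outputs the per-probe outputs, as returned by
#'   [run_artificial_probe()]; defaults to the ones stored on `verdict`.
#' @param sweep optional `removal_sweep_result`.
#' @param out_dir output directory (created if needed).
#' @param dynamic_range display dynamic range in dB for the PNGs.
#' @return `out_dir`, invisibly.
#' @export
build_report <- function(verdict, probe_outputs = NULL, sweep = NULL,
                         out_dir, dynamic_range = 60) {
  stopifnot(inherits(verdict, "overfit_verdict"))
  if (is.null(probe_outputs)) {
    probe_outputs <- attr(verdict, "probe_outputs")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop_io("cannot create output directory '%s'", out_dir)
    }
  }
  if (file.access(out_dir, mode = 2) != 0) {
    stop_io("output directory '%s' is not writable", out_dir)
  }

  jsonlite::write_json(verdict_to_list(verdict),
                       file.path(out_dir, "verdict.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  rows <- lapply(names(verdict$per_probe_flags), function(kind) {
    r <- verdict$per_probe_flags[[kind]]$report
    data.frame(probe = kind, mean = r$mean, std = r$std,
               gt_mean = r$gt_mean, gt_std = r$gt_std, l1 = r$l1,
               l2 = r$l2, ncc = r$ncc, ssim = r$ssim,
               status = verdict$per_probe_flags[[kind]]$status)
  })
  utils::write.csv(do.call(rbind, rows),
                   file.path(out_dir, "metrics.csv"), row.names = FALSE)

  if (!is.null(probe_outputs)) {
    for (p in probe_outputs) {
      write_bmode_png(p$net_image,
                      file.path(out_dir, sprintf("net_%s.png", p$kind)),
                      dynamic_range)
      write_bmode_png(p$gt_image,
                      file.path(out_dir, sprintf("gt_%s.png", p$kind)),
                      dynamic_range)
    }
  }

  if (!is.null(sweep)) {
    utils::write.csv(
      data.frame(fraction = sweep$fractions, ncc = sweep$ncc_curve,
                 ssim = sweep$ssim_curve),
      file.path(out_dir, "sweep.csv"), row.names = FALSE)
    grDevices::png(file.path(out_dir, "sweep.png"), width = 640,
                   height = 480)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::plot(sweep$fractions * 100, sweep$ncc_curve, type = "b",
                   pch = 16, col = "steelblue", ylim = c(-0.1, 1),
                   xlab = "channel data removed (%)", ylab = "metric",
                   main = sprintf("removal sweep: %s", sweep$network))
    graphics::lines(sweep$fractions * 100, sweep$ssim_curve, type = "b",
                    pch = 17, col = "firebrick")
    graphics::legend("bottomleft", legend = c("NCC", "SSIM"),
                     col = c("steelblue", "firebrick"), pch = c(16, 17))
  }
  invisible(out_dir)
}
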