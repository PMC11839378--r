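test_that("trainable-parameter counting matches weights-plus-biases arithmetic", {
  expect_equal(count_trainable_params(list()), 0)  # conventional DAS
  expect_equal(count_trainable_params(list(layer_dense(10, 5))), 55)
  expect_equal(count_trainable_params(list(layer_dense(10, 5,
                                                       has_bias = FALSE))),
               50)
  expect_equal(count_trainable_params(list(layer_conv2d(3, 3, 2, 4))), 76)
  expect_equal(count_trainable_params(list(layer_dense(10, 5),
                                           layer_conv2d(3, 3, 2, 4),
                                           layer_other(100))), 231)
  expect_error(layer_other(), class = "bp_validation_error")
  expect_error(layer_dense(0, 5), class = "bp_validation_error")
})

# verdict logic exercised directly on metric reports (pure function)
fake_report <- function(mean, ncc, ssim, std = 0.05) {
  structure(list(mean = mean, std = std, gt_mean = 0, gt_std = 0,
                 l1 = 0.01, l2 = 0.001, ncc = ncc, ssim = ssim,
                 n_pixels = 100), class = "metric_report")
}

test_that("verdict flags an overfit-style zeros probe and passes a faithful one", {
  thr <- detector_thresholds()
  # overfit profile: zeros mean 0.0871, NCC 0.1325 (both past thresholds)
  v <- beamprobe:::verdict_from_reports(
    list(zeros = fake_report(0.0871, ncc = 0.1325, ssim = 0.103)),
    thr)
  expect_equal(v$overall, "overfit-suspected")
  expect_equal(v$per_probe_flags$zeros$status, "flag")
  expect_length(v$per_probe_flags$zeros$flags, 3)  # mean, NCC, SSIM

  # faithful profile: zeros mean 0.0068, ones mean 0.9953, NCC 0.9903
  v2 <- beamprobe:::verdict_from_reports(
    list(zeros = fake_report(0.0068, ncc = 0.9903, ssim = 0.9776),
         ones = fake_report(0.9953, ncc = 0.9480, ssim = 0.8651)),
    thr)
  expect_equal(v2$overall, "pass")
  expect_true(all(vapply(v2$per_probe_flags, function(p) {
    p$status == "pass"
  }, logical(1))))
})

test_that("threshold comparisons are inclusive at the boundary", {
  thr <- detector_thresholds()
  at <- beamprobe:::verdict_from_reports(
    list(gaussian = fake_report(0.5, ncc = 0.8, ssim = 0.5)), thr)
  expect_equal(at$overall, "overfit-suspected")  # NCC exactly 0.8 flags
  above <- beamprobe:::verdict_from_reports(
    list(gaussian = fake_report(0.5, ncc = 0.8000001, ssim = 0.5)), thr)
  expect_equal(above$overall, "pass")
  # ones mean exactly at threshold flags; zeros mean exactly at flags
  z <- beamprobe:::verdict_from_reports(
    list(zeros = fake_report(0.08, ncc = 0.99, ssim = 0.99)), thr)
  expect_equal(z$per_probe_flags$zeros$status, "flag")
  o <- beamprobe:::verdict_from_reports(
    list(ones = fake_report(0.07, ncc = 0.99, ssim = 0.99)), thr)
  expect_equal(o$per_probe_flags$ones$status, "flag")
})

test_that("gaussian-probe mean is not a flag criterion", {
  thr <- detector_thresholds()
  v <- beamprobe:::verdict_from_reports(
    list(gaussian = fake_report(0.9, ncc = 0.95, ssim = 0.5)), thr)
  expect_equal(v$overall, "pass")
})

test_that("every flag's rationale quotes the metric value and threshold", {
  thr <- detector_thresholds()
  v <- beamprobe:::verdict_from_reports(
    list(zeros = fake_report(0.0871, ncc = 0.1325, ssim = 0.103)), thr)
  flags <- v$per_probe_flags$zeros$flags
  expect_true(all(nzchar(flags)))
  expect_match(flags[1], "0.0871")
  expect_match(flags[1], "0.08")
  expect_match(flags[2], "0.1325")
  expect_match(flags[2], "0.8")
})

test_that("verdict is a pure function of reports and thresholds", {
  thr <- detector_thresholds()
  reports <- list(zeros = fake_report(0.01, ncc = 0.95, ssim = 0.9),
                  ones = fake_report(0.98, ncc = 0.9, ssim = 0.85))
  v1 <- beamprobe:::verdict_from_reports(reports, thr, baseline_ncc = 0.93)
  v2 <- beamprobe:::verdict_from_reports(reports, thr, baseline_ncc = 0.93)
  expect_identical(v1, v2)
  # baseline below floor raises the baseline flag alone
  v3 <- beamprobe:::verdict_from_reports(reports, thr, baseline_ncc = 0.5)
  expect_true(v3$baseline_flag)
  expect_equal(v3$overall, "overfit-suspected")
  expect_match(v3$baseline_rationale, "0.5")
})

test_that("end-to-end evaluation verdicts separate the mock pair", {
  cfg <- small_cfg()
  base <- small_speckle_data(cfg, seed = 7)
  stored <- beamform_das(base, cfg$geom, cfg$grid)

  vf <- evaluate_network(mock_faithful_net(), cfg$geom, cfg$grid,
                         baseline_data = base, n_samples = cfg$n_samples,
                         sampling_rate = cfg$sampling_rate)
  expect_equal(vf$overall, "pass")
  expect_false(vf$baseline_flag)
  expect_equal(vf$param_count, 0)

  vm <- evaluate_network(mock_memorizer_net(list(stored)), cfg$geom,
                         cfg$grid, baseline_data = base,
                         n_samples = cfg$n_samples,
                         sampling_rate = cfg$sampling_rate)
  expect_equal(vm$overall, "overfit-suspected")
  n_flagged <- sum(vapply(vm$per_probe_flags, function(p) {
    p$status == "flag"
  }, logical(1)))
  expect_gte(n_flagged, 3)
})

test_that("report bundle writes verdict JSON, CSV, image pairs and sweep files", {
  cfg <- small_cfg()
  base <- small_speckle_data(cfg, seed = 7)
  stored <- beamform_das(base, cfg$geom, cfg$grid)
  net <- mock_memorizer_net(list(stored))
  v <- evaluate_network(net, cfg$geom, cfg$grid,
                        n_samples = cfg$n_samples,
                        sampling_rate = cfg$sampling_rate)
  sweep <- removal_sweep(net, base, cfg$geom, cfg$grid,
                         removal_protocol(seed = 2))
  dir <- withr::local_tempdir()
  build_report(v, sweep = sweep, out_dir = dir)
  expect_true(file.exists(file.path(dir, "verdict.json")))
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  expect_true(file.exists(file.path(dir, "sweep.csv")))
  for (k in c("zeros", "ones", "gaussian")) {
    expect_true(file.exists(file.path(dir, sprintf("net_%s.png", k))))
    expect_true(file.exists(file.path(dir, sprintf("gt_%s.png", k))))
  }
  j <- jsonlite::read_json(file.path(dir, "verdict.json"))
  expect_equal(j$overall, "overfit-suspected")
  expect_length(j$probes, 3)
  # PNGs share the grid's pixel dimensions
  img <- png::readPNG(file.path(dir, "net_zeros.png"))
  expect_equal(dim(img)[1:2], c(length(cfg$grid$z), length(cfg$grid$x)))
  # idempotent re-run
  expect_silent(build_report(v, sweep = sweep, out_dir = dir))
  # faithful run writes a passing verdict
  vf <- evaluate_network(mock_faithful_net(), cfg$geom, cfg$grid,
                         n_samples = cfg$n_samples,
                         sampling_rate = cfg$sampling_rate)
  dir2 <- withr::local_tempdir()
  build_report(vf, out_dir = dir2)
  expect_equal(jsonlite::read_json(file.path(dir2, "verdict.json"))$overall,
               "pass")
})
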