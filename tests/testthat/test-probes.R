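test_that("channel removal counts follow round-half-away and preserve data otherwise", {
  cfg <- small_cfg()
  cd <- small_speckle_data(cfg, seed = 3)
  prot <- removal_protocol(seed = 1)

  r0 <- remove_channels(cd, 0, prot)
  expect_identical(r0$data$samples, cd$samples)
  expect_length(r0$removed, 0)

  # n = 32: 5% of 32 = 1.6 -> 2 rows; 0.05 * 128 = 6.4 -> 6 rows
  r5 <- remove_channels(cd, 0.05, prot)
  expect_length(r5$removed, 2)
  expect_true(all(r5$data$samples[r5$removed, ] == 1e-20))
  kept <- setdiff(seq_len(32), r5$removed)
  expect_identical(r5$data$samples[kept, ], cd$samples[kept, ])

  cd128 <- channel_data(matrix(rnorm(128 * 64), 128, 64), 20.832e6)
  expect_length(remove_channels(cd128, 0.05, prot)$removed, 6)
  # half-away rounding: n = 10, f = 0.25 -> 2.5 rows -> 3 (away from zero)
  cd10 <- channel_data(matrix(rnorm(10 * 8), 10, 8), 1e6)
  expect_length(remove_channels(cd10, 0.25, prot)$removed, 3)

  expect_error(remove_channels(cd, 1.5, prot), class = "bp_validation_error")
  expect_error(remove_channels(cd, -0.1, prot), class = "bp_validation_error")
})

test_that("full removal yields exactly the zeros artificial probe", {
  cfg <- small_cfg()
  cd <- small_speckle_data(cfg, seed = 3)
  r <- remove_channels(cd, 1, removal_protocol(seed = 1))
  ref <- make_zeros_input(artificial_input_spec("zeros", dim(cd$samples)),
                          sampling_rate = cd$sampling_rate)
  expect_identical(r$data$samples, ref$samples)
  expect_length(r$removed, 32)
})

test_that("nested removal sets form a chain under inclusion; non-nested draws fresh", {
  cfg <- small_cfg()
  cd <- small_speckle_data(cfg, seed = 3)
  prot <- removal_protocol(nested = TRUE, seed = 11)
  sets <- lapply(seq(0, 1, 0.05),
                 function(f) remove_channels(cd, f, prot)$removed)
  for (i in 2:length(sets)) {
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
  }
  free <- removal_protocol(nested = FALSE, seed = 11)
  sets2 <- lapply(seq(0.05, 0.95, 0.05),
                  function(f) remove_channels(cd, f, free)$removed)
  chained <- all(vapply(2:length(sets2), function(i) {
    all(sets2[[i - 1]] %in% sets2[[i]])
  }, logical(1)))
  expect_false(chained)
})

test_that("removal sweep runs 21 fractions and is bitwise seed-reproducible", {
  cfg <- small_cfg()
  cd <- small_speckle_data(cfg, seed = 3)
  net <- mock_faithful_net()
  s1 <- removal_sweep(net, cd, cfg$geom, cfg$grid,
                      removal_protocol(seed = 2))
  expect_equal(s1$fractions, seq(0, 1, 0.05))
  expect_length(s1$fractions, 21)
  expect_equal(vapply(s1$removed_elements, length, integer(1)),
               as.integer(round(s1$fractions * 32 + 1e-9)))
  s2 <- removal_sweep(net, cd, cfg$geom, cfg$grid,
                      removal_protocol(seed = 2))
  expect_identical(s1$ncc_curve, s2$ncc_curve)
  expect_identical(s1$ssim_curve, s2$ssim_curve)
  expect_identical(s1$removed_elements, s2$removed_elements)
})

test_that("probe battery evaluates ground truth and network on identical inputs", {
  cfg <- small_cfg()
  shape <- c(32, cfg$n_samples)
  specs <- list(artificial_input_spec("zeros", shape),
                artificial_input_spec("ones", shape),
                artificial_input_spec("gaussian", shape, seed = 4))
  res <- run_artificial_probe(mock_faithful_net(), specs, cfg$geom,
                              cfg$grid, sampling_rate = cfg$sampling_rate)
  expect_length(res, 3)
  for (p in res) {
    expect_equal(p$report$l1, 0)
    expect_equal(p$report$l2, 0)
    expect_equal(p$report$ncc, 1)
    expect_identical(p$net_image$values, p$gt_image$values)
  }
  expect_error(run_artificial_probe(mock_faithful_net(), list(),
                                    cfg$geom, cfg$grid),
               class = "bp_validation_error")
})

test_that("memorizer mock ignores its input entirely", {
  cfg <- small_cfg()
  stored <- beamform_das(small_speckle_data(cfg, seed = 3),
                         cfg$geom, cfg$grid)
  net <- mock_memorizer_net(list(stored))
  shape <- c(32, cfg$n_samples)
  specs <- list(artificial_input_spec("zeros", shape),
                artificial_input_spec("ones", shape),
                artificial_input_spec("gaussian", shape, seed = 4))
  res <- run_artificial_probe(net, specs, cfg$geom, cfg$grid,
                              sampling_rate = cfg$sampling_rate)
  expect_identical(res[[1]]$net_image$values, res[[2]]$net_image$values)
  expect_identical(res[[1]]$net_image$values, res[[3]]$net_image$values)
  expect_equal(res[[1]]$report$mean, mean(stored$values))
  expect_error(mock_memorizer_net(list()), class = "bp_validation_error")
})

test_that("faithful mock with zero perturbation reproduces the reference DAS bitwise", {
  cfg <- small_cfg()
  cd <- small_speckle_data(cfg, seed = 3)
  out <- predict_network(mock_faithful_net(), cd, cfg$geom, cfg$grid)
  ref <- beamform_das(cd, cfg$geom, cfg$grid)
  expect_identical(out$values, ref$values)
})

test_that("5% gain-field faithful mock keeps NCC >= 0.99 on speckle", {
  cfg <- small_cfg()
  cd <- small_speckle_data(cfg, seed = 3)
  net <- mock_faithful_net(perturbation = 0.05, seed = 21)
  out <- predict_network(net, cd, cfg$geom, cfg$grid)
  ref <- beamform_das(cd, cfg$geom, cfg$grid)
  expect_false(identical(out$values, ref$values))
  expect_gte(ncc(ref, out), 0.99)
  expect_error(mock_faithful_net(perturbation = 0.2),
               class = "bp_validation_error")
})

test_that("contract violations name the offending network", {
  cfg <- small_cfg()
  cd <- small_speckle_data(cfg, seed = 3)
  bad_shape <- network_under_test(function(d, g, gr) matrix(0.5, 2, 2),
                                  name = "bad-shape")
  err <- tryCatch(predict_network(bad_shape, cd, cfg$geom, cfg$grid),
                  error = function(e) e)
  expect_s3_class(err, "bp_contract_error")
  expect_match(conditionMessage(err), "bad-shape")

  bad_range <- network_under_test(function(d, g, gr) {
    matrix(2, length(cfg$grid$z), length(cfg$grid$x))
  }, name = "bad-range")
  expect_error(predict_network(bad_range, cd, cfg$geom, cfg$grid),
               class = "bp_contract_error")
})
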