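test_that("valid-mode breaths are reproducible and classify valid", {
  cfg <- sim_config(target_volume_level = 5)
  a <- generate_valid_breath(cfg, seed = 4)
  b <- generate_valid_breath(cfg, seed = 4)
  expect_identical(a$stream$samples, b$stream$samples)
  expect_identical(a$truth, b$truth)
  c2 <- generate_valid_breath(cfg, seed = 5)
  expect_false(identical(a$stream$samples, c2$stream$samples))

  an <- classify_stream(a$stream)
  expect_length(an, 1)
  expect_true(an[[1]]$classification$valid)
  expect_equal(an[[1]]$metrics$max_volume_level, 5)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); runif(1)
  invisible(generate_valid_breath(sim_config(), seed = 9))
  expect_identical(runif(2), before[2:3])
})

test_that("every generated stream passes validation", {
  for (k in 1:20) {
    lab <- generate_protocol_suite(sim_config(), 3, 6, seed = 300 + k)
    expect_identical(validate_stream(lab$stream), list())
  }
})

test_that("each invalid mode yields exactly its targeted violation", {
  cfg <- sim_config(target_volume_level = 4)
  intended <- c(NONZERO_START = "NONZERO_START",
                TIP_DECREASE = "DECREASE_UNDER_FLOW",
                TOO_SHORT = "DURATION_OUT_OF_RANGE",
                TOO_LONG = "DURATION_OUT_OF_RANGE",
                LATE_RISE = "LATE_RISE",
                DROPOUT = "VOLUME_DROPOUT")
  for (mode in invalid_modes()) {
    for (k in 1:25) {
      lab <- generate_invalid_breath(mode, cfg, seed = 40 + k)
      an <- classify_stream(lab$stream)
      expect_length(an, 1)
      expect_false(an[[1]]$classification$valid)
      expect_equal(an[[1]]$classification$violations,
                   unname(intended[mode]),
                   label = paste(mode, "seed", 40 + k))
    }
  }
  expect_error(generate_invalid_breath("WOBBLE", cfg, 1), "arg")
})

test_that("classifier decisions match ground truth across many draws", {
  # scaled label-fidelity sweep across levels and modes
  n_ok <- 0L; n_tot <- 0L
  for (k in 1:40) {
    lab <- generate_protocol_suite(sim_config(), 10, 12, seed = 7000 + k)
    an <- classify_stream(lab$stream)
    expect_length(an, nrow(lab$truth))
    agree <- predicted_valid(an) == (lab$truth$label == "valid")
    n_ok <- n_ok + sum(agree); n_tot <- n_tot + length(agree)
  }
  expect_identical(n_ok, n_tot)  # 100% agreement, margins preclude ties
})

test_that("protocol suites have the requested composition and labels", {
  suite <- generate_protocol_suite(sim_config(), 65, 100, seed = 1)
  expect_equal(nrow(suite$truth), 165)
  expect_equal(sum(suite$truth$label == "valid"), 65)
  expect_equal(sum(suite$truth$label != "valid"), 100)
  expect_length(extract_breaths(suite$stream), 165)
  # valid breaths cycle the ten volume sensor levels
  expect_setequal(unique(suite$truth$target_level[suite$truth$label ==
                                                    "valid"]), 1:10)

  empty <- generate_protocol_suite(sim_config(), 0, 0, seed = 1)
  expect_equal(nrow(empty$truth), 0)
  expect_equal(nrow(empty$stream$samples), 0)

  s1 <- generate_protocol_suite(sim_config(), 10, 10, seed = 77)
  s2 <- generate_protocol_suite(sim_config(), 10, 10, seed = 77)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$stream$samples, s2$stream$samples)
})

test_that("simulated peak flows reproduce the measured band statistics", {
  cfg <- sim_config(flow_label = "best")
  flows <- vapply(1:1000, function(k)
    generate_valid_breath(cfg, seed = k)$truth$achieved_flow_lpm, 0)
  se <- 5.56 / sqrt(1000)
  expect_lt(abs(mean(flows) - 26.36), 3 * se)
  # and the discrete peak flow level is the band's level
  an <- classify_stream(generate_valid_breath(cfg, seed = 12)$stream)
  expect_equal(an[[1]]$metrics$max_flow_level, 3)
})

test_that("flowmeter readings embed display + dead volume + noise", {
  r <- generate_flowmeter_readings(183.75, 1000, n = 10, noise_sd = 0,
                                   seed = 2)
  expect_equal(r, rep(1183.75, 10))
  expect_equal(calibrate_dead_volume(r, 1000)$dead_volume_mL, 183.75)
  r1 <- generate_flowmeter_readings(50, 1000, n = 1, noise_sd = 0, seed = 2)
  expect_equal(calibrate_dead_volume(r1, 1000)$dead_volume_mL, 50)
})
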