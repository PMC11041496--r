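# Reference breath used across cases: t = 0..4 s at 0.5 s, one breath
# (segmentation ends it at the first of two trailing zeros in-stream).
ref_flow <- c(0, 2, 3, 2, 2, 1, 1, 1, 0)
ref_vol  <- c(0, 1, 3, 5, 5, 5, 5, 5, 5)

test_that("a well-formed breath satisfies all five criteria", {
  b <- make_breath(ref_flow, ref_vol)
  cl <- classify_breath(b)
  expect_true(cl$valid)
  expect_length(cl$violations, 0)
})

test_that("each criterion is violated by its targeted construction", {
  # (1) nonzero starting position
  cl <- classify_breath(make_breath(ref_flow, c(2, 2, 3, 5, 5, 5, 5, 5, 5)))
  expect_equal(cl$violations, "NONZERO_START")
  # (2) first rise after the 1.5 s window (here at 1.6 s)
  b <- make_breath(c(0, 1, 1, 1, 1, 1, 1, 0), c(0, 0, 0, 0, 1, 3, 3, 3),
                   dt = 0.4)
  expect_equal(classify_breath(b)$violations, "LATE_RISE")
  # (3) volume returns to zero mid-breath (flow zero at the drop)
  cl <- classify_breath(make_breath(c(0, 2, 2, 0, 2, 1, 1, 1, 0),
                                    c(0, 2, 4, 0, 4, 4, 4, 4, 4)))
  expect_equal(cl$violations, "VOLUME_DROPOUT")
  # (4) volume decrease while flow is positive (tipping)
  cl <- classify_breath(make_breath(ref_flow, c(0, 1, 3, 5, 4, 5, 5, 5, 5)))
  expect_equal(cl$violations, "DECREASE_UNDER_FLOW")
  # (5) valid shape compressed to 1.5 s < 2 s
  b <- make_breath(c(0, 2, 2, 1, 0), c(0, 2, 4, 4, 4), dt = 0.375)
  expect_equal(b$duration, 1.5)
  expect_equal(classify_breath(b)$violations, "DURATION_OUT_OF_RANGE")
  # a decrease with zero flow is allowed
  cl <- classify_breath(make_breath(c(0, 2, 2, 2, 1, 0, 1, 1, 0),
                                    c(0, 2, 4, 4, 4, 3, 3, 3, 3)))
  expect_true(cl$valid)
})

test_that("violation sets are complete, not short-circuited", {
  cl <- classify_breath(make_breath(c(0, 2, 2, 1, 0), c(1, 3, 2, 2, 2),
                                    dt = 0.25))
  expect_setequal(cl$violations,
                  c("NONZERO_START", "DECREASE_UNDER_FLOW",
                    "DURATION_OUT_OF_RANGE"))
  expect_false(cl$valid)
  # rise exactly at the window edge is timely; duration bounds inclusive
  b <- make_breath(c(0, 1, 1, 1, 0), c(0, 0, 0, 1, 1), dt = 0.5)
  expect_equal(classify_breath(b)$violations, character(0))
  b15 <- make_breath(c(0, rep(1, 14), 0), c(0, rep(3, 15)), dt = 1)
  expect_equal(b15$duration, 15)
  expect_true(classify_breath(b15)$valid)
})

test_that("breaths with fewer than two samples are rejected", {
  expect_error(classify_breath(make_breath(0, 0)), "malformed")
  expect_error(compute_metrics(make_breath(0, 0)), "malformed")
})

test_that("metrics report maxima, first-attainment time and rates", {
  m <- compute_metrics(make_breath(ref_flow, ref_vol))
  expect_equal(m$max_flow_level, 3)
  expect_equal(m$max_volume_level, 5)
  expect_equal(m$time_to_max_volume, 1.5)
  expect_equal(m$volume_ascent_rate, 5 / 1.5)
  expect_equal(m$volume_descent_rate, 0)
  expect_equal(m$duration, 4)

  # monotone rise 0 -> 4 over 2 s then flat
  m <- compute_metrics(make_breath(c(0, 1, 1, 1, 1, 1, 1, 1, 0),
                                   c(0, 1, 2, 3, 4, 4, 4, 4, 4), dt = 0.5))
  expect_equal(m$volume_ascent_rate, 2)
  expect_equal(m$volume_descent_rate, 0)

  # never rises: zero maxima and rates
  m <- compute_metrics(make_breath(c(0, 1, 1, 0, 0), rep(0, 5)))
  expect_equal(m$max_volume_level, 0)
  expect_equal(m$volume_ascent_rate, 0)

  # fall after the peak yields a positive descent rate
  m <- compute_metrics(make_breath(c(0, 2, 2, 0, 0, 0),
                                   c(0, 2, 4, 3, 2, 2)))
  expect_equal(m$time_to_max_volume, 1)
  expect_equal(m$volume_descent_rate, (4 - 2) / (2.5 - 1))
  expect_gte(m$time_to_max_volume, 0)
  expect_lte(m$time_to_max_volume, m$duration)
})

test_that("widening the rule windows never invalidates a valid breath", {
  set.seed(7)
  loose <- validity_params(rise_window = 1.2, min_duration = 2.5,
                           max_duration = 14)
  wider <- validity_params(rise_window = 1.4, min_duration = 2.2,
                           max_duration = 16)
  for (k in 1:50) {
    lab <- generate_protocol_suite(sim_config(), 2, 2, seed = 1000 + k)
    for (b in extract_breaths(lab$stream)) {
      if (classify_breath(b, loose)$valid)
        expect_true(classify_breath(b, wider)$valid)
    }
  }
})

test_that("classify_stream composes segmentation, rules and metrics", {
  # valid breath then a nonzero-start breath, back-to-back
  f <- c(0, 2, 3, 2, 2, 1, 1, 1, 0, 0, 0, 2, 3, 2, 2, 1, 1, 1, 0, 0)
  v <- c(0, 1, 3, 5, 5, 5, 5, 5, 5, 5, 2, 2, 3, 5, 5, 5, 5, 5, 5, 5)
  s <- sensor_stream(t = (seq_along(f) - 1) * 0.5, flow_level = f,
                     volume_level = v)
  a <- classify_stream(s)
  expect_length(a, 2)
  expect_true(a[[1]]$classification$valid)
  expect_false(a[[2]]$classification$valid)
  expect_equal(a[[2]]$classification$violations, "NONZERO_START")
  df <- as.data.frame(a)
  expect_equal(nrow(df), 2)
  expect_equal(df$valid, c(TRUE, FALSE))

  empty <- sensor_stream(numeric(0), integer(0), integer(0))
  expect_length(classify_stream(empty), 0)
})
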