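test_that("confusion counts and rates follow the bench-test arithmetic", {
  # 65 valid and 100 invalid breaths, one invalid classified valid
  truth <- rep(c("valid", "invalid"), c(65, 100))
  pred <- truth; pred[66] <- "valid"
  ev <- evaluate_classification(truth, pred)
  expect_equal(c(ev$tp, ev$fn, ev$tn, ev$fp), c(65, 0, 99, 1))
  expect_equal(ev$sensitivity, 100)
  expect_equal(ev$specificity, 99)

  perfect <- evaluate_classification(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$accuracy, 100)

  inverted <- evaluate_classification(rep(c(TRUE, FALSE), each = 3),
                                      rep(c(FALSE, TRUE), each = 3))
  expect_equal(inverted$sensitivity, 0)
  expect_equal(inverted$specificity, 0)

  expect_error(evaluate_classification(character(0), character(0)), "empty")
  expect_error(evaluate_classification(c(TRUE, FALSE), TRUE), "mismatch")
})

test_that("evaluate matches a brute-force count on random label pairs", {
  set.seed(31)
  for (k in 1:1000) {
    n <- sample(1:50, 1)
    truth <- runif(n) < 0.5
    pred <- ifelse(runif(n) < 0.8, truth, !truth)
    ev <- evaluate_classification(truth, pred)
    want <- oracle_evaluate(truth, pred)
    expect_equal(c(ev$tp, ev$fn, ev$tn, ev$fp),
                 unname(want[c("tp", "fn", "tn", "fp")]))
    if (any(truth)) expect_equal(ev$sensitivity, unname(want["sensitivity"]))
    if (!all(truth)) expect_equal(ev$specificity, unname(want["specificity"]))
  }
})

test_that("level summaries agree with an independent statistics oracle", {
  s <- summarize_by_level(data.frame(level = 1,
                                     measurement = c(0.5, 0.6, 0.7)))
  expect_equal(s$mean, 0.6)
  expect_equal(s$median, 0.6)
  expect_equal(s$min, 0.5)
  expect_equal(s$max, 0.7)

  set.seed(17)
  recs <- data.frame(level = sample(1:10, 400, replace = TRUE),
                     measurement = rnorm(400, 2, 0.5))
  got <- summarize_by_level(recs)
  for (i in seq_len(nrow(got))) {
    x <- recs$measurement[recs$level == got$level[i]]
    expect_equal(got$n[i], length(x))
    expect_equal(got$mean[i], sum(x) / length(x), tolerance = 1e-9)
    expect_equal(got$sd[i], sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
                 tolerance = 1e-9)
    expect_equal(got$median[i],
                 unname(quantile(x, 0.5, type = 7)), tolerance = 1e-9)
    expect_equal(c(got$q25[i], got$q75[i]),
                 unname(quantile(x, c(.25, .75), type = 7)),
                 tolerance = 1e-9)
    expect_equal(c(got$min[i], got$max[i]), range(x))
  }
})

test_that("single-measurement levels report sd 0 with a flag; absent levels are omitted", {
  s <- summarize_by_level(data.frame(level = 3, measurement = 1.2))
  expect_equal(s$n, 1)
  expect_equal(s$mean, 1.2)
  expect_equal(s$median, 1.2)
  expect_equal(s$sd, 0)
  expect_false(s$sd_defined)
  expect_message(
    s2 <- summarize_by_level(data.frame(level = 1, measurement = 1),
                             levels = c(1, 2)),
    "no measurements")
  expect_equal(s2$level, 1)
  # schema mirrors the range-table columns
  expect_true(all(c("level", "n", "mean", "sd", "median", "q25", "q75",
                    "min", "max") %in% names(s)))
})

test_that("sensor accuracy is the match percentage", {
  target <- rep(1:10, each = 10)
  recorded <- target; recorded[1] <- 2
  expect_equal(sensor_accuracy(target, recorded), 99)
  expect_equal(sensor_accuracy(1:5, 1:5), 100)
  expect_equal(sensor_accuracy(rep(1, 5), rep(2, 5)), 0)
  expect_error(sensor_accuracy(integer(0), integer(0)), "empty")
  expect_error(sensor_accuracy(1, 11), "range")
})

test_that("streaming emission equals batch classification", {
  lab <- generate_protocol_suite(sim_config(), 8, 10, seed = 55)
  batch <- classify_stream(lab$stream)
  s <- lab$stream$samples

  # sample-at-a-time feed
  p <- stream_processor()
  for (i in seq_len(nrow(s)))
    p$feed(s$t[i], s$flow_level[i], s$volume_level[i])
  ev <- p$events()
  expect_length(ev, length(batch))
  for (k in seq_along(ev)) {
    expect_identical(ev[[k]]$breath$samples, batch[[k]]$breath$samples)
    expect_equal(ev[[k]]$breath$start_index, batch[[k]]$breath$start_index)
    expect_equal(ev[[k]]$classification, batch[[k]]$classification)
    expect_equal(ev[[k]]$metrics, batch[[k]]$metrics)
  }

  # ragged chunked feed gives the same events
  p2 <- stream_processor()
  i <- 1L
  set.seed(2)
  while (i <= nrow(s)) {
    j <- min(nrow(s), i + sample(0:30, 1))
    p2$feed(s$t[i:j], s$flow_level[i:j], s$volume_level[i:j])
    i <- j + 1L
  }
  expect_equal(length(p2$events()), length(batch))
  expect_equal(p2$n_fed(), nrow(s))
})

test_that("a feed ending mid-breath never emits, and order errors are raised", {
  p <- stream_processor()
  p$feed(c(0, 0.1, 0.2), c(0L, 2L, 2L), c(0L, 1L, 2L))  # no terminator yet
  expect_length(p$events(), 0)
  expect_error(p$feed(0.15, 0L, 0L), class = "stream_order_error")
  expect_length(stream_processor()$events(), 0)
})

test_that("breaths are emitted as soon as their terminator arrives", {
  p <- stream_processor()
  out <- p$feed(c(0, 0.1, 0.2, 0.3), c(0L, 2L, 2L, 0L), c(0L, 1L, 2L, 2L))
  expect_length(out, 0)               # only one trailing zero so far
  out <- p$feed(0.4, 0L, 2L)          # second zero completes the pair
  expect_length(out, 1)
  expect_equal(out[[1]]$breath$start_index, 1L)
  expect_equal(out[[1]]$breath$end_index, 4L)
})
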