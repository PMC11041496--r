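#' Simulator configuration
#'
#' Parameterizes the synthetic sensor-stream generator that stands in for
#' the physical device and its human testers. A generated breath follows a
#' trapezoidal piston trajectory (rise, hold, settle), sampled at
#' `sample_rate_hz` with optional timing jitter and flow-level flicker.
#' Valid-mode breaths keep a safety margin inside every rule boundary so
#' that ground truth is unambiguous: the volume first rises within
#' `rise_max_s` seconds (against the 1.5 s rule) and the duration is drawn
#' from `duration_range_s` (against the 2--15 s rule).
#'
#' @param profile a [device_profile()].
#' @param target_volume_level intended peak volume level, 1--10.
#' @param flow_label `"good"`, `"better"` or `"best"` bobbin band; the
#'   breath's peak discrete flow level is the band's level (1--3) and its
#'   achieved flow in L/min is drawn from the band's measured mean and SD.
#' @param sample_rate_hz sampling rate, default 10.
#' @param jitter_sd SD of additive timing jitter on each sampling interval,
#'   seconds (clipped so timestamps stay strictly increasing).
#' @param flicker_prob per-sample probability that the flow level flickers
#'   within its positive range during the hold phase.
#' @param rise_max_s valid-mode margin: latest first volume rise, seconds;
#'   must be < the 1.5 s rule window.
#' @param duration_range_s valid-mode margin: duration range, seconds;
#'   must lie strictly inside the 2--15 s rule bounds.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(target_volume_level = 5, flow_label = "best")
#' @export
sim_config <- function(profile = device_profile("VOLDYNE_5000"),
                       target_volume_level = 5,
                       flow_label = c("best", "better", "good"),
                       sample_rate_hz = 10,
                       jitter_sd = 0.003,
                       flicker_prob = 0,
                       rise_max_s = 1.0,
                       duration_range_s = c(3, 10)) {
  flow_label <- match.arg(flow_label)
  stopifnot(inherits(profile, "device_profile"),
            target_volume_level %in% 1:10,
            sample_rate_hz > 0,
            jitter_sd >= 0,
            flicker_prob >= 0, flicker_prob <= 1,
            length(duration_range_s) == 2L)
  p <- validity_params()
  if (!(rise_max_s < p$rise_window &&
          duration_range_s[1] > p$min_duration &&
          duration_range_s[2] < p$max_duration))
    stop("margins must lie strictly inside the validity rule boundaries")
  structure(list(profile = profile,
                 target_volume_level = as.integer(target_volume_level),
                 flow_label = flow_label,
                 sample_rate_hz = sample_rate_hz,
                 jitter_sd = jitter_sd,
                 flicker_prob = flicker_prob,
                 rise_max_s = rise_max_s,
                 duration_range_s = as.numeric(duration_range_s)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %s, target level %d, flow '%s', %g Hz, valid margins: rise <= %g s, duration [%g, %g] s\n",
    x$profile$name, x$target_volume_level, x$flow_label, x$sample_rate_hz,
    x$rise_max_s, x$duration_range_s[1], x$duration_range_s[2]))
  invisible(x)
}

# Evaluate fn with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647), kind = "Mersenne-Twister")
  fn()
}

# Per-breath substream seed derived from (seed, index): regenerating breath
# k alone reproduces its samples regardless of the other breaths.
breath_seed <- function(seed, index) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %% 2147483629 + 1
}

# Jittered sample spacings for n intervals, strictly positive.
sample_dts <- function(n, cfg) {
  dt <- 1 / cfg$sample_rate_hz
  if (cfg$jitter_sd == 0) return(rep(dt, n))
  pmax(dt + stats::rnorm(n, 0, cfg$jitter_sd), 0.2 * dt)
}

# Core trapezoidal breath builder operating on the *current* RNG stream.
# Returns list(t, f, v, achieved_flow_lpm) for one breath unit: one leading
# zero-flow sample, a positive-flow body, two terminating zero-flow samples.
# `mode` is "valid" or one of the invalid construction names.
build_breath <- function(cfg, mode) {
  band <- cfg$profile$flow_bands
  row <- band[band$label == cfg$flow_label, ]
  peak_level <- row$level
  achieved <- abs(stats::rnorm(1, row$mean_lpm, row$sd_lpm))
  target <- cfg$target_volume_level
  if (mode == "TIP_DECREASE") target <- max(target, 2L)

  dur <- switch(mode,
    TOO_SHORT = stats::runif(1, 0.8, 1.5),
    TOO_LONG  = stats::runif(1, 16, 20),
    LATE_RISE = stats::runif(1, 6, 10),
    stats::runif(1, cfg$duration_range_s[1], cfg$duration_range_s[2]))
  rise_start <- switch(mode,
    LATE_RISE = stats::runif(1, 2.0, 3.0),
    0)
  rise_len <- switch(mode,
    TOO_SHORT = 0.3 * dur,
    stats::runif(1, 0.3, cfg$rise_max_s) * 0.9)

  n_body <- max(4L, ceiling(dur * cfg$sample_rate_hz))
  dts <- sample_dts(n_body + 2L, cfg)
  # rescale spacings up to the end sample so the duration is exactly `dur`
  idx <- seq_len(n_body + 1L)
  dts[idx] <- dts[idx] * (dur / sum(dts[idx]))
  t <- c(0, cumsum(dts))           # leading sample + body + 2 terminators
  n <- length(t)                   # = n_body + 3
  end_i <- n - 1L                  # first terminating zero = breath end

  # flow: zero at lead and the two terminators, positive in between
  f <- integer(n)
  body <- 2:(end_i - 1L)
  f[body] <- peak_level
  if (length(body) > 2L) f[body[length(body)]] <- 1L  # trailing decay
  if (cfg$flicker_prob > 0 && length(body) > 2L) {
    mid <- body[-c(1L, length(body))]
    flick <- stats::runif(length(mid)) < cfg$flicker_prob
    f[mid[flick]] <- sample.int(peak_level, sum(flick), replace = TRUE)
  }

  # volume: ramp from v0 to target over [rise_start, rise_start+rise_len]
  v0 <- 0L
  if (mode == "NONZERO_START") v0 <- sample.int(min(2L, target), 1L)
  tb <- t - t[1L]
  frac <- pmin(pmax((tb - rise_start) / rise_len, 0), 1)
  v <- v0 + as.integer(round(frac * (target - v0)))
  if (mode != "LATE_RISE" && v0 == 0L) {
    # guarantee the first body sample is already positive (timely rise)
    v[2:n][v[2:n] == 0L & tb[2:n] > rise_start] <- 1L
    v <- cummax(v)
  }
  v[n] <- 0L  # after breath end; outside the segmented breath

  if (mode == "TIP_DECREASE") {
    hold <- which(v == target & f > 0L)
    hold <- hold[hold > 3L & hold < end_i - 1L]
    k <- hold[ceiling(length(hold) / 2)]
    v[k] <- target - 1L            # dip under positive flow, then recover
  } else if (mode == "DROPOUT") {
    hold <- which(v == target)
    hold <- hold[hold > 3L & hold < end_i - 1L]
    k <- hold[ceiling(length(hold) / 2)]
    f[k] <- 0L                     # piston falls while flow pauses
    v[k] <- 0L                     # (a single zero-flow sample: no end)
  }
  list(t = t, f = f, v = v, achieved_flow_lpm = achieved,
       target_level = target)
}

finish_labeled <- function(t, f, v, truth, cfg) {
  stream <- sensor_stream(t, f, v, device = cfg$profile$name,
                          sample_rate_hz = cfg$sample_rate_hz)
  structure(list(stream = stream, truth = truth),
            class = "labeled_breath_stream")
}

#' @export
print.labeled_breath_stream <- function(x, ...) {
  cat(sprintf("<labeled_breath_stream> %d breath(s), %d samples\n",
              nrow(x$truth), nrow(x$stream$samples)))
  print(utils::head(x$truth, 10L))
  invisible(x)
}

#' Generate one valid synthetic breath
#'
#' Produces a single breath whose trapezoidal volume trajectory starts at
#' level 0, rises within the configured margin window to the target level,
#' holds under positive flow, and terminates with two zero-flow samples.
#' By construction it satisfies all five validity criteria with margin.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; identical seed and config give a byte-identical
#'   stream. The caller's RNG state is left untouched.
#' @return A `labeled_breath_stream`: list with `stream` (a
#'   [sensor_stream()]) and `truth` (data.frame with columns `breath`,
#'   `label`, `target_level`, `flow_label`, `achieved_flow_lpm`).
#' @examples
#' lab <- generate_valid_breath(sim_config(target_volume_level = 5), seed = 1)
#' classify_stream(lab$stream)
#' @export
generate_valid_breath <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  b <- with_seed(breath_seed(seed, 1L), function() build_breath(cfg, "valid"))
  finish_labeled(b$t, b$f, b$v,
                 data.frame(breath = 1L, label = "valid",
                            target_level = b$target_level,
                            flow_label = cfg$flow_label,
                            achieved_flow_lpm = b$achieved_flow_lpm), cfg)
}

#' Invalid-breath construction modes
#'
#' The two physical constructions used in bench testing -- starting the
#' piston above zero (`NONZERO_START`) and tipping the spirometer so the
#' piston falls during inhalation (`TIP_DECREASE`) -- plus direct timing
#' violations (`TOO_SHORT`, `TOO_LONG`, `LATE_RISE`) and a mid-breath
#' return of the piston to zero (`DROPOUT`), so that every classifier rule
#' is exercised.
#'
#' @return Character vector of mode names.
#' @export
invalid_modes <- function() {
  c("NONZERO_START", "TIP_DECREASE", "TOO_SHORT", "TOO_LONG",
    "LATE_RISE", "DROPOUT")
}

# Which violation each invalid mode is constructed to trigger.
mode_violation <- function(mode) {
  switch(mode,
         NONZERO_START = "NONZERO_START",
         TIP_DECREASE = "DECREASE_UNDER_FLOW",
         TOO_SHORT = "DURATION_OUT_OF_RANGE",
         TOO_LONG = "DURATION_OUT_OF_RANGE",
         LATE_RISE = "LATE_RISE",
         DROPOUT = "VOLUME_DROPOUT",
         stop("unknown invalid mode: ", mode))
}

#' Generate one invalid synthetic breath
#'
#' Produces a breath violating exactly the targeted criterion (with margin)
#' and no other; see [invalid_modes()] for the constructions.
#'
#' @param mode one of [invalid_modes()].
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return A `labeled_breath_stream` whose truth `label` is the mode name.
#' @examples
#' lab <- generate_invalid_breath("TIP_DECREASE",
#'                                sim_config(target_volume_level = 4),
#'                                seed = 1)
#' classify_stream(lab$stream)[[1]]$classification
#' @export
generate_invalid_breath <- function(mode, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  mode <- match.arg(mode, invalid_modes())
  b <- with_seed(breath_seed(seed, 1L), function() build_breath(cfg, mode))
  finish_labeled(b$t, b$f, b$v,
                 data.frame(breath = 1L, label = mode,
                            target_level = b$target_level,
                            flow_label = cfg$flow_label,
                            achieved_flow_lpm = b$achieved_flow_lpm), cfg)
}

#' Generate a labeled protocol suite of breaths
#'
#' Emulates the bench test protocol: a single concatenated stream of
#' `n_valid` valid and `n_invalid` invalid breaths with ground-truth
#' labels. Valid breaths cycle through volume levels 1--10 (as in the
#' 5-breaths-per-level protocol); invalid breaths cycle through
#' [invalid_modes()]. Breaths are interleaved and separated by zero-flow,
#' zero-volume gaps of at least two samples, so segmentation recovers
#' exactly `n_valid + n_invalid` breaths in truth order.
#'
#' @param cfg_base a [sim_config()]; its target level is overridden by the
#'   per-breath level cycle, other settings are shared.
#' @param n_valid,n_invalid non-negative breath counts.
#' @param seed integer seed; per-breath substreams are derived from
#'   `(seed, breath index)`.
#' @return A `labeled_breath_stream` whose truth has one row per breath in
#'   stream order.
#' @examples
#' suite <- generate_protocol_suite(sim_config(), 5, 5, seed = 42)
#' table(suite$truth$label)
#' @export
generate_protocol_suite <- function(cfg_base, n_valid, n_invalid, seed = 1L) {
  stopifnot(inherits(cfg_base, "sim_config"), n_valid >= 0, n_invalid >= 0)
  n <- n_valid + n_invalid
  if (n == 0L)
    return(finish_labeled(numeric(0), integer(0), integer(0),
                          data.frame(breath = integer(0),
                                     label = character(0),
                                     target_level = integer(0),
                                     flow_label = character(0),
                                     achieved_flow_lpm = numeric(0)),
                          cfg_base))
  # interleave valid and invalid breaths proportionally
  is_valid <- rep(FALSE, n)
  if (n_valid > 0)
    is_valid[round(seq(1, n, length.out = n_valid))] <- TRUE
  modes <- character(n)
  modes[is_valid] <- "valid"
  if (n_invalid > 0)
    modes[!is_valid] <- rep_len(invalid_modes(), n_invalid)
  levels_cycle <- rep_len(1:10, n)

  dt <- 1 / cfg_base$sample_rate_hz
  tt <- vector("list", n); ff <- vector("list", n); vv <- vector("list", n)
  truth <- vector("list", n)
  clock <- 0
  for (k in seq_len(n)) {
    cfg_k <- cfg_base
    cfg_k$target_volume_level <- levels_cycle[k]
    b <- with_seed(breath_seed(seed, k),
                   function() build_breath(cfg_k, modes[k]))
    # gap of 3 zero-flow samples before each breath after the first
    if (k > 1L) {
      gap_t <- clock + dt * (1:3)
      tt[[k]] <- c(gap_t, b$t + gap_t[3] + dt)
      ff[[k]] <- c(integer(3), b$f)
      vv[[k]] <- c(integer(3), b$v)
    } else {
      tt[[k]] <- b$t; ff[[k]] <- b$f; vv[[k]] <- b$v
    }
    clock <- tt[[k]][length(tt[[k]])]
    truth[[k]] <- data.frame(breath = k, label = modes[k],
                             target_level = b$target_level,
                             flow_label = cfg_base$flow_label,
                             achieved_flow_lpm = b$achieved_flow_lpm)
  }
  finish_labeled(unlist(tt), unlist(ff), unlist(vv),
                 do.call(rbind, truth), cfg_base)
}

#' Simulate raw flowmeter readings for dead-volume calibration
#'
#' Emulates holding the spirometer at a fixed display volume and reading
#' the in-line flowmeter `n` times: each raw reading is
#' `display + true_dead + noise` with zero-mean Gaussian noise. Feeding the
#' result to [calibrate_dead_volume()] recovers `true_dead_mL` within
#' sampling error.
#'
#' @param true_dead_mL true apparatus dead volume, mL.
#' @param display_mL spirometer display volume held during calibration, mL.
#' @param n number of breaths/readings.
#' @param noise_sd reading noise SD, mL.
#' @param seed integer seed.
#' @return Numeric vector of `n` raw readings in mL.
#' @examples
#' r <- generate_flowmeter_readings(183.75, 1000, n = 10, noise_sd = 0,
#'                                  seed = 1)
#' calibrate_dead_volume(r, 1000)
#' @export
generate_flowmeter_readings <- function(true_dead_mL, display_mL, n = 10,
                                        noise_sd = 15, seed = 1L) {
  stopifnot(n >= 1, true_dead_mL >= 0, display_mL > 0, noise_sd >= 0)
  with_seed(seed, function()
    display_mL + true_dead_mL + stats::rnorm(n, 0, noise_sd))
}
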