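#' Validity rule parameters
#'
#' The timing constants of the five breath-validity criteria: the volume
#' must first rise within `rise_window` seconds of breath start, and the
#' breath duration must lie in `[min_duration, max_duration]` (both ends
#' inclusive). Defaults are the device's rules: 1.5 s rise window, 2--15 s
#' duration.
#'
#' @param rise_window seconds; must satisfy `0 < rise_window < min_duration`.
#' @param min_duration,max_duration seconds, `min_duration < max_duration`.
#' @return An object of class `validity_params`.
#' @examples
#' validity_params()
#' @export
validity_params <- function(rise_window = 1.5, min_duration = 2,
                            max_duration = 15) {
  if (!(0 < rise_window && rise_window < min_duration &&
          min_duration < max_duration))
    stop("require 0 < rise_window < min_duration < max_duration")
  structure(list(rise_window = rise_window, min_duration = min_duration,
                 max_duration = max_duration), class = "validity_params")
}

#' @export
print.validity_params <- function(x, ...) {
  cat(sprintf(
    "<validity_params> rise within %.2g s; duration in [%.3g, %.3g] s\n",
    x$rise_window, x$min_duration, x$max_duration))
  invisible(x)
}

#' Classify a breath as valid or invalid
#'
#' Applies the five validity criteria to a segmented breath. A valid breath
#' must satisfy all of:
#'
#' 1. **zero start** -- the volume level of the first (zero-flow) sample is
#'    0; violation code `NONZERO_START`;
#' 2. **timely rise** -- some sample with volume level > 0 occurs within
#'    `rise_window` seconds of breath start; violation `LATE_RISE`;
#' 3. **no dropout** -- from the first positive-volume sample through the
#'    end sample the volume level never returns to 0; violation
#'    `VOLUME_DROPOUT`;
#' 4. **no decrease under flow** -- between consecutive samples the volume
#'    level never decreases while the later sample has positive flow (a
#'    drop with zero flow, e.g. the piston settling, is allowed); violation
#'    `DECREASE_UNDER_FLOW`;
#' 5. **duration in range** -- `min_duration <= duration <= max_duration`,
#'    both inclusive; violation `DURATION_OUT_OF_RANGE`.
#'
#' All five criteria are always evaluated (no short-circuiting), so the
#' violation set is complete.
#'
#' @param breath a `breath` from [extract_breaths()] with at least 2 samples.
#' @param params a [validity_params()].
#' @return An object of class `breath_classification`: list with `valid`
#'   (logical) and `violations` (character vector of violated criteria,
#'   empty iff valid).
#' @examples
#' b <- extract_breaths(sensor_stream(t = seq(0, 4.5, by = 0.5),
#'        flow_level = c(0, 2, 3, 2, 2, 1, 1, 1, 0, 0),
#'        volume_level = c(0, 1, 3, 5, 5, 5, 5, 5, 5, 5)))[[1]]
#' classify_breath(b)
#' @export
classify_breath <- function(breath, params = validity_params()) {
  stopifnot(inherits(breath, "breath"))
  s <- breath$samples
  if (nrow(s) < 2L) stop("malformed breath: fewer than 2 samples")
  v <- s$volume_level
  f <- s$flow_level
  t <- s$t
  violations <- character(0)
  # (1) volume starts at 0
  if (v[1L] != 0L) violations <- c(violations, "NONZERO_START")
  # (2) rises within the window
  pos <- which(v > 0L)
  rise_ok <- length(pos) > 0L && t[pos[1L]] <= t[1L] + params$rise_window
  if (!rise_ok) violations <- c(violations, "LATE_RISE")
  # (3) > 0 from first rise through the end sample
  if (length(pos) > 0L && any(v[pos[1L]:length(v)] == 0L))
    violations <- c(violations, "VOLUME_DROPOUT")
  # (4) no decrease while the later sample has positive flow
  if (nrow(s) > 1L) {
    dec <- diff(v) < 0L & f[-1L] > 0L
    if (any(dec)) violations <- c(violations, "DECREASE_UNDER_FLOW")
  }
  # (5) duration within bounds, inclusive
  if (breath$duration < params$min_duration ||
        breath$duration > params$max_duration)
    violations <- c(violations, "DURATION_OUT_OF_RANGE")
  structure(list(valid = length(violations) == 0L, violations = violations),
            class = "breath_classification")
}

#' @export
print.breath_classification <- function(x, ...) {
  if (x$valid) cat("<breath_classification> valid\n")
  else cat("<breath_classification> invalid:",
           paste(x$violations, collapse = ", "), "\n")
  invisible(x)
}

#' Compute per-breath metrics
#'
#' The metrics the device reports for each breath: maximum flow level,
#' maximum volume level, time to the *first* attainment of the maximum
#' volume (seconds from breath start), the volume ascent rate
#' (`max_volume_level / time_to_max_volume`, in levels/s; 0 when the volume
#' never rises or when the maximum is already held at the start sample),
#' the volume descent rate (`(max - final) / (end_t - t_first_max)` when
#' that span and drop are positive, else 0), and the breath duration.
#'
#' @param breath a `breath` with at least 2 samples.
#' @return An object of class `breath_metrics`: a list with fields
#'   `max_flow_level`, `max_volume_level`, `time_to_max_volume`,
#'   `volume_ascent_rate`, `volume_descent_rate`, `duration`.
#' @export
compute_metrics <- function(breath) {
  stopifnot(inherits(breath, "breath"))
  s <- breath$samples
  if (nrow(s) < 2L) stop("malformed breath: fewer than 2 samples")
  v <- s$volume_level
  max_v <- max(v)
  i_max <- which(v == max_v)[1L]
  ttm <- s$t[i_max] - breath$start_t
  ascent <- if (max_v > 0L && ttm > 0) max_v / ttm else 0
  fall <- max_v - v[nrow(s)]
  span <- breath$end_t - s$t[i_max]
  descent <- if (fall > 0L && span > 0) fall / span else 0
  structure(list(max_flow_level = max(s$flow_level),
                 max_volume_level = max_v,
                 time_to_max_volume = ttm,
                 volume_ascent_rate = ascent,
                 volume_descent_rate = descent,
                 duration = breath$duration),
            class = "breath_metrics")
}

#' @export
print.breath_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<breath_metrics> max flow %d, max volume %d, t(max vol) %.3f s,\n",
    "  ascent %.3f levels/s, descent %.3f levels/s, duration %.3f s\n"),
    x$max_flow_level, x$max_volume_level, x$time_to_max_volume,
    x$volume_ascent_rate, x$volume_descent_rate, x$duration))
  invisible(x)
}

#' Segment and classify every breath in a stream
#'
#' Runs the full pipeline on a batched log: [extract_breaths()], then
#' [classify_breath()] and [compute_metrics()] per breath, in stream order.
#'
#' @param stream a valid [sensor_stream()].
#' @param params a [validity_params()].
#' @return An object of class `breath_analysis`: a list of per-breath
#'   records, each with `breath`, `classification`, `metrics`. Has `print`,
#'   `summary` and [as.data.frame()] methods.
#' @examples
#' cfg <- sim_config(target_volume_level = 5)
#' lab <- generate_protocol_suite(cfg, n_valid = 3, n_invalid = 2, seed = 1)
#' classify_stream(lab$stream)
#' @export
classify_stream <- function(stream, params = validity_params()) {
  breaths <- extract_breaths(stream)
  recs <- lapply(breaths, function(b)
    list(breath = b, classification = classify_breath(b, params),
         metrics = compute_metrics(b)))
  structure(recs, class = "breath_analysis", params = params)
}

#' Coerce a breath analysis to a data frame
#'
#' @param x a `breath_analysis` from [classify_stream()].
#' @param ... unused.
#' @return A data.frame with one row per breath: indices, times, duration,
#'   validity, semicolon-joined violation codes, and all breath metrics.
#' @export
as.data.frame.breath_analysis <- function(x, ...) {
  if (length(x) == 0L)
    return(data.frame(start_index = integer(0), end_index = integer(0),
                      start_t = numeric(0), end_t = numeric(0),
                      duration = numeric(0), valid = logical(0),
                      violations = character(0),
                      max_flow_level = integer(0),
                      max_volume_level = integer(0),
                      time_to_max_volume = numeric(0),
                      volume_ascent_rate = numeric(0),
                      volume_descent_rate = numeric(0)))
  do.call(rbind, lapply(x, function(r)
    data.frame(start_index = r$breath$start_index,
               end_index = r$breath$end_index,
               start_t = r$breath$start_t, end_t = r$breath$end_t,
               duration = r$breath$duration,
               valid = r$classification$valid,
               violations = paste(r$classification$violations,
                                  collapse = ";"),
               max_flow_level = r$metrics$max_flow_level,
               max_volume_level = r$metrics$max_volume_level,
               time_to_max_volume = r$metrics$time_to_max_volume,
               volume_ascent_rate = r$metrics$volume_ascent_rate,
               volume_descent_rate = r$metrics$volume_descent_rate)))
}

#' @export
print.breath_analysis <- function(x, ...) {
  cat(sprintf("<breath_analysis> %d breath(s), %d valid\n", length(x),
              sum(vapply(x, function(r) r$classification$valid, TRUE))))
  if (length(x) > 0) print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' @export
summary.breath_analysis <- function(object, ...) {
  df <- as.data.frame(object)
  viol <- table(factor(unlist(lapply(object, function(r)
    r$classification$violations)), levels = VIOLATION_CODES))
  out <- list(n = nrow(df), n_valid = sum(df$valid),
              violation_counts = viol,
              duration = if (nrow(df)) summary(df$duration) else NULL,
              max_volume_level = if (nrow(df)) table(df$max_volume_level)
                                 else NULL)
  class(out) <- "summary.breath_analysis"
  out
}

#' @export
print.summary.breath_analysis <- function(x, ...) {
  cat(sprintf("Breath analysis: %d breaths, %d valid (%.1f%%)\n", x$n,
              x$n_valid, if (x$n) 100 * x$n_valid / x$n else NA_real_))
  if (x$n > 0) {
    cat("Violations:\n"); print(x$violation_counts)
    cat("Duration (s):\n"); print(x$duration)
  }
  invisible(x)
}
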