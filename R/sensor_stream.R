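#' Construct a sensor stream
#'
#' A sensor stream is the in-memory form of the add-on device's log: an
#' ordered sequence of time-stamped discrete sensor readings. Each sample
#' carries the time in seconds from the session origin, the flow level
#' (0 = no flow, 1 = "good", 2 = "better", 3 = "best") and the volume level
#' (0 = below the lowest sensor, k = highest triggered sensor; sensor k sits
#' at the k-th volume marking of the spirometer).
#'
#' @param t numeric vector of sample times in seconds; finite, non-negative,
#'   strictly increasing.
#' @param flow_level integer vector in 0--3, same length as `t`.
#' @param volume_level integer vector in 0--10, same length as `t`.
#' @param device device profile name stored in the stream metadata
#'   (e.g. `"VOLDYNE_5000"`). Must be non-empty.
#' @param sample_rate_hz optional sampling-rate hint in Hz, or `NA`.
#' @param session optional session identifier string.
#' @param validate if `TRUE` (default) the invariants are enforced and any
#'   violation raises an error; set `FALSE` to build a possibly invalid
#'   stream for inspection with [validate_stream()].
#'
#' @return An object of class `sensor_stream`: a list with `samples` (a
#'   data.frame with columns `t`, `flow_level`, `volume_level`) and `meta`
#'   (list with `device`, `sample_rate_hz`, `session`).
#'
#' @examples
#' s <- sensor_stream(t = c(0, 0.1, 0.2), flow_level = c(0, 1, 0),
#'                    volume_level = c(0, 1, 1))
#' s
#' @seealso [validate_stream()], [read_sensor_log()]
#' @export
sensor_stream <- function(t, flow_level, volume_level,
                          device = "VOLDYNE_5000", sample_rate_hz = NA_real_,
                          session = NA_character_, validate = TRUE) {
  if (length(t) != length(flow_level) || length(t) != length(volume_level))
    stop("t, flow_level and volume_level must have equal length")
  samples <- data.frame(t = as.numeric(t),
                        flow_level = as.integer(flow_level),
                        volume_level = as.integer(volume_level))
  obj <- structure(list(samples = samples,
                        meta = list(device = as.character(device),
                                    sample_rate_hz = as.numeric(sample_rate_hz),
                                    session = as.character(session))),
                   class = "sensor_stream")
  if (validate) {
    v <- validate_stream(obj)
    if (length(v) > 0)
      stop("invalid sensor stream: ", paste(vapply(v, `[[`, "", "message"),
                                            collapse = "; "))
  }
  obj
}

#' Validate a sensor stream
#'
#' Checks every stream invariant and returns the violations as data rather
#' than raising: timestamps finite, non-negative and strictly increasing;
#' flow levels in 0--3; volume levels in 0--10; non-empty device name in the
#' metadata. Total over any well-typed input.
#'
#' @param stream a `sensor_stream` (possibly built with `validate = FALSE`).
#' @return A list of violations, empty iff the stream is valid. Each entry
#'   is a list with `index` (sample row, or `NA` for metadata rules), `rule`
#'   (a short code) and `message`.
#' @examples
#' s <- sensor_stream(c(0, 0.1), c(0, 5), c(0, 0), validate = FALSE)
#' validate_stream(s)
#' @export
validate_stream <- function(stream) {
  stopifnot(inherits(stream, "sensor_stream"))
  s <- stream$samples
  out <- list()
  add <- function(index, rule, message)
    out[[length(out) + 1L]] <<- list(index = index, rule = rule,
                                     message = message)
  dev <- stream$meta$device
  if (length(dev) != 1L || is.na(dev) || !nzchar(dev))
    add(NA_integer_, "meta_device", "meta device name is empty")
  n <- nrow(s)
  if (n == 0L) return(out)
  bad_t <- which(!is.finite(s$t) | s$t < 0)
  for (i in bad_t)
    add(i, "time_range", sprintf("sample %d: t=%s not finite/non-negative",
                                 i, format(s$t[i])))
  if (n > 1L) {
    nondec <- which(diff(s$t) <= 0) + 1L
    for (i in nondec)
      add(i, "time_order",
          sprintf("sample %d: t=%s not greater than previous t=%s",
                  i, format(s$t[i]), format(s$t[i - 1L])))
  }
  bad_f <- which(is.na(s$flow_level) | s$flow_level < 0L |
                   s$flow_level > FLOW_LEVEL_MAX)
  for (i in bad_f)
    add(i, "flow_range", sprintf("sample %d: flow_level %s outside 0-%d",
                                 i, format(s$flow_level[i]), FLOW_LEVEL_MAX))
  bad_v <- which(is.na(s$volume_level) | s$volume_level < 0L |
                   s$volume_level > VOLUME_LEVEL_MAX)
  for (i in bad_v)
    add(i, "volume_range", sprintf("sample %d: volume_level %s outside 0-%d",
                                   i, format(s$volume_level[i]),
                                   VOLUME_LEVEL_MAX))
  out
}

#' @export
print.sensor_stream <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<sensor_stream> %d samples, device %s\n", n, x$meta$device))
  if (n > 0)
    cat(sprintf("  t: %.3f .. %.3f s; flow levels %d-%d; volume levels %d-%d\n",
                min(x$samples$t), max(x$samples$t),
                min(x$samples$flow_level), max(x$samples$flow_level),
                min(x$samples$volume_level), max(x$samples$volume_level)))
  invisible(x)
}

#' @export
length.sensor_stream <- function(x) nrow(x$samples)

#' Plot a sensor stream
#'
#' Draws the discrete flow and volume level traces against time as stepped
#' lines, the same encoding the device's companion display uses.
#'
#' @param x a `sensor_stream`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sensor_stream <- function(x, ...) {
  s <- x$samples
  if (nrow(s) == 0L) stop("cannot plot an empty stream")
  graphics::plot(s$t, s$volume_level, type = "s", col = "steelblue", lwd = 2,
                 xlab = "time (s)", ylab = "sensor level",
                 ylim = c(0, max(VOLUME_LEVEL_MAX, s$volume_level)), ...)
  graphics::lines(s$t, s$flow_level, type = "s", col = "firebrick", lwd = 2)
  graphics::legend("topright", legend = c("volume (0-10)", "flow (0-3)"),
                   col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
  invisible(x)
}
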