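#' Find breath boundaries in a sensor stream
#'
#' Scans the flow-level trace for breaths using the two boundary rules the
#' device's classifier is built on: a breath *starts* at a zero-flow sample
#' that immediately precedes a positive-flow sample, and *ends* at the first
#' of the first pair of consecutive zero-flow samples after the start.
#'
#' The second terminating zero is available to start the next breath, so
#' back-to-back breaths need only a two-sample gap. A trailing segment that
#' never reaches a two-zero terminator before the stream ends is discarded
#' (its count is available via `attr(, "n_discarded")`).
#'
#' @param stream a valid [sensor_stream()].
#' @return A data.frame with columns `start_index` and `end_index`
#'   (1-based positions into `stream$samples`), one row per breath, ordered
#'   and disjoint; attribute `n_discarded` counts incomplete trailing
#'   segments (0 or 1).
#' @examples
#' s <- sensor_stream(t = seq(0, 0.5, by = 0.1),
#'                    flow_level = c(0, 1, 2, 1, 0, 0),
#'                    volume_level = c(0, 1, 2, 3, 3, 3))
#' find_breath_boundaries(s)
#' @export
find_breath_boundaries <- function(stream) {
  stopifnot(inherits(stream, "sensor_stream"))
  f <- stream$samples$flow_level
  n <- length(f)
  starts <- integer(0)
  ends <- integer(0)
  discarded <- 0L
  i <- 1L
  while (i < n) {
    if (f[i] == 0L && f[i + 1L] > 0L) {
      # breath start; look for the first zero-zero pair after it
      j <- i + 2L
      end <- NA_integer_
      while (j < n) {
        if (f[j] == 0L && f[j + 1L] == 0L) { end <- j; break }
        j <- j + 1L
      }
      if (is.na(end)) { discarded <- 1L; break }
      starts <- c(starts, i)
      ends <- c(ends, end)
      i <- end + 1L  # second zero may start the next breath
    } else {
      i <- i + 1L
    }
  }
  out <- data.frame(start_index = starts, end_index = ends)
  attr(out, "n_discarded") <- discarded
  out
}

#' Extract breaths from a sensor stream
#'
#' Applies [find_breath_boundaries()] and materializes one `breath` object
#' per boundary pair, carrying the contiguous sample slice inclusive of both
#' endpoints and its duration in seconds.
#'
#' @param stream a valid [sensor_stream()].
#' @return A list of `breath` objects. Each is a list with `start_index`,
#'   `end_index`, `start_t`, `end_t`, `duration` and `samples` (the
#'   data.frame slice).
#' @examples
#' s <- sensor_stream(t = seq(0, 0.5, by = 0.1),
#'                    flow_level = c(0, 1, 2, 1, 0, 0),
#'                    volume_level = c(0, 1, 2, 3, 3, 3))
#' extract_breaths(s)[[1]]
#' @export
extract_breaths <- function(stream) {
  b <- find_breath_boundaries(stream)
  lapply(seq_len(nrow(b)), function(k)
    new_breath(stream, b$start_index[k], b$end_index[k]))
}

new_breath <- function(stream, start_index, end_index) {
  s <- stream$samples
  sl <- s[start_index:end_index, , drop = FALSE]
  rownames(sl) <- NULL
  structure(list(start_index = start_index,
                 end_index = end_index,
                 start_t = s$t[start_index],
                 end_t = s$t[end_index],
                 duration = s$t[end_index] - s$t[start_index],
                 samples = sl),
            class = "breath")
}

#' @export
print.breath <- function(x, ...) {
  cat(sprintf(
    "<breath> samples %d-%d, t %.3f-%.3f s (duration %.3f s), max volume level %d\n",
    x$start_index, x$end_index, x$start_t, x$end_t, x$duration,
    max(x$samples$volume_level)))
  invisible(x)
}
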