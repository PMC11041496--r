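#' Incremental (streaming) breath processor
#'
#' Creates a stateful processor that consumes sensor samples as they
#' arrive -- the mode in which the device drives a real-time consumer such
#' as a game controller -- and emits each breath's classification and
#' metrics as soon as its two-zero-flow terminator is seen. The full event
#' sequence over any feed equals [classify_stream()] on the batched input
#' (batch/stream equivalence); a feed ending mid-breath never emits that
#' breath.
#'
#' @param params a [validity_params()].
#' @return A list of closures:
#' \describe{
#'   \item{`feed(t, flow_level, volume_level)`}{append one or more samples
#'     (vectors are fine); returns the list of breath events completed by
#'     this chunk. Each event is a list with `breath`, `classification`,
#'     `metrics`; breath indices are absolute positions in the full feed.
#'     A non-increasing timestamp raises a `stream_order_error`.}
#'   \item{`events()`}{all events emitted so far.}
#'   \item{`n_fed()`}{number of samples consumed.}
#' }
#' @examples
#' lab <- generate_protocol_suite(sim_config(), 2, 1, seed = 7)
#' p <- stream_processor()
#' s <- lab$stream$samples
#' for (i in seq_len(nrow(s)))            # one sample at a time
#'   p$feed(s$t[i], s$flow_level[i], s$volume_level[i])
#' length(p$events())
#' @export
stream_processor <- function(params = validity_params()) {
  buf_t <- numeric(0)
  buf_f <- integer(0)
  buf_v <- integer(0)
  offset <- 0L       # absolute index of buf[1] minus 1
  last_t <- -Inf
  all_events <- list()

  emit_ready <- function() {
    events <- list()
    n <- length(buf_f)
    i <- 1L
    consumed <- 0L
    while (i < n) {
      if (buf_f[i] == 0L && buf_f[i + 1L] > 0L) {
        j <- i + 2L
        end <- NA_integer_
        while (j < n) {
          if (buf_f[j] == 0L && buf_f[j + 1L] == 0L) { end <- j; break }
          j <- j + 1L
        }
        if (is.na(end)) break   # wait for more samples
        sl <- data.frame(t = buf_t[i:end], flow_level = buf_f[i:end],
                         volume_level = buf_v[i:end])
        br <- structure(list(start_index = offset + i,
                             end_index = offset + end,
                             start_t = sl$t[1L],
                             end_t = sl$t[nrow(sl)],
                             duration = sl$t[nrow(sl)] - sl$t[1L],
                             samples = sl),
                        class = "breath")
        events[[length(events) + 1L]] <-
          list(breath = br, classification = classify_breath(br, params),
               metrics = compute_metrics(br))
        consumed <- end          # keep the second zero: may start the next
        i <- end + 1L
      } else {
        consumed <- i            # samples before any start are final
        i <- i + 1L
      }
    }
    if (consumed > 0L) {
      buf_t <<- buf_t[-seq_len(consumed)]
      buf_f <<- buf_f[-seq_len(consumed)]
      buf_v <<- buf_v[-seq_len(consumed)]
      offset <<- offset + consumed
    }
    events
  }

  feed <- function(t, flow_level, volume_level) {
    t <- as.numeric(t)
    if (length(t) == 0L) return(list())
    if (any(diff(c(last_t, t)) <= 0))
      stop(structure(class = c("stream_order_error", "error", "condition"),
                     list(message = "out-of-order timestamp in feed",
                          call = sys.call(-1))))
    fl <- as.integer(flow_level); vl <- as.integer(volume_level)
    if (any(fl < 0L | fl > FLOW_LEVEL_MAX) ||
          any(vl < 0L | vl > VOLUME_LEVEL_MAX))
      stop("sensor level out of range in feed")
    last_t <<- t[length(t)]
    buf_t <<- c(buf_t, t)
    buf_f <<- c(buf_f, fl)
    buf_v <<- c(buf_v, vl)
    ev <- emit_ready()
    all_events <<- c(all_events, ev)
    ev
  }

  list(feed = feed,
       events = function() all_events,
       n_fed = function() offset + length(buf_f))
}
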