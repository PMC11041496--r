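# Independent brute-force oracles, deliberately written in a different
# style from the package internals.

# Boundary oracle: enumerate all start candidates (zero flow immediately
# followed by positive flow) and all zero-zero pairs, then pair them up
# greedily from the left, re-using the second terminating zero.
oracle_boundaries <- function(f) {
  n <- length(f)
  starts <- which(f[-n] == 0 & f[-1] > 0)
  pair_first <- which(f[-n] == 0 & f[-1] == 0)
  out <- NULL
  cursor <- 1
  repeat {
    st <- starts[starts >= cursor]
    if (length(st) == 0) break
    st <- st[1]
    en <- pair_first[pair_first > st]
    if (length(en) == 0) break
    en <- en[1]
    out <- rbind(out, c(st, en))
    cursor <- en + 1
  }
  if (is.null(out)) out <- matrix(numeric(0), ncol = 2)
  colnames(out) <- c("start_index", "end_index")
  out
}

# Random discrete sensor stream as a level random walk.
random_stream <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0)
    return(sensor_stream(numeric(0), integer(0), integer(0)))
  f <- pmin(pmax(cumsum(sample(-1:1, n, replace = TRUE)), 0), 3)
  # sprinkle extra zeros so both boundary rules actually fire
  f[sample.int(n, max(1, n %/% 4))] <- 0
  v <- pmin(pmax(cumsum(sample(-1:1, n, replace = TRUE)), 0), 10)
  sensor_stream(t = seq_len(n) / 10, flow_level = f, volume_level = v)
}

# Confusion-count oracle: one explicit loop, no vectorized set logic.
oracle_evaluate <- function(truth_valid, pred_valid) {
  tp <- fn <- tn <- fp <- 0
  for (i in seq_along(truth_valid)) {
    if (truth_valid[i] && pred_valid[i]) tp <- tp + 1
    else if (truth_valid[i] && !pred_valid[i]) fn <- fn + 1
    else if (!truth_valid[i] && !pred_valid[i]) tn <- tn + 1
    else fp <- fp + 1
  }
  c(tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp))
}

predicted_valid <- function(analysis)
  vapply(analysis, function(r) r$classification$valid, logical(1))

# Hand-built breath object for direct classifier tests: one row per sample,
# 0.5 s spacing by default.
make_breath <- function(flow, volume, dt = 0.5) {
  s <- sensor_stream(t = (seq_along(flow) - 1) * dt, flow_level = flow,
                     volume_level = volume, validate = FALSE)
  spirobreath:::new_breath(s, 1L, length(flow))
}
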