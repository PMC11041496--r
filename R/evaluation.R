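#' Confusion-matrix evaluation of breath classification
#'
#' Compares predicted valid/invalid labels with ground truth. The positive
#' class is the *valid* breath: sensitivity is the percentage of truly
#' valid breaths classified valid, specificity the percentage of truly
#' invalid breaths classified invalid, accuracy the percentage of all
#' breaths classified correctly.
#'
#' @param truth,predicted equal-length label vectors. Logical vectors
#'   (`TRUE` = valid) or character vectors with values `"valid"` /
#'   `"invalid"`; any simulator truth label other than `"valid"` counts as
#'   invalid.
#' @return An object of class `evaluation_result`: list with counts `tp`,
#'   `fn`, `tn`, `fp` and percentages `sensitivity`, `specificity`,
#'   `accuracy` (full precision; the print method rounds to one decimal).
#'   Rates whose denominator is 0 are `NaN`.
#' @examples
#' evaluate_classification(rep(c(TRUE, FALSE), c(65, 100)),
#'                         rep(c(TRUE, FALSE, TRUE, FALSE), c(65, 0, 1, 99)))
#' @export
evaluate_classification <- function(truth, predicted) {
  if (length(truth) == 0L) stop("empty input")
  if (length(truth) != length(predicted)) stop("length mismatch")
  truth <- as_valid_logical(truth)
  predicted <- as_valid_logical(predicted)
  tp <- sum(truth & predicted)
  fn <- sum(truth & !predicted)
  tn <- sum(!truth & !predicted)
  fp <- sum(!truth & predicted)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 accuracy = 100 * (tp + tn) / length(truth)),
            class = "evaluation_result")
}

as_valid_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- as.character(x)
  if (any(is.na(x))) stop("labels must not be NA")
  x == "valid"
}

# round-half-up at `digits`, matching integer-percent reporting conventions
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result>\n")
  cat(sprintf("  tp %d  fn %d  tn %d  fp %d\n", x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%\n",
              round_half_up(x$sensitivity, 1), round_half_up(x$specificity, 1),
              round_half_up(x$accuracy, 1)))
  invisible(x)
}

#' Level-wise summary statistics
#'
#' Summarizes a per-breath measurement (volume in L or flow in L/min) by
#' sensor level, in the layout of the device's bench-test range tables:
#' n, mean (SD), median (IQR as the 25th--75th percentile pair), minimum
#' and maximum. Percentiles use linear interpolation
#' ([stats::quantile()] type 7). A level with a single measurement gets
#' `sd = 0` and `sd_defined = FALSE`; a requested level absent from the
#' records is omitted (with a message).
#'
#' @param records data.frame with columns `level` and `measurement`, or two
#'   vectors via `level` and `measurement` arguments.
#' @param levels levels to summarize; defaults to those present, sorted.
#' @return A data.frame of class `level_summary` with columns `level`, `n`,
#'   `mean`, `sd`, `sd_defined`, `median`, `q25`, `q75`, `min`, `max`.
#' @examples
#' summarize_by_level(data.frame(level = c(1, 1, 1, 2),
#'                               measurement = c(0.5, 0.6, 0.7, 1.1)))
#' @export
summarize_by_level <- function(records, levels = NULL) {
  stopifnot(is.data.frame(records),
            all(c("level", "measurement") %in% names(records)),
            all(is.finite(records$measurement)))
  if (is.null(levels)) levels <- sort(unique(records$level))
  rows <- lapply(levels, function(lv) {
    x <- records$measurement[records$level == lv]
    if (length(x) == 0L) {
      message("level ", lv, " has no measurements; omitted")
      return(NULL)
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(level = lv, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0,
               sd_defined = length(x) > 1L,
               median = q[2], q25 = q[1], q75 = q[3],
               min = min(x), max = max(x))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(level = numeric(0), n = integer(0),
                                      mean = numeric(0), sd = numeric(0),
                                      sd_defined = logical(0),
                                      median = numeric(0), q25 = numeric(0),
                                      q75 = numeric(0), min = numeric(0),
                                      max = numeric(0))
  class(out) <- c("level_summary", "data.frame")
  out
}

#' @export
print.level_summary <- function(x, digits = 3, ...) {
  if (nrow(x) == 0L) { cat("<level_summary> empty\n"); return(invisible(x)) }
  fmt <- function(v) formatC(v, digits = digits, format = "fg")
  tab <- data.frame(level = x$level, n = x$n,
                    `mean (SD)` = sprintf("%s (%s)", fmt(x$mean),
                                          ifelse(x$sd_defined, fmt(x$sd),
                                                 "N/A")),
                    `median (IQR)` = sprintf("%s (%s-%s)", fmt(x$median),
                                             fmt(x$q25), fmt(x$q75)),
                    min = fmt(x$min), max = fmt(x$max),
                    check.names = FALSE)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Sensor placement accuracy
#'
#' Percentage of breath attempts whose recorded sensor level equals the
#' targeted level.
#'
#' @param target_level,recorded_level equal-length integer vectors of
#'   levels (0--10).
#' @return Accuracy percentage.
#' @examples
#' sensor_accuracy(rep(1:10, each = 10),
#'                 c(2, rep(1, 9), rep(2:10, each = 10)))  # 99
#' @export
sensor_accuracy <- function(target_level, recorded_level) {
  if (length(target_level) == 0L) stop("empty attempts")
  if (length(target_level) != length(recorded_level))
    stop("length mismatch")
  rng <- range(c(target_level, recorded_level))
  if (rng[1] < 0 || rng[2] > VOLUME_LEVEL_MAX)
    stop("levels out of range 0-", VOLUME_LEVEL_MAX)
  100 * sum(target_level == recorded_level) / length(target_level)
}
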