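# Log format: CSV with header `t_s,flow_level,volume_level` ("." decimal
# mark, UTF-8, LF), or JSON-lines with keys t, flow_level, volume_level.
# An optional leading comment `# device=<name>` carries the device profile
# name into the stream metadata.

#' Read a sensor log
#'
#' Reads a time-stamped sensor-level stream from a file or from literal
#' text, standing in for the device's SD-card log. Two textual formats are
#' supported: CSV with header `t_s,flow_level,volume_level`, and JSON-lines
#' with one object per sample (keys `t`, `flow_level`, `volume_level`).
#' Lines starting with `#` are treated as comments; a `# device=<name>`
#' comment sets the device name in the stream metadata.
#'
#' All stream invariants are enforced: a malformed row raises a parse error
#' naming its line number, and non-increasing timestamps or out-of-range
#' levels raise validation errors.
#'
#' @param source path to a log file, or the log body itself as a character
#'   string (detected by the presence of a newline, or pass a
#'   `textConnection`-style literal).
#' @param format `"csv"` or `"jsonl"`.
#' @param device fallback device name when the log carries none.
#' @return A [sensor_stream()].
#' @examples
#' read_sensor_log("t_s,flow_level,volume_level\n0.0,0,0\n0.1,1,1\n0.2,0,1",
#'                 format = "csv")
#' @export
read_sensor_log <- function(source, format = c("csv", "jsonl"),
                            device = "VOLDYNE_5000") {
  format <- match.arg(format)
  is_path <- length(source) == 1L && !grepl("\n", source) &&
    file.exists(source)
  if (is_path) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(source, collapse = "\n"), "\n",
                             fixed = TRUE))
  }
  # comment header
  meta_device <- device
  is_comment <- grepl("^\\s*#", lines)
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("#\\s*device\\s*=\\s*(\\S+)", cl))[[1]]
    if (length(m) == 2L) meta_device <- m[2]
  }
  lineno <- seq_along(lines)
  keep <- !is_comment & nzchar(trimws(lines))
  body <- lines[keep]
  body_lineno <- lineno[keep]
  if (format == "csv") {
    if (length(body) > 0 && grepl("^\\s*t_s\\s*,", body[1])) {
      body <- body[-1]
      body_lineno <- body_lineno[-1]
    }
    if (length(body) == 0L) stop("empty sensor log: no samples")
    parts <- strsplit(body, ",", fixed = TRUE)
    bad <- which(vapply(parts, length, 0L) != 3L)
    if (length(bad) > 0)
      stop(sprintf("parse error at line %d: expected 3 comma-separated fields",
                   body_lineno[bad[1]]))
    mat <- matrix(suppressWarnings(as.numeric(trimws(unlist(parts)))),
                  ncol = 3L, byrow = TRUE)
    badnum <- which(apply(mat, 1L, function(r) any(is.na(r))))
    if (length(badnum) > 0)
      stop(sprintf("parse error at line %d: non-numeric field",
                   body_lineno[badnum[1]]))
    t <- mat[, 1L]; fl <- mat[, 2L]; vl <- mat[, 3L]
  } else {
    if (length(body) == 0L) stop("empty sensor log: no samples")
    recs <- vector("list", length(body))
    for (i in seq_along(body)) {
      rec <- tryCatch(jsonlite::fromJSON(body[i]),
                      error = function(e) NULL)
      if (is.null(rec) || !all(c("t", "flow_level", "volume_level")
                               %in% names(rec)))
        stop(sprintf("parse error at line %d: not a sample object",
                     body_lineno[i]))
      recs[[i]] <- rec
    }
    t <- vapply(recs, function(r) as.numeric(r$t), 0)
    fl <- vapply(recs, function(r) as.numeric(r$flow_level), 0)
    vl <- vapply(recs, function(r) as.numeric(r$volume_level), 0)
  }
  if (any(fl != floor(fl)) || any(vl != floor(vl)))
    stop("validation error: sensor levels must be integers")
  sensor_stream(t, fl, vl, device = meta_device)
}

#' Write a sensor log
#'
#' Serializes a sensor stream to CSV or JSON-lines text such that
#' [read_sensor_log()] reproduces it exactly; timestamps are written with
#' full double precision (17 significant digits) for a lossless round trip.
#' A `# device=<name>` comment header carries the metadata.
#'
#' @param stream a valid, non-empty [sensor_stream()].
#' @param format `"csv"` or `"jsonl"`.
#' @param path optional file path; if omitted the text is returned.
#' @return The log text as a single string (invisibly when `path` given).
#' @examples
#' s <- sensor_stream(c(0, 0.1), c(0, 1), c(0, 1))
#' cat(write_sensor_log(s))
#' @export
write_sensor_log <- function(stream, format = c("csv", "jsonl"),
                             path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(stream, "sensor_stream"))
  if (nrow(stream$samples) == 0L)
    stop("refusing to write an empty sensor stream")
  v <- validate_stream(stream)
  if (length(v) > 0) stop("refusing to write an invalid stream")
  s <- stream$samples
  ts <- formatC(s$t, digits = 17, format = "g")
  hdr <- sprintf("# device=%s", stream$meta$device)
  if (format == "csv") {
    rows <- sprintf("%s,%d,%d", ts, s$flow_level, s$volume_level)
    txt <- paste(c(hdr, "t_s,flow_level,volume_level", rows, ""),
                 collapse = "\n")
  } else {
    rows <- sprintf('{"t":%s,"flow_level":%d,"volume_level":%d}',
                    ts, s$flow_level, s$volume_level)
    txt <- paste(c(hdr, rows, ""), collapse = "\n")
  }
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path)
    return(invisible(txt))
  }
  txt
}
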