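#' Read and write session event logs as CSV
#'
#' Dialect: columns `time_s`, `event_type`, `lever`, `reinforced`; phase and
#' duration travel in the first two comment lines (`# phase=...`,
#' `# duration_s=...`).
#'
#' @param log An `event_log`.
#' @param path File path.
#' @return `read_event_log` returns an `event_log`; `write_event_log`
#'   returns `path` invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# phase=%s", attr(log, "phase")),
               sprintf("# duration_s=%g", attr(log, "duration_s"))), con)
  write.csv(as.data.frame(log), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  hdr <- readLines(path, n = 2)
  phase <- sub("^# phase=", "", hdr[1])
  duration_s <- as.numeric(sub("^# duration_s=", "", hdr[2]))
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  d$lever[is.na(d$lever)] <- NA_character_
  new_event_log(d, duration_s = duration_s, phase = phase)
}

#' Read and write trace matrices as CSV
#'
#' Neurons as rows, frames as columns; the frame rate travels in a leading
#' comment line.
#'
#' @param traces A [trace_matrix()].
#' @param path File path.
#' @export
write_traces_csv <- function(traces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate_hz=%g", frame_rate(traces)), con)
  write.csv(as.data.frame(unclass(traces)), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  fr <- as.numeric(sub("^# frame_rate_hz=", "", hdr))
  m <- as.matrix(read.csv(path, comment.char = "#"))
  dimnames(m) <- NULL
  trace_matrix(m, fr)
}

#' Read and write I-V curves as CSV
#'
#' Columns `voltage_mV`, `current_pA`.
#'
#' @param curve An `iv_curve`.
#' @param path File path.
#' @export
write_iv_csv <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_iv_csv
#' @export
read_iv_csv <- function(path) {
  d <- read.csv(path)
  iv_curve(d$voltage_mV, d$current_pA)
}

#' Read and write drug-wash series as CSV
#'
#' Columns `time_s`, `amplitude_pA`; the drug-on time travels in a leading
#' comment line.
#'
#' @param series A `wash_series`.
#' @param path File path.
#' @export
write_wash_csv <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# drug_on_s=%g", attr(series, "drug_on_s")), con)
  write.csv(as.data.frame(series), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wash_csv
#' @export
read_wash_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  d <- read.csv(path, comment.char = "#")
  wash_series(d$time_s, d$amplitude_pA,
              drug_on_s = as.numeric(sub("^# drug_on_s=", "", hdr)))
}

#' Read and write movie stacks as multi-page TIFF
#'
#' Requires the `tiff` package. Intensities are stored as 32-bit floats;
#' values should be scaled to \[0, 1\] or written with `scale = FALSE` kept
#' in mind by the caller.
#'
#' @param movie A [movie_stack()].
#' @param path File path.
#' @param frame_rate_hz Frame rate to attach on read.
#' @export
write_movie_tiff <- function(movie, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("TIFF I/O requires the tiff package", call. = FALSE)
  frames <- lapply(seq_len(dim(movie$frames)[3]),
                   function(k) movie$frames[, , k])
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, frame_rate_hz = 30) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("TIFF I/O requires the tiff package", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]]
  movie_stack(frames, frame_rate_hz)
}
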