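#' Uniformly sampled physiological waveform
#'
#' The raw substrate of the pipeline: one channel of pressure (or flow)
#' samples at a fixed rate, together with a per-sample validity mask.
#' Nothing is ever deleted from a waveform; cleaning operations only mark
#' samples invalid, so provenance is preserved through the whole pipeline.
#'
#' @param values numeric vector of samples, in channel units (mmHg for
#'   vascular/intracranial channels, cmH2O for airway/esophageal, L/s for
#'   flow).
#' @param fs sampling rate in Hz (>= 50 for waveform analysis; trend-level
#'   inputs may be slower).
#' @param channel channel name, e.g. `"ABP"`, `"ICP"`, `"PAW"`, `"PES"`,
#'   `"FLOW"`, `"PBO2"`.
#' @param start_time time of the first sample in seconds.
#' @param valid logical vector, same length as `values`; `FALSE` marks a
#'   sample as artifact/missing. Defaults to all valid (with `NA` samples
#'   marked invalid).
#' @return an object of class `"waveform"`.
#' @examples
#' wf <- waveform(sin(2 * pi * 1.5 * seq(0, 10, by = 0.01)), fs = 100,
#'                channel = "ICP")
#' wf
#' @export
waveform <- function(values, fs, channel = "ICP", start_time = 0,
                     valid = NULL) {
  stopifnot(is.numeric(values), length(values) > 0L,
            is.numeric(fs), length(fs) == 1L, fs > 0)
  if (is.null(valid)) valid <- !is.na(values)
  if (length(valid) != length(values))
    stop("`valid` must have the same length as `values`", call. = FALSE)
  structure(
    list(channel = as.character(channel), fs = as.numeric(fs),
         start_time = as.numeric(start_time),
         values = as.numeric(values), valid = as.logical(valid)),
    class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  dur <- length(x$values) / x$fs
  cat(sprintf("<waveform> %s: %d samples @ %g Hz (%.1f s), %.1f%% valid\n",
              x$channel, length(x$values), x$fs, dur,
              100 * mean(x$valid)))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$values)

#' Sample timestamps of a waveform
#'
#' @param x a [waveform()].
#' @return numeric vector of sample times in seconds (first sample at
#'   `start_time`).
#' @export
wf_time <- function(x) {
  stopifnot(inherits(x, "waveform"))
  x$start_time + (seq_along(x$values) - 1L) / x$fs
}

wf_end_time <- function(x) x$start_time + length(x$values) / x$fs

#' Mask manually identified artifact windows
#'
#' Marks all samples falling inside the given exclusion windows as invalid.
#' This mirrors the usual first cleaning pass on multimodal recordings,
#' where gross artifacts (probe handling, flushes, disconnections) are
#' excluded by time window before any automated rule runs. Samples are
#' masked, never removed.
#'
#' @param x a [waveform()].
#' @param windows a two-column matrix or data.frame of `(start, end)` times
#'   in seconds, or `NULL`/empty for no exclusions. Windows must be
#'   non-overlapping, satisfy `start < end`, and lie within the record span.
#' @return the waveform with an updated validity mask.
#' @export
apply_manual_exclusions <- function(x, windows) {
  stopifnot(inherits(x, "waveform"))
  if (is.null(windows) || NROW(windows) == 0L) return(x)
  w <- as.matrix(as.data.frame(windows)[, 1:2])
  if (any(w[, 1] >= w[, 2]))
    stop("exclusion windows must have start < end", call. = FALSE)
  o <- order(w[, 1])
  w <- w[o, , drop = FALSE]
  if (nrow(w) > 1L && any(w[-1L, 1] < w[-nrow(w), 2]))
    stop("exclusion windows must not overlap", call. = FALSE)
  if (w[1L, 1] < x$start_time - 1e-9 || w[nrow(w), 2] > wf_end_time(x) + 1e-9)
    stop("exclusion windows outside record span", call. = FALSE)
  tt <- wf_time(x)
  for (i in seq_len(nrow(w)))
    x$valid[tt >= w[i, 1] & tt < w[i, 2]] <- FALSE
  x
}

#' Write waveforms to long-format CSV
#'
#' One row per sample: `time_s, channel, value` (invalid samples written
#' with empty value). This is the package's plain-text interchange format;
#' [read_waveforms_csv()] round-trips it.
#'
#' @param waves a named list of [waveform()] objects (names ignored; the
#'   channel field is used).
#' @param path output file path.
#' @export
write_waveforms_csv <- function(waves, path) {
  if (inherits(waves, "waveform")) waves <- list(waves)
  rows <- lapply(waves, function(w) {
    v <- w$values
    v[!w$valid] <- NA_real_
    data.frame(time_s = wf_time(w), channel = w$channel, value = v)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read waveforms from long-format CSV
#'
#' @param path a CSV with columns `time_s, channel, value` and uniform
#'   sampling within each channel.
#' @return a named list of [waveform()] objects, one per channel.
#' @export
read_waveforms_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_s", "channel", "value") %in% names(d)))
  out <- lapply(split(d, d$channel), function(s) {
    s <- s[order(s$time_s), ]
    dt <- diff(s$time_s)
    if (length(dt) > 0L && diff(range(dt)) > 1e-6)
      stop("non-uniform sampling in channel ", s$channel[1L], call. = FALSE)
    fs <- if (length(dt) > 0L) 1 / stats::median(dt) else 1
    waveform(s$value, fs = fs, channel = s$channel[1L],
             start_time = s$time_s[1L])
  })
  out[order(names(out))]
}
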