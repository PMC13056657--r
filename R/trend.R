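#' 0.1 Hz trend series
#'
#' A coarse-grained series: one value per non-overlapping 10-s window of a
#' waveform, with the fraction of valid raw samples per window recorded as
#' `coverage`. Trend series are the substrate of all index computations and
#' period means.
#'
#' @param time window-end timestamps in seconds (fixed spacing).
#' @param value window means (NA where coverage fell below threshold).
#' @param coverage fraction of valid raw samples per window, in \[0, 1\].
#' @param variable variable name (e.g. `"ICP"`, `"ABP"`, `"CPP"`, `"AMP"`).
#' @param spacing window length in seconds (default 10).
#' @return a data.frame of class `"trend_series"` with columns
#'   `time`, `value`, `coverage` and attributes `variable`, `spacing`.
#' @export
trend_series <- function(time, value, coverage, variable, spacing = 10) {
  stopifnot(length(time) == length(value), length(value) == length(coverage))
  if (length(time) > 1L && diff(range(diff(time))) > 1e-9)
    stop("trend timestamps must be evenly spaced", call. = FALSE)
  structure(
    data.frame(time = as.numeric(time), value = as.numeric(value),
               coverage = as.numeric(coverage)),
    variable = as.character(variable), spacing = as.numeric(spacing),
    class = c("trend_series", "data.frame"))
}

trend_variable <- function(x) attr(x, "variable")

#' @export
print.trend_series <- function(x, ...) {
  cat(sprintf("<trend_series> %s: %d windows @ %g s, %d missing\n",
              trend_variable(x), nrow(x), attr(x, "spacing"),
              sum(is.na(x$value))))
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Coarse-grain a waveform to 0.1 Hz
#'
#' Averages non-overlapping fixed-length windows (default 10 s, i.e.
#' downsampling to 0.1 Hz). Each output value is the arithmetic mean of the
#' valid samples in its window; windows whose valid-sample fraction falls
#' below `min_coverage` emit a missing value. A trailing partial window is
#' dropped.
#'
#' @param x a [waveform()].
#' @param window window length in seconds.
#' @param min_coverage minimum fraction of valid samples for a window to
#'   emit a value (default 0.5).
#' @param variable name for the resulting trend; defaults to the channel.
#' @return a [trend_series()], timestamps at window ends.
#' @export
coarse_grain <- function(x, window = 10, min_coverage = 0.5,
                         variable = NULL) {
  stopifnot(inherits(x, "waveform"), window > 0)
  nper <- round(x$fs * window)
  if (nper < 1L) stop("window shorter than one sample", call. = FALSE)
  nwin <- floor(length(x$values) / nper)
  if (nwin == 0L)
    return(trend_series(numeric(0), numeric(0), numeric(0),
                        variable %||% x$channel, window))
  v <- x$values[seq_len(nwin * nper)]
  ok <- x$valid[seq_len(nwin * nper)]
  v[!ok] <- NA_real_
  m <- matrix(v, nrow = nper)
  cov <- colMeans(matrix(ok, nrow = nper))
  val <- colMeans(m, na.rm = TRUE)
  val[!is.finite(val)] <- NA_real_
  val[cov < min_coverage] <- NA_real_
  trend_series(x$start_time + window * seq_len(nwin), val, cov,
               variable %||% x$channel, window)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validity intervals for automated threshold rejection
#'
#' Closed (inclusive) physiological plausibility intervals per variable.
#' Defaults follow standard neuromonitoring practice: ICP outside
#' \[-10, 60\] mmHg and CPP outside \[0, 150\] mmHg are artifacts. Bounds
#' are retained: only values strictly below the lower or strictly above the
#' upper bound are rejected.
#'
#' @param ... named length-2 numeric vectors overriding or extending the
#'   defaults, e.g. `ABP = c(20, 250)`.
#' @return named list of `c(lower, upper)` intervals.
#' @export
validity_rules <- function(...) {
  rules <- list(ICP = c(-10, 60), CPP = c(0, 150))
  extra <- list(...)
  for (nm in names(extra)) {
    iv <- extra[[nm]]
    stopifnot(is.numeric(iv), length(iv) == 2L)
    if (iv[1L] >= iv[2L]) stop("lower bound must be < upper", call. = FALSE)
    rules[[nm]] <- as.numeric(iv)
  }
  rules
}

#' Reject trend values outside validity intervals
#'
#' Sets trend values outside the variable's closed interval to missing.
#' Idempotent; variables without a rule pass through unchanged.
#'
#' @param trend a [trend_series()].
#' @param rules a [validity_rules()] list.
#' @return the filtered trend series.
#' @export
threshold_filter <- function(trend, rules = validity_rules()) {
  stopifnot(inherits(trend, "trend_series"))
  iv <- rules[[trend_variable(trend)]]
  if (is.null(iv)) return(trend)
  bad <- !is.na(trend$value) & (trend$value < iv[1L] | trend$value > iv[2L])
  trend$value[bad] <- NA_real_
  trend
}

#' Cerebral perfusion pressure trend
#'
#' CPP = mean arterial pressure minus mean ICP, computed value-wise on
#' aligned 10-s trends. Missing wherever either input is missing.
#'
#' @param abp,icp aligned [trend_series()] with identical timestamps.
#' @return a `"CPP"` trend series; coverage is the elementwise minimum of
#'   the input coverages.
#' @export
cpp_trend <- function(abp, icp) {
  stopifnot(inherits(abp, "trend_series"), inherits(icp, "trend_series"))
  if (nrow(abp) != nrow(icp) || any(abs(abp$time - icp$time) > 1e-9))
    stop("ABP and ICP trends must share timestamps", call. = FALSE)
  trend_series(abp$time, abp$value - icp$value,
               pmin(abp$coverage, icp$coverage), "CPP",
               attr(abp, "spacing"))
}

#' Intracranial pulse amplitude trend
#'
#' Per 10-s window, the amplitude of the fundamental cardiac harmonic of
#' the ICP waveform: the peak of the single-sided amplitude spectrum within
#' the heart-rate band, in signal units (so a pure sinusoid `A*sin(...)` at
#' cardiac frequency yields AMP = A up to spectral-leakage error). A
#' time-domain peak-to-trough estimator is available as `method =
#' "timedomain"`; the spectral estimator is the default because it is
#' robust to slow drift and broadband noise within the window.
#'
#' @param x ICP [waveform()].
#' @param heart_rate_band frequency interval (Hz) containing the cardiac
#'   fundamental; must lie within (0.5, 5) Hz and below Nyquist.
#' @param window window length in seconds (default 10).
#' @param min_coverage minimum valid-sample fraction per window.
#' @param method `"spectral"` (default) or `"timedomain"`
#'   (half peak-to-trough of the window after mean removal).
#' @return an `"AMP"` [trend_series()].
#' @export
pulse_amplitude <- function(x, heart_rate_band = c(0.8, 3), window = 10,
                            min_coverage = 0.5,
                            method = c("spectral", "timedomain")) {
  stopifnot(inherits(x, "waveform"))
  method <- match.arg(method)
  b <- as.numeric(heart_rate_band)
  if (length(b) != 2L || b[1L] >= b[2L])
    stop("heart_rate_band must be an increasing interval", call. = FALSE)
  if (b[1L] < 0.5 || b[2L] > 5 || b[2L] > x$fs / 2)
    stop("heart_rate_band must lie within (0.5, 5) Hz and below Nyquist",
         call. = FALSE)
  nper <- round(x$fs * window)
  nwin <- floor(length(x$values) / nper)
  val <- rep(NA_real_, nwin)
  cov <- numeric(nwin)
  freqs <- (seq_len(nper) - 1L) / window        # FFT bin frequencies
  band_bins <- which(freqs >= b[1L] & freqs <= b[2L])
  for (k in seq_len(nwin)) {
    idx <- ((k - 1L) * nper + 1L):(k * nper)
    ok <- x$valid[idx]
    cov[k] <- mean(ok)
    if (cov[k] < min_coverage) next
    v <- x$values[idx]
    mu <- mean(v[ok])
    v[!ok] <- mu                                # fill gaps at window mean
    if (method == "spectral") {
      sp <- 2 * Mod(stats::fft(v - mu)) / nper  # single-sided amplitude
      val[k] <- max(sp[band_bins])
    } else {
      val[k] <- (max(v) - min(v)) / 2
    }
  }
  trend_series(x$start_time + window * seq_len(nwin), val, cov, "AMP",
               window)
}
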