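#' Minute-resolution reactivity index series
#'
#' Values are moving-window Pearson correlations in \[-1, 1\]; `n_pairs`
#' records how many complete trend pairs entered each window, for
#' provenance.
#'
#' @param time update timestamps in seconds.
#' @param value correlation values (NA where too few pairs or degenerate).
#' @param n_pairs number of complete pairs per window.
#' @param index index name, `"PRx"` or `"RAP"` (free-form allowed).
#' @return a data.frame of class `"index_series"`.
#' @export
index_series <- function(time, value, n_pairs, index) {
  stopifnot(length(time) == length(value), length(value) == length(n_pairs))
  if (any(abs(value) > 1 + 1e-12, na.rm = TRUE))
    stop("index values must lie in [-1, 1]", call. = FALSE)
  structure(
    data.frame(time = as.numeric(time), value = as.numeric(value),
               n_pairs = as.integer(n_pairs)),
    index = as.character(index),
    class = c("index_series", "data.frame"))
}

#' @export
print.index_series <- function(x, ...) {
  cat(sprintf("<index_series> %s: %d updates, %d missing\n",
              attr(x, "index"), nrow(x), sum(is.na(x$value))))
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Moving Pearson correlation between two trend series
#'
#' The workhorse behind PRx and RAP: at each update instant (every
#' `update_interval` seconds, anchored at the record start), the Pearson
#' correlation of the most recent `window_samples` paired trend values
#' (trailing window). Timestamps where either value is missing are dropped
#' from the window; a value is emitted only when at least `min_pairs`
#' complete pairs remain. Zero variance in either channel within a window
#' yields a missing value, not an error.
#'
#' @param x,y [trend_series()] with identical timestamps.
#' @param window_samples number of trend samples per window (default 30,
#'   i.e. 5 minutes of 10-s averages).
#' @param update_interval seconds between updates (default 60).
#' @param min_pairs minimum complete pairs per window (default 15, half the
#'   window).
#' @param index name for the resulting index series.
#' @return an [index_series()].
#' @export
moving_correlation <- function(x, y, window_samples = 30,
                               update_interval = 60, min_pairs = 15,
                               index = "r") {
  stopifnot(inherits(x, "trend_series"), inherits(y, "trend_series"))
  if (nrow(x) != nrow(y) || any(abs(x$time - y$time) > 1e-9))
    stop("trend series must share timestamps", call. = FALSE)
  sp <- attr(x, "spacing")
  step <- round(update_interval / sp)
  if (step < 1L) stop("update interval shorter than trend spacing",
                      call. = FALSE)
  n <- nrow(x)
  # anchor updates to multiples of update_interval from record start;
  # first update at the first grid point with a full trailing window
  first_update <- ceiling(window_samples / step) * step
  if (n < first_update)
    return(index_series(numeric(0), numeric(0), integer(0), index))
  ends <- seq.int(from = first_update, to = n, by = step)
  val <- rep(NA_real_, length(ends))
  npair <- integer(length(ends))
  for (j in seq_along(ends)) {
    i <- ends[j]
    xs <- x$value[(i - window_samples + 1L):i]
    ys <- y$value[(i - window_samples + 1L):i]
    ok <- !is.na(xs) & !is.na(ys)
    npair[j] <- sum(ok)
    if (npair[j] < min_pairs) next
    xs <- xs[ok]; ys <- ys[ok]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) next
    val[j] <- stats::cor(xs, ys)
  }
  index_series(x$time[ends], pmin(1, pmax(-1, val)), npair, index)
}

#' Pressure reactivity index (PRx)
#'
#' Moving Pearson correlation between 30 consecutive 10-s averages of
#' arterial blood pressure and intracranial pressure (5 minutes of data),
#' updated every minute. Positive values indicate passive, pressure-driven
#' ICP (impaired cerebrovascular reactivity); negative values indicate
#' active counter-regulation.
#'
#' @param abp_trend,icp_trend aligned 10-s [trend_series()].
#' @inheritParams moving_correlation
#' @return an [index_series()] named `"PRx"`.
#' @export
prx <- function(abp_trend, icp_trend, window_samples = 30,
                update_interval = 60, min_pairs = 15) {
  moving_correlation(abp_trend, icp_trend, window_samples,
                     update_interval, min_pairs, index = "PRx")
}

#' Compensatory reserve index (RAP)
#'
#' Computed in the same manner as [prx()], correlating intracranial pulse
#' amplitude (AMP) with mean ICP. Values near +1 indicate that pulse
#' amplitude rises with ICP, i.e. operation on the steep part of the
#' craniospinal pressure-volume curve (exhausted compensatory reserve).
#'
#' @param amp_trend,icp_trend aligned 10-s [trend_series()].
#' @inheritParams moving_correlation
#' @return an [index_series()] named `"RAP"`.
#' @export
rap <- function(amp_trend, icp_trend, window_samples = 30,
                update_interval = 60, min_pairs = 15) {
  moving_correlation(amp_trend, icp_trend, window_samples,
                     update_interval, min_pairs, index = "RAP")
}

#' Fisher transform of a correlation index
#'
#' `z = artanh(r)`, the variance-stabilizing transform applied to PRx/RAP
#' before statistical analysis. Values at exactly +/-1 are clipped to
#' +/-(1 - eps) so the transform stays finite.
#'
#' @param x an [index_series()] or numeric vector of correlations.
#' @param eps clipping margin at the boundary (default 1e-6).
#' @return same shape as the input, transformed.
#' @export
fisher_transform <- function(x, eps = 1e-6) {
  f <- function(r) atanh(pmin(1 - eps, pmax(-(1 - eps), r)))
  if (inherits(x, "index_series")) {
    out <- x
    out$value <- f(x$value)
    # transformed values can exceed 1 in magnitude; drop the class check
    class(out) <- "data.frame"
    attr(out, "index") <- paste0(attr(x, "index"), "_fisher")
    out
  } else f(x)
}

#' Inverse Fisher transform
#'
#' `r = tanh(z)`; the round trip `inverse_fisher(fisher_transform(r))`
#' is the identity to well below 1e-9 away from the clipping boundary.
#'
#' @param x a data.frame with a `value` column (as returned by
#'   [fisher_transform()]) or a numeric vector.
#' @return same shape as the input, back-transformed.
#' @export
inverse_fisher <- function(x) {
  if (is.data.frame(x)) {
    x$value <- tanh(x$value)
    x
  } else tanh(x)
}
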