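#' Two-channel fluorescence trace
#'
#' Pairs a calcium-sensitive channel (GCaMP6s) with a calcium-insensitive
#' reporter (tdTomato) acquired on the same cycle; their ratio cancels any
#' motion artifact shared multiplicatively by both channels.
#'
#' @param signal calcium-sensitive intensities, one per cycle.
#' @param reporter calcium-insensitive intensities; strictly positive.
#' @param cadence seconds per imaging cycle (default 1.5).
#' @param record_start recording start, hAEL.
#' @return a \code{dual_channel_trace}.
#' @export
dual_channel_trace <- function(signal, reporter, cadence = 1.5,
                               record_start = 0) {
  stopifnot(length(signal) == length(reporter), length(signal) >= 1L,
            all(is.finite(signal)), all(is.finite(reporter)), cadence > 0)
  structure(list(signal = as.numeric(signal),
                 reporter = as.numeric(reporter),
                 cadence = cadence, record_start = record_start),
            class = "dual_channel_trace")
}

#' Channel ratio of a two-channel trace
#'
#' Element-wise \code{signal / reporter}; errors if any reporter sample is
#' non-positive (listing the offending indices).
#'
#' @param d a [dual_channel_trace()].
#' @return numeric ratio series.
#' @export
ratio_trace <- function(d) {
  stopifnot(inherits(d, "dual_channel_trace"))
  bad <- which(d$reporter <= 0)
  if (length(bad)) {
    stop("non-positive reporter samples at indices: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L))
  }
  d$signal / d$reporter
}

#' Motion-corrected \eqn{\Delta F/F} trace
#'
#' The channel ratio minus its local baseline, where the baseline at each
#' cycle is the minimum of the ratio over a centred window of
#' \code{baseline_window} seconds (default 600 s = 10 min), shrinking at the
#' trace edges. With \code{normalise = TRUE} the baseline-subtracted value
#' is additionally divided by the baseline (conventional
#' \eqn{\Delta F/F_0}); the default follows the subtraction-only definition.
#'
#' @param d a [dual_channel_trace()].
#' @param baseline_window baseline window, seconds.
#' @param normalise divide by the baseline as well as subtracting it.
#' @return a \code{dff_trace}: \code{values} (dimensionless), \code{cadence},
#'   \code{record_start}, \code{baseline_window}.
#' @export
dff <- function(d, baseline_window = 600, normalise = FALSE) {
  stopifnot(inherits(d, "dual_channel_trace"), baseline_window > 0)
  r <- ratio_trace(d)
  w <- round(baseline_window / d$cadence)
  if (w %% 2L == 0L) w <- w + 1L  # centred window
  if (w > length(r)) {
    warning("trace shorter than the ", baseline_window,
            "-s baseline window; window shrinks to the trace")
    w <- length(r) - (1L - length(r) %% 2L)  # largest odd width <= n
  }
  base <- if (w <= 1L) r else {
    zoo::rollapply(zoo::zoo(r), width = w, FUN = min, align = "center",
                   partial = TRUE)
  }
  base <- as.numeric(base)
  vals <- r - base
  if (normalise) {
    if (any(base <= 0)) stop("non-positive baseline; cannot normalise")
    vals <- vals / base
  }
  structure(list(values = vals, cadence = d$cadence,
                 record_start = d$record_start,
                 baseline_window = baseline_window,
                 normalised = normalise),
            class = "dff_trace")
}

#' Summed \eqn{\Delta F/F} over a time window
#'
#' Whole-recording (or windowed) summation of \eqn{\Delta F/F}; negative
#' excursions are retained as-is.
#'
#' @param trace a \code{dff_trace}.
#' @param window \code{c(start, end)} hAEL, half-open; default spans the
#'   whole trace.
#' @return scalar sum.
#' @export
sum_dff <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "dff_trace"))
  times <- trace$record_start +
    (seq_along(trace$values) - 1L) * trace$cadence / 3600
  if (is.null(window)) return(sum(trace$values))
  if (window[2] <= window[1]) stop("empty window")
  idx <- which(times >= window[1] & times < window[2])
  if (length(idx) == 0L) stop("no samples in window")
  sum(trace$values[idx])
}

#' Count calcium transients in a \eqn{\Delta F/F} trace
#'
#' A transient is a maximal run of samples above \code{threshold}; returns
#' the onset times (seconds from record start) and peak amplitudes. Used to
#' recover injected events from synthetic recordings.
#'
#' @param trace a \code{dff_trace}.
#' @param threshold detection level, ratio units.
#' @return data.frame with \code{onset} (s), \code{peak} (\eqn{\Delta F/F}).
#' @export
count_transients <- function(trace, threshold) {
  stopifnot(inherits(trace, "dff_trace"), threshold > 0)
  above <- trace$values > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- r$values
  data.frame(
    onset = (starts[on] - 1L) * trace$cadence,
    peak = vapply(which(on), function(i) {
      max(trace$values[starts[i]:ends[i]])
    }, numeric(1)))
}
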