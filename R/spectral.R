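#' Sliding-window FFT spectrogram of a movement trace
#'
#' The movement trace (thresholded rectified MGV deviations) is cut into
#' windows of \code{window_length} seconds advanced by \code{step} seconds
#' (defaults 1 hr / 30 min, the settings of the original analysis); the
#' trailing partial window is discarded. Each window is mean-subtracted,
#' optionally tapered, and transformed; amplitudes are reported one-sided as
#' \code{2 |X_k| / N} with the DC bin excluded, so an on-bin sinusoid of
#' amplitude A yields a spectral amplitude of A under the rectangular taper.
#'
#' @param trace a \code{movement_trace} (or \code{raw_trace}).
#' @param window_length window, seconds; must be a whole number of samples.
#' @param step window advance, seconds.
#' @param taper \code{"rectangular"} (default, the most literal segment FFT)
#'   or \code{"hann"} for leakage-sensitive use.
#' @return a \code{spectrogram}: \code{amplitudes} (window x frequency
#'   matrix), \code{frequencies} (Hz, ascending, DC removed),
#'   \code{window_centers} (hAEL), plus the window, step and taper used.
#' @export
sliding_fft <- function(trace, window_length = 3600, step = 1800,
                        taper = c("rectangular", "hann")) {
  taper <- match.arg(taper)
  fr <- trace$frame_rate
  x <- trace$values
  win <- round(window_length * fr)
  stp <- max(1L, round(step * fr))
  if (abs(win - window_length * fr) > 1e-9) {
    stop("window_length must be a whole number of samples at ", fr, " Hz")
  }
  n <- length(x)
  if (n < win) {
    stop("trace (", n, " samples) shorter than one ", window_length,
         "-s window (", win, " samples); use a shorter window")
  }
  n_win <- (n - win) %/% stp + 1L
  w <- switch(taper,
              rectangular = rep(1, win),
              hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1L) / (win - 1L)))
  k_max <- win %/% 2L
  amps <- matrix(0, n_win, k_max)
  centers <- numeric(n_win)
  # taper amplitude correction so an on-bin sinusoid still reads A
  coherent_gain <- mean(w)
  for (j in seq_len(n_win)) {
    i0 <- (j - 1L) * stp + 1L
    seg <- x[i0:(i0 + win - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    a <- 2 * Mod(X[2L:(k_max + 1L)]) / (win * coherent_gain)
    if (win %% 2L == 0L) a[k_max] <- a[k_max] / 2  # Nyquist bin is unpaired
    amps[j, ] <- a
    centers[j] <- trace$record_start + (i0 - 1L + (win - 1L) / 2) / fr / 3600
  }
  structure(list(amplitudes = amps,
                 frequencies = (1:k_max) * fr / win,
                 window_centers = centers,
                 window_length = window_length, step = step, taper = taper,
                 embryo_label = trace$embryo_label %||% NA_character_),
            class = "spectrogram")
}

#' Average spectrograms across embryos
#'
#' Element-wise mean over spectrograms on identical frequency and window
#' grids; spectrograms with differing numbers of windows (e.g. traces
#' cropped at different hatch times) are aligned by window center and each
#' cell records how many embryos contributed.
#'
#' @param spectrograms list of \code{spectrogram}.
#' @param align_tol window-center alignment tolerance, hours.
#' @return a \code{spectrogram} with an extra \code{n_contributing} matrix.
#' @export
average_spectrogram <- function(spectrograms, align_tol = 1e-6) {
  stopifnot(length(spectrograms) >= 1L,
            all(vapply(spectrograms, inherits, logical(1), "spectrogram")))
  f0 <- spectrograms[[1L]]$frequencies
  for (s in spectrograms) {
    if (length(s$frequencies) != length(f0) ||
        max(abs(s$frequencies - f0)) > 1e-12) {
      stop("spectrograms have incompatible frequency grids")
    }
  }
  centers <- sort(unique(round(unlist(
    lapply(spectrograms, `[[`, "window_centers")) / align_tol)) * align_tol)
  total <- matrix(0, length(centers), length(f0))
  count <- matrix(0L, length(centers), length(f0))
  for (s in spectrograms) {
    ix <- vapply(s$window_centers, function(ct) {
      j <- which.min(abs(centers - ct))
      if (abs(centers[j] - ct) > align_tol) {
        stop("window centers not alignable within tolerance")
      }
      j
    }, integer(1))
    total[ix, ] <- total[ix, ] + s$amplitudes
    count[ix, ] <- count[ix, ] + 1L
  }
  avg <- total / pmax(count, 1L)
  avg[count == 0L] <- NA_real_
  out <- spectrograms[[1L]]
  out$amplitudes <- avg
  out$window_centers <- centers
  out$n_contributing <- count
  out$embryo_label <- NA_character_
  out
}

#' Period-amplitude distribution from a spectrogram
#'
#' Averages spectral amplitudes over the windows whose centers fall in
#' \code{time_window}, then re-indexes frequency as period \code{p = 1/f}
#' restricted to \code{band}. This is the per-embryo distribution of signal
#' amplitude across movement periods.
#'
#' @param spectrogram a \code{spectrogram}.
#' @param time_window \code{c(start, end)} hAEL; windows with centers inside
#'   it are used (default: all windows).
#' @param band \code{c(min_period, max_period)} seconds; default 4 s to half
#'   the FFT window (Nyquist-safe at 4 Hz up to 1800 s).
#' @return a \code{period_amplitude}: \code{periods} (seconds, ascending)
#'   and \code{amplitudes} aligned to them.
#' @export
period_amplitude <- function(spectrogram, time_window = NULL, band = NULL) {
  stopifnot(inherits(spectrogram, "spectrogram"))
  if (is.null(band)) band <- c(4, spectrogram$window_length / 2)
  if (band[2] <= band[1]) stop("empty period band")
  ctr <- spectrogram$window_centers
  use <- if (is.null(time_window)) seq_along(ctr) else {
    which(ctr >= time_window[1] & ctr < time_window[2])
  }
  if (length(use) == 0L) stop("time_window contains no spectrogram windows")
  mean_amp <- colMeans(spectrogram$amplitudes[use, , drop = FALSE],
                       na.rm = TRUE)
  periods <- 1 / spectrogram$frequencies
  keep <- periods >= band[1] & periods <= band[2]
  if (!any(keep)) stop("period band [", band[1], ", ", band[2],
                       "] s contains no frequency bins")
  ord <- order(periods[keep])
  structure(list(periods = periods[keep][ord],
                 amplitudes = mean_amp[keep][ord],
                 band = band,
                 embryo_label = spectrogram$embryo_label),
            class = "period_amplitude")
}

#' Summary periods of a period-amplitude distribution
#'
#' \code{modal_period} is the period with the largest mean amplitude (the
#' mode of the distribution); \code{weighted_period} is the
#' amplitude-weighted mean period, a continuous summary used for cohort
#' comparisons of bout frequency.
#'
#' @param pa a \code{period_amplitude}.
#' @return named numeric \code{c(modal_period, weighted_period)} in seconds.
#' @export
summarise_periods <- function(pa) {
  stopifnot(inherits(pa, "period_amplitude"))
  total <- sum(pa$amplitudes)
  c(modal_period = pa$periods[which.max(pa$amplitudes)],
    weighted_period = if (total > 0) {
      sum(pa$periods * pa$amplitudes) / total
    } else NA_real_)
}

#' Detect activity bouts in a movement trace
#'
#' The trace is smoothed with a centred moving average over
#' \code{smooth_window} seconds; a bout is a maximal run of samples strictly
#' above \code{bout_threshold}. Runs separated by gaps shorter than
#' \code{merge_gap} seconds are merged, then bouts shorter than
#' \code{min_duration} seconds are discarded. Deterministic.
#'
#' @param trace a \code{movement_trace}.
#' @param smooth_window smoothing window, seconds.
#' @param bout_threshold activity level defining a bout, MGV units; must be
#'   positive.
#' @param min_duration minimum bout length, seconds.
#' @param merge_gap gaps shorter than this are bridged, seconds.
#' @param time_window optional \code{c(start, end)} hAEL restricting
#'   detection (e.g. the neurogenic phase).
#' @return data.frame of bouts: \code{start}, \code{end} (hAEL),
#'   \code{duration} (seconds), \code{mean_amplitude} (smoothed MGV units).
#' @export
detect_bouts <- function(trace, smooth_window = 10, bout_threshold = 0.05,
                         min_duration = 5, merge_gap = 10,
                         time_window = NULL) {
  stopifnot(inherits(trace, "movement_trace"))
  if (bout_threshold <= 0) stop("bout_threshold must be positive")
  fr <- trace$frame_rate
  times <- trace_times(trace)
  x <- trace$values
  if (!is.null(time_window)) {
    idx <- window_indices(times, time_window[1], time_window[2])
    x <- x[idx]; times <- times[idx]
  }
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), mean_amplitude = numeric(0))
  if (length(x) == 0L) return(empty)
  sm_w <- max(1L, round(smooth_window * fr))
  if (sm_w %% 2L == 0L) sm_w <- sm_w + 1L  # odd: symmetric, no edge bias
  sm <- centred_mean(x, sm_w)
  above <- sm > bout_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0L) return(empty)
  # merge runs separated by short gaps
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) for (i in 2L:nrow(runs)) {
    gap_s <- (runs$start[i] - merged$end[nrow(merged)] - 1L) / fr
    if (gap_s < merge_gap) {
      merged$end[nrow(merged)] <- runs$end[i]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  dur <- (merged$end - merged$start + 1L) / fr
  keep <- dur >= min_duration
  merged <- merged[keep, , drop = FALSE]
  dur <- dur[keep]
  if (nrow(merged) == 0L) return(empty)
  data.frame(
    start = times[merged$start],
    end = times[merged$end] + 1 / fr / 3600,
    duration = dur,
    mean_amplitude = vapply(seq_len(nrow(merged)), function(i) {
      mean(sm[merged$start[i]:merged$end[i]])
    }, numeric(1)))
}

#' Summary statistics over a set of detected bouts
#'
#' @param bouts data.frame from [detect_bouts()].
#' @return list: \code{count}, \code{mean_duration}, \code{median_duration}
#'   (seconds; \code{NA} when no bouts), \code{mean_interval} (mean
#'   start-to-start interval, seconds; \code{NA} with fewer than two bouts).
#' @export
bout_stats <- function(bouts) {
  n <- nrow(bouts)
  list(count = n,
       mean_duration = if (n > 0) mean(bouts$duration) else NA_real_,
       median_duration = if (n > 0) stats::median(bouts$duration) else NA_real_,
       mean_interval = if (n > 1) mean(diff(bouts$start) * 3600) else NA_real_)
}
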