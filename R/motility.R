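#' Pipeline configuration for the motility analysis
#'
#' Defaults follow the original assay: a 60-frame (15 s at 4 Hz) centred
#' rolling-average baseline, a 0.01 MGV noise threshold determined against
#' unfertilised embryos, and fixed phase boundaries at 16 hAEL (myogenic
#' onset) and 18 hAEL (neurogenic onset).
#'
#' @param baseline_window rolling-baseline window, samples.
#' @param noise_threshold per-sample noise floor, MGV units; rectified
#'   deviations strictly below it are zeroed.
#' @param myogenic_start,neurogenic_start default phase boundaries, hAEL.
#' @param threshold_mode \code{"per_sample"} (default) zeroes sub-threshold
#'   samples before any summation; \code{"post_sum"} keeps raw rectified
#'   values and is provided for sensitivity analysis only.
#' @return a \code{pipeline_config}.
#' @export
pipeline_config <- function(baseline_window = 60L, noise_threshold = 0.01,
                            myogenic_start = 16.0, neurogenic_start = 18.0,
                            threshold_mode = c("per_sample", "post_sum")) {
  stopifnot(baseline_window >= 1L, noise_threshold >= 0,
            myogenic_start < neurogenic_start)
  structure(list(baseline_window = as.integer(baseline_window),
                 noise_threshold = noise_threshold,
                 myogenic_start = myogenic_start,
                 neurogenic_start = neurogenic_start,
                 threshold_mode = match.arg(threshold_mode)),
            class = "pipeline_config")
}

#' Centred rolling-average baseline of a raw MGV trace
#'
#' Moving average with a symmetric window (\code{window \%/\% 2} samples on
#' each side) that shrinks at the trace edges; same length as the input.
#' This is the slow background (gradual morphological change, tracheal
#' gas-filling) that is subtracted before rectification.
#'
#' @param trace a \code{raw_trace} (or bare numeric vector).
#' @param window window length in samples (default 60).
#' @return numeric baseline series.
#' @export
rolling_baseline <- function(trace, window = 60L) {
  x <- if (inherits(trace, "raw_trace")) trace$values else as.numeric(trace)
  centred_mean(x, window)
}

#' Detrend, rectify and noise-threshold a raw trace
#'
#' \code{value_i = |raw_i - baseline_i|}, then values strictly below
#' \code{noise_threshold} are set to exactly zero (per-sample mode). The
#' result is a \code{movement_trace} carrying the window and threshold used.
#'
#' @param trace a \code{raw_trace}.
#' @param config a [pipeline_config()].
#' @return a \code{movement_trace}: non-negative deviations plus metadata
#'   (\code{threshold_applied}, \code{baseline_window}, \code{hatch_time}
#'   once cropped).
#' @export
detrend_rectify <- function(trace, config = pipeline_config()) {
  stopifnot(inherits(trace, "raw_trace"), inherits(config, "pipeline_config"))
  dev <- abs(trace$values - rolling_baseline(trace, config$baseline_window))
  if (config$threshold_mode == "per_sample") {
    dev[dev < config$noise_threshold] <- 0
  }
  structure(list(values = dev, frame_rate = trace$frame_rate,
                 record_start = trace$record_start,
                 embryo_label = trace$embryo_label,
                 hatch_time = NA_real_,
                 threshold_applied = config$noise_threshold,
                 threshold_mode = config$threshold_mode,
                 baseline_window = config$baseline_window),
            class = "movement_trace")
}

#' Crop a movement trace at larval hatching
#'
#' Removes all samples at or after \code{hatch_time} and records the hatch
#' time on the trace. Hatch times are annotated (by the user or from
#' synthetic ground truth); see [suggest_hatch()] for an advisory candidate.
#'
#' @param trace a \code{movement_trace}.
#' @param hatch_time hatching time, hAEL.
#' @return the cropped \code{movement_trace}.
#' @export
crop_at_hatch <- function(trace, hatch_time) {
  stopifnot(inherits(trace, "movement_trace"), is.finite(hatch_time))
  if (hatch_time < trace$record_start) {
    stop("hatch_time (", hatch_time, " hAEL) precedes record start (",
         trace$record_start, " hAEL)")
  }
  times <- trace_times(trace)
  if (hatch_time > times[length(times)]) {
    warning("hatch_time after record end; trace unchanged")
    trace$hatch_time <- hatch_time
    return(trace)
  }
  trace$values <- trace$values[times < hatch_time]
  trace$hatch_time <- hatch_time
  trace
}

#' Advisory hatch-time candidate from a raw trace
#'
#' Hatching leaves the largest sustained step in the raw MGV late in the
#' recording. The candidate is the time, within the final third of the
#' record, of the largest absolute difference between the mean MGV over
#' \code{step_window} seconds after versus before each sample; ties go to
#' the earlier time. Confidence is the step size in units of the trace's
#' robust noise scale (median absolute deviation of first differences).
#' Advisory only — never applied automatically.
#'
#' @param trace a \code{raw_trace}.
#' @param step_window comparison window on each side, seconds.
#' @param min_confidence candidates below this confidence are suppressed.
#' @return list with \code{hatch_time} (hAEL, or \code{NA} if no candidate)
#'   and \code{confidence}.
#' @export
suggest_hatch <- function(trace, step_window = 30, min_confidence = 10) {
  stopifnot(inherits(trace, "raw_trace"))
  x <- trace$values
  n <- length(x)
  w <- max(2L, round(step_window * trace$frame_rate))
  if (n < 3L * w) return(list(hatch_time = NA_real_, confidence = 0))
  cs <- cumsum(c(0, x))
  idx <- seq.int(max(w + 1L, floor(2 * n / 3)), n - w)
  before <- (cs[idx] - cs[idx - w]) / w
  after <- (cs[idx + w] - cs[idx]) / w
  step <- abs(after - before)
  noise <- stats::mad(diff(x))
  conf <- if (noise > 0) max(step) / noise else Inf
  if (length(idx) == 0L || conf < min_confidence) {
    return(list(hatch_time = NA_real_, confidence = conf))
  }
  best <- idx[which.max(step)]  # which.max takes the earliest maximum
  list(hatch_time = trace_times(trace)[best], confidence = conf)
}

#' Phase windows for phase-wise quantification
#'
#' Default fixed-time windows — myogenic \code{[16, 18)} hAEL, neurogenic
#' \code{[18, hatch)} — clipped to the record window; annotated boundaries
#' override the defaults.
#'
#' @param trace a \code{movement_trace} (its record window and hatch time
#'   bound the phases).
#' @param config a [pipeline_config()].
#' @param boundaries optional annotated override,
#'   \code{c(myogenic_start, neurogenic_start)} in hAEL.
#' @return a \code{phase_windows} object: \code{myogenic} and
#'   \code{neurogenic} \code{c(start, end)} pairs, a \code{clipped} flag and
#'   the \code{source} ("fixed-times" or "annotated").
#' @export
segment_phases <- function(trace, config = pipeline_config(),
                           boundaries = NULL) {
  stopifnot(inherits(trace, "movement_trace"))
  myo_start <- config$myogenic_start
  neuro_start <- config$neurogenic_start
  source <- "fixed-times"
  if (!is.null(boundaries)) {
    stopifnot(length(boundaries) == 2L, boundaries[1] < boundaries[2])
    myo_start <- boundaries[1]; neuro_start <- boundaries[2]
    source <- "annotated"
  }
  times <- trace_times(trace)
  rec_start <- times[1L]
  rec_end <- times[length(times)] + 1 / trace$frame_rate / 3600
  neuro_end <- if (is.finite(trace$hatch_time)) {
    min(trace$hatch_time, rec_end)
  } else rec_end
  myo <- c(max(myo_start, rec_start), min(neuro_start, rec_end))
  neuro <- c(max(neuro_start, rec_start), neuro_end)
  clipped <- myo[1] > myo_start || neuro[2] < neuro_end
  if (myo[2] <= myo[1] && neuro[2] <= neuro[1]) {
    stop("record window overlaps neither the myogenic nor the neurogenic phase")
  }
  structure(list(myogenic = myo, neurogenic = neuro,
                 clipped = myo[1] > myo_start, source = source),
            class = "phase_windows")
}

#' Summed movement over a time window
#'
#' The quantity plotted per phase in the original assay: the sum of
#' thresholded rectified MGV deviations over all samples in the half-open
#' window \code{[start, end)}, in intensity-samples.
#'
#' @param trace a \code{movement_trace}.
#' @param window \code{c(start, end)} in hAEL (e.g. a component of
#'   [segment_phases()]).
#' @return scalar movement sum.
#' @export
quantify_phase <- function(trace, window) {
  stopifnot(inherits(trace, "movement_trace"), length(window) == 2L)
  if (window[2] <= window[1]) stop("empty quantification window")
  idx <- window_indices(trace_times(trace), window[1], window[2])
  if (length(idx) == 0L) stop("no samples in window [", window[1], ", ",
                              window[2], ") hAEL")
  sum(trace$values[idx])
}

#' Phase-wise quantification table for a cohort
#'
#' Runs detrend/rectify, hatch cropping, phase segmentation and phase
#' summation over a list of raw traces and returns one tidy row per embryo
#' and phase. Excluded traces are dropped (with their reason carried in the
#' attribute \code{"excluded"}).
#'
#' @param traces named list of \code{raw_trace}.
#' @param hatch_times named numeric vector of hatch annotations (hAEL),
#'   matched to traces by label; missing labels are left uncropped.
#' @param config a [pipeline_config()].
#' @param genotype optional character vector (one per trace) carried into
#'   the output.
#' @return data.frame with columns \code{embryo}, \code{genotype},
#'   \code{phase}, \code{movement_sum}, \code{n_samples}, \code{clipped}.
#' @export
quantify_cohort <- function(traces, hatch_times = NULL,
                            config = pipeline_config(), genotype = NULL) {
  stopifnot(length(traces) >= 1L)
  if (is.null(genotype)) genotype <- rep(NA_character_, length(traces))
  keep <- !vapply(traces, `[[`, logical(1), "excluded")
  dropped <- names(traces)[!keep]
  rows <- list()
  for (i in which(keep)) {
    tr <- traces[[i]]
    mt <- detrend_rectify(tr, config)
    ht <- hatch_times[tr$embryo_label]
    if (!is.null(ht) && length(ht) == 1L && is.finite(ht)) {
      mt <- suppressWarnings(crop_at_hatch(mt, ht))
    }
    ph <- segment_phases(mt, config)
    for (phase in c("myogenic", "neurogenic")) {
      win <- ph[[phase]]
      if (win[2] <= win[1]) next
      idx <- window_indices(trace_times(mt), win[1], win[2])
      rows[[length(rows) + 1L]] <- data.frame(
        embryo = tr$embryo_label, genotype = genotype[i], phase = phase,
        movement_sum = sum(mt$values[idx]), n_samples = length(idx),
        clipped = ph$clipped, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- dropped
  out
}
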