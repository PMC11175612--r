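#' Generate one synthetic embryo MGV recording with ground truth
#'
#' Simulates a per-embryo mean-grey-value (MGV) trace with the structure the
#' motility pipeline assumes: a slow baseline (linear drift, a smooth
#' tracheal gas-filling step, a hatching discontinuity), a myogenic phase of
#' Poisson-timed biphasic movement pulses, a neurogenic phase of periodic
#' activity bouts carrying a within-bout oscillation, and additive Gaussian
#' sensor noise. The movement signal is identically zero before
#' \code{movement_onset} and from \code{hatch_time} onwards.
#'
#' Myogenic pulses are one full sine cycle lasting one second, so each pulse
#' (and the within-bout oscillation, whose frequency defaults to 1 Hz at a
#' 4 Hz frame rate) is zero-mean over the detrending window; the rolling
#' baseline then tracks only the slow drift and the injected rectified
#' movement is recoverable by the pipeline.
#'
#' @param preset a [genotype_preset()].
#' @param frame_rate sampling rate, Hz.
#' @param record_start recording start, hAEL.
#' @param record_duration recording length, hours.
#' @param seed integer seed; the trace is a deterministic function of
#'   \code{(preset, frame_rate, record_start, record_duration, seed)}.
#' @param baseline_level constant MGV offset of the recording (default 100,
#'   a typical mid-range camera value; the pipeline is offset-invariant).
#' @return a list with components \code{trace} (a \code{raw_trace}) and
#'   \code{truth} (a \code{ground_truth} with \code{bout_intervals},
#'   \code{phase_boundaries} and \code{injected_total_activity}, the sum of
#'   the rectified injected movement signal in intensity-samples).
#' @export
generate_trace <- function(preset, frame_rate = 4, record_start = 14.0,
                           record_duration = 8.0, seed = 1L,
                           baseline_level = 100) {
  stopifnot(inherits(preset, "genotype_preset"),
            frame_rate > 0, record_duration > 0)
  n <- round(record_duration * 3600 * frame_rate)
  times <- record_start + (seq_len(n) - 1L) / frame_rate / 3600
  record_end <- record_start + record_duration

  if (record_end <= preset$movement_onset || record_start >= preset$hatch_time) {
    warning("record window does not overlap the movement window [",
            preset$movement_onset, ", ", preset$hatch_time,
            "] hAEL; trace is drift + noise only")
  }

  # slow baseline: linear drift + logistic gas-filling step + hatch step
  tau_s <- preset$gasfill_rise / (2 * log(9))  # 10-90% rise -> logistic scale
  drift <- baseline_level +
    preset$drift_slope * (times - record_start) +
    preset$gasfill_step * stats::plogis((times - preset$gasfill_time) * 3600 / tau_s) +
    preset$hatch_step * (times >= preset$hatch_time)

  movement <- numeric(n)
  bouts <- data.frame(start = numeric(0), end = numeric(0))

  out <- with_seed(seed, {
    # myogenic phase: Poisson pulses, gamma amplitudes, 1-s biphasic shape
    myo_lo <- max(preset$movement_onset, record_start)
    myo_hi <- min(preset$rhythmic_onset, record_end)
    pulse_samples <- max(2L, round(frame_rate))  # one sine cycle over ~1 s
    pulse_shape <- sin(2 * pi * (seq_len(pulse_samples) - 1L) / pulse_samples)
    if (myo_hi > myo_lo && preset$myogenic_event_rate > 0) {
      dur_min <- (myo_hi - myo_lo) * 60
      n_ev <- stats::rpois(1L, preset$myogenic_event_rate * dur_min)
      if (n_ev > 0) {
        ev_t <- sort(stats::runif(n_ev, myo_lo, myo_hi - pulse_samples /
                                    frame_rate / 3600))
        ev_a <- stats::rgamma(n_ev, shape = preset$myogenic_event_shape,
                              rate = preset$myogenic_event_shape /
                                max(preset$myogenic_event_mean, .Machine$double.eps))
        if (preset$myogenic_event_mean == 0) ev_a <- rep(0, n_ev)
        for (k in seq_len(n_ev)) {
          i0 <- floor((ev_t[k] - record_start) * 3600 * frame_rate) + 1L
          idx <- i0:(i0 + pulse_samples - 1L)
          keep <- idx >= 1L & idx <= n
          movement[idx[keep]] <- movement[idx[keep]] +
            ev_a[k] * pulse_shape[keep]
        }
      }
    }

    # neurogenic phase: periodic bouts with within-bout oscillation
    if (preset$bout_amplitude > 0 && preset$bout_duration > 0) {
      phase_len_s <- (preset$hatch_time - preset$rhythmic_onset) * 3600
      k_max <- ceiling(phase_len_s / preset$bout_period)
      starts_s <- (seq_len(k_max) - 1L) * preset$bout_period
      if (preset$bout_jitter_sd > 0) {
        starts_s <- sort(starts_s +
                           stats::rnorm(k_max, 0, preset$bout_jitter_sd))
      }
      starts_s <- starts_s[starts_s < phase_len_s & starts_s >= 0]
      for (s0 in starts_s) {
        b_start <- preset$rhythmic_onset + s0 / 3600
        b_end <- min(b_start + preset$bout_duration / 3600, preset$hatch_time)
        bouts <- rbind(bouts, data.frame(start = b_start, end = b_end))
        idx <- which(times >= b_start & times < b_end)
        if (length(idx)) {
          t_rel <- (times[idx] - b_start) * 3600
          movement[idx] <- movement[idx] + preset$bout_amplitude *
            sin(2 * pi * preset$within_bout_freq * t_rel)
        }
      }
    }

    # hard phase purity: no movement outside [movement_onset, hatch_time)
    movement[times < preset$movement_onset | times >= preset$hatch_time] <- 0

    noise <- if (preset$noise_sd > 0) stats::rnorm(n, 0, preset$noise_sd) else numeric(n)
    list(movement = movement, noise = noise, bouts = bouts)
  })

  trace <- raw_trace(drift + out$movement + out$noise,
                     frame_rate = frame_rate, record_start = record_start,
                     embryo_label = preset$name)
  truth <- structure(list(
    bout_intervals = out$bouts,
    phase_boundaries = c(movement_onset = preset$movement_onset,
                         rhythmic_onset = preset$rhythmic_onset,
                         hatch_time = preset$hatch_time),
    injected_total_activity = sum(abs(out$movement)),
    calcium_event_times = NULL
  ), class = "ground_truth")
  list(trace = trace, truth = truth)
}

#' Generate a cohort of synthetic recordings
#'
#' One trace per embryo, with per-embryo seeds derived deterministically from
#' the master seed so a cohort is reproducible bit-for-bit.
#'
#' @param spec a [cohort_spec()].
#' @return list with \code{traces} (list of \code{raw_trace}), \code{truths}
#'   (list of \code{ground_truth}), and \code{genotype} (character vector of
#'   preset names, one per embryo).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  total <- sum(spec$n_embryos)
  seeds <- with_seed(spec$seed,
                     sample.int(.Machine$integer.max - 1L, total))
  traces <- vector("list", total)
  truths <- vector("list", total)
  genotype <- character(total)
  i <- 0L
  for (p in seq_along(spec$presets)) {
    preset <- spec$presets[[p]]
    for (e in seq_len(spec$n_embryos[p])) {
      i <- i + 1L
      res <- generate_trace(preset, frame_rate = spec$frame_rate,
                            record_start = spec$record_start,
                            record_duration = spec$record_duration,
                            seed = seeds[i])
      res$trace$embryo_label <- sprintf("%s_%02d", preset$name, e)
      traces[[i]] <- res$trace
      truths[[i]] <- res$truth
      genotype[i] <- preset$name
    }
  }
  names(traces) <- vapply(traces, `[[`, character(1), "embryo_label")
  names(truths) <- names(traces)
  list(traces = traces, truths = truths, genotype = genotype)
}

#' Render a trace as a small synthetic frame stack
#'
#' Builds a grayscale image stack whose mean pixel value inside a rectangular
#' ROI equals the trace value at every frame, with a constant background
#' outside. A static zero-mean spatial pattern is added inside the ROI so the
#' frames are not trivially flat while the ROI mean stays exact. Used to test
#' the acquisition path end-to-end.
#'
#' @param trace a \code{raw_trace}.
#' @param roi an [roi_rect()] lying inside the frame.
#' @param frame_size \code{c(rows, cols)} in pixels.
#' @param seed seed for the static pattern.
#' @param background constant background intensity.
#' @param pattern_sd SD of the static within-ROI pattern.
#' @return an \code{image_stack} (see [image_stack()]).
#' @export
render_frame_stack <- function(trace, roi, frame_size = c(36, 48), seed = 1L,
                               background = 0, pattern_sd = 1) {
  stopifnot(inherits(trace, "raw_trace"), inherits(roi, "roi_rect"),
            all(is.finite(trace$values)))
  if (roi$row0 < 0 || roi$col0 < 0 || roi$row1 > frame_size[1] ||
      roi$col1 > frame_size[2]) {
    stop("ROI must lie fully inside the frame")
  }
  n <- length(trace$values)
  frames <- array(background, dim = c(n, frame_size[1], frame_size[2]))
  rows <- (roi$row0 + 1L):roi$row1
  cols <- (roi$col0 + 1L):roi$col1
  pat <- with_seed(seed,
                   matrix(stats::rnorm(length(rows) * length(cols), 0, pattern_sd),
                          length(rows), length(cols)))
  pat <- pat - mean(pat)  # exact zero mean: ROI mean equals the trace value
  for (f in seq_len(n)) {
    frames[f, rows, cols] <- trace$values[f] + pat
  }
  image_stack(frames, frame_rate = trace$frame_rate,
              record_start = trace$record_start)
}

#' Generate a matched two-channel calcium recording
#'
#' Simulates simultaneous GCaMP-like (calcium-sensitive) and tdTomato-like
#' (calcium-insensitive) traces sharing a strictly positive multiplicative
#' motion artifact, so the channel ratio cancels motion. Calcium events are
#' instantaneous-rise, single-exponential-decay transients.
#'
#' @param event_times event onset times, seconds from recording start.
#' @param event_amplitude peak fractional fluorescence change per event
#'   (ratio units).
#' @param motion_artifact strictly positive series, one value per sample,
#'   applied multiplicatively to both channels.
#' @param cadence seconds per sample (default 1.5, one imaging cycle).
#' @param seed seed for channel noise.
#' @param decay_tau transient decay constant, seconds (default 6).
#' @param baseline_signal,baseline_reporter channel baselines.
#' @param noise_sd additive per-channel noise SD.
#' @param record_start recording start, hAEL.
#' @return list with \code{pair} (a [dual_channel_trace()]) and \code{truth}
#'   (\code{ground_truth} with \code{calcium_event_times} in seconds).
#' @export
generate_calcium_pair <- function(event_times, event_amplitude,
                                  motion_artifact, cadence = 1.5, seed = 1L,
                                  decay_tau = 6,
                                  baseline_signal = 1, baseline_reporter = 1,
                                  noise_sd = 0, record_start = 18.0) {
  stopifnot(cadence > 0, decay_tau > 0, all(is.finite(motion_artifact)))
  if (any(motion_artifact <= 0)) {
    stop("motion_artifact must be strictly positive (the ratio divides by it)")
  }
  n <- length(motion_artifact)
  t_s <- (seq_len(n) - 1L) * cadence
  kernel <- numeric(n)
  for (te in event_times) {
    on <- t_s >= te
    kernel[on] <- kernel[on] + event_amplitude * exp(-(t_s[on] - te) / decay_tau)
  }
  out <- with_seed(seed, {
    nz <- function() if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    list(signal = baseline_signal * motion_artifact * (1 + kernel) + nz(),
         reporter = baseline_reporter * motion_artifact + nz())
  })
  pair <- dual_channel_trace(out$signal, out$reporter, cadence = cadence,
                             record_start = record_start)
  truth <- structure(list(
    bout_intervals = NULL, phase_boundaries = NULL,
    injected_total_activity = NULL,
    calcium_event_times = as.numeric(event_times)
  ), class = "ground_truth")
  list(pair = pair, truth = truth)
}
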