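#' Genotype preset for the synthetic recording generator
#'
#' A preset bundles every parameter that shapes a synthetic embryo
#' mean-grey-value (MGV) recording: the developmental timeline (movement
#' onset, transition to rhythmic activity, tracheal gas-filling, hatching),
#' the myogenic-phase event process, the neurogenic-phase bout structure,
#' baseline drift, and sensor noise. Times are in hours after egg laying
#' (hAEL); intensities are arbitrary linear MGV units.
#'
#' The movement model has two phases. During the myogenic phase
#' (\code{movement_onset} to \code{rhythmic_onset}) disorganised movements are
#' drawn as a Poisson process of short biphasic (zero-mean) pulses with
#' gamma-distributed amplitudes. During the neurogenic phase
#' (\code{rhythmic_onset} to \code{hatch_time}) activity arrives in bouts: a
#' rectangular envelope recurring every \code{bout_period} seconds, lasting
#' \code{bout_duration} seconds, carrying a sinusoidal oscillation at
#' \code{within_bout_freq} Hz with amplitude \code{bout_amplitude}. The
#' baseline adds a linear drift, a smooth sigmoidal step at tracheal
#' gas-filling and a discontinuous step at hatching.
#'
#' @param name preset label.
#' @param movement_onset,rhythmic_onset,hatch_time phase boundaries, hAEL;
#'   must be strictly increasing.
#' @param myogenic_event_rate Poisson rate of myogenic pulses, events/min.
#' @param myogenic_event_mean mean pulse amplitude, MGV units.
#' @param myogenic_event_shape gamma shape of pulse amplitudes
#'   (dispersion control; variance = mean^2/shape).
#' @param bout_period,bout_duration neurogenic bout recurrence and length,
#'   seconds; \code{bout_duration < bout_period} whenever bouts are active.
#' @param bout_amplitude within-bout oscillation amplitude, MGV units;
#'   0 silences the rhythmic phase entirely.
#' @param within_bout_freq within-bout oscillation frequency, Hz.
#' @param bout_jitter_sd SD of Gaussian jitter on bout start times, seconds
#'   (default 0 so spectral recovery is exact).
#' @param noise_sd additive Gaussian sensor noise SD, MGV units.
#' @param drift_slope slow morphological drift, MGV units/hour.
#' @param gasfill_time,gasfill_step,gasfill_rise tracheal gas-filling event:
#'   centre time (hAEL), step height (MGV units), 10--90\% rise time
#'   (seconds; rendered as a logistic step).
#' @param hatch_step MGV discontinuity at hatching.
#' @return an object of class \code{genotype_preset}.
#' @seealso [preset_wild_type()], [preset_silenced()], [preset_mutant()],
#'   [generate_trace()]
#' @export
genotype_preset <- function(name,
                            movement_onset = 16.0,
                            rhythmic_onset = 18.0,
                            hatch_time = 21.0,
                            myogenic_event_rate = 3.0,
                            myogenic_event_mean = 0.3,
                            myogenic_event_shape = 2.0,
                            bout_period = 180,
                            bout_duration = 60,
                            bout_amplitude = 0.5,
                            within_bout_freq = 1.0,
                            bout_jitter_sd = 0,
                            noise_sd = 0.003,
                            drift_slope = 0.2,
                            gasfill_time = 19.5,
                            gasfill_step = 2.0,
                            gasfill_rise = 120,
                            hatch_step = -3.0) {
  stopifnot(
    is.character(name), length(name) == 1L,
    movement_onset < rhythmic_onset, rhythmic_onset < hatch_time,
    myogenic_event_rate >= 0, myogenic_event_mean >= 0,
    myogenic_event_shape > 0,
    bout_period > 0, bout_duration >= 0, bout_amplitude >= 0,
    within_bout_freq > 0, bout_jitter_sd >= 0,
    noise_sd >= 0, gasfill_rise > 0
  )
  if (bout_amplitude > 0 && bout_duration >= bout_period) {
    stop("bout_duration must be smaller than bout_period for rhythmic presets")
  }
  structure(as.list(environment()), class = "genotype_preset")
}

#' Built-in genotype presets
#'
#' Three presets mirror the study conditions the pipeline is designed to
#' discriminate: a wild-type-like control with both movement phases; a
#' neurally silenced preset (as under pan-neuronal Kir expression) in which
#' the myogenic event process is untouched but rhythmic bouts are absent; and
#' a mutant-like preset with movement amplitudes halved, a shorter bout
#' period (higher bout frequency) and shorter bouts.
#'
#' @param ... overrides forwarded to [genotype_preset()].
#' @return a \code{genotype_preset}.
#' @export
preset_wild_type <- function(...) {
  args <- list(...)
  do.call(genotype_preset, c(list(name = args$name %||% "wild_type"),
                             args[names(args) != "name"]))
}

#' @rdname preset_wild_type
#' @export
preset_silenced <- function(...) {
  args <- c(list(name = "silenced", bout_amplitude = 0), list(...))
  do.call(genotype_preset, args[!duplicated(names(args))])
}

#' @rdname preset_wild_type
#' @export
preset_mutant <- function(...) {
  args <- c(list(name = "mutant",
                 myogenic_event_mean = 0.15,
                 bout_amplitude = 0.25,
                 bout_period = 120,
                 bout_duration = 30), list(...))
  do.call(genotype_preset, args[!duplicated(names(args))])
}

#' Cohort specification for the synthetic generator
#'
#' @param presets list of \code{genotype_preset} objects, or a named list of
#'   \code{list(preset, n)} pairs; alternatively supply \code{n_embryos} as a
#'   vector matched to \code{presets}.
#' @param n_embryos embryos per preset (recycled); all \eqn{\ge} 1.
#' @param frame_rate acquisition rate, Hz (default 4, the recording rate of
#'   the original assay).
#' @param record_start recording start, hAEL (default 14, embryos staged just
#'   before movement onset).
#' @param record_duration recording length, hours.
#' @param seed integer master seed; per-embryo seeds are derived from it
#'   deterministically.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(presets, n_embryos = 12, frame_rate = 4,
                        record_start = 14.0, record_duration = 8.0,
                        seed = 1L) {
  if (inherits(presets, "genotype_preset")) presets <- list(presets)
  stopifnot(length(presets) >= 1L,
            all(vapply(presets, inherits, logical(1), "genotype_preset")),
            frame_rate > 0, record_duration > 0)
  n_embryos <- rep_len(as.integer(n_embryos), length(presets))
  if (any(n_embryos < 1L)) stop("n_embryos must be >= 1 for every preset")
  structure(list(presets = presets, n_embryos = n_embryos,
                 frame_rate = frame_rate, record_start = record_start,
                 record_duration = record_duration, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.genotype_preset <- function(x, ...) {
  cat(sprintf(
    "<genotype_preset '%s'> phases %.1f/%.1f/%.1f hAEL; events %.2g/min x %.2g MGV; bouts %gs/%gs x %.2g MGV @ %g Hz; noise %.3g\n",
    x$name, x$movement_onset, x$rhythmic_onset, x$hatch_time,
    x$myogenic_event_rate, x$myogenic_event_mean, x$bout_period,
    x$bout_duration, x$bout_amplitude, x$within_bout_freq, x$noise_sd))
  invisible(x)
}
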