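# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Centred moving average with edge shrinkage: sample i averages indices
# [i - half, i + half] intersected with [1, n], half = window %/% 2.
# Shift-and-add accumulation (in window-index order) rather than prefix
# sums: window sums then round identically to a per-window left-to-right
# loop, so results agree bitwise with a naive reference implementation.
centred_mean <- function(x, window) {
  stopifnot(window >= 1)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  half <- window %/% 2
  acc <- numeric(n)
  cnt <- numeric(n)
  for (off in seq.int(-half, half)) {
    dst <- max(1L, 1L - off):min(n, n - off)
    acc[dst] <- acc[dst] + x[dst + off]
    cnt[dst] <- cnt[dst] + 1
  }
  acc / cnt
}

# half-open index range [start, end) on a trace timebase (hours AEL)
window_indices <- function(times, start, end) {
  which(times >= start & times < end)
}

trace_times <- function(trace) {
  trace$record_start + (seq_along(trace$values) - 1L) / trace$frame_rate / 3600
}

`%||%` <- function(a, b) if (is.null(a)) b else a
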