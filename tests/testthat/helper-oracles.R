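# Independent brute-force oracles, kept deliberately naive so they cannot
# share code paths with the implementation.

# windowed mean: explicit loop, window %/% 2 samples each side, edge shrink
brute_rolling_mean <- function(x, window) {
  n <- length(x)
  half <- window %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- sum(x[lo:hi]) / (hi - lo + 1L)
  }
  out
}

# random values quantised to multiples of 2^-10: window sums are then exactly
# representable in double precision, so a correct windowed mean agrees with
# the oracle bit-for-bit regardless of accumulation order
dyadic_noise <- function(n, scale = 1) round(rnorm(n, 0, scale) * 1024) / 1024

# per-pixel mean over a rectangle, frame by frame
brute_roi_mean <- function(frames, row0, row1, col0, col1) {
  n <- dim(frames)[1]
  out <- numeric(n)
  for (f in seq_len(n)) {
    acc <- 0; cnt <- 0
    for (r in (row0 + 1L):row1) for (cc in (col0 + 1L):col1) {
      acc <- acc + frames[f, r, cc]
      cnt <- cnt + 1L
    }
    out[f] <- acc / cnt
  }
  out
}

# exact two-sided Mann-Whitney p by full enumeration of group labelings
brute_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  idx <- utils::combn(length(pooled), nx)
  mu <- nx * length(y) / 2
  count <- 0L
  for (j in seq_len(ncol(idx))) {
    xs <- pooled[idx[, j]]
    ys <- pooled[-idx[, j]]
    u <- sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    if (abs(u - mu) >= abs(u_obs - mu) - 1e-12) count <- count + 1L
  }
  count / ncol(idx)
}

# enumeration of periodic bout start times (independent of the generator)
brute_bout_starts <- function(phase_start, phase_end, period_s) {
  starts <- c()
  t <- phase_start
  while (t < phase_end) {
    starts <- c(starts, t)
    t <- t + period_s / 3600
  }
  starts
}

# default wild-type-like test cohort scaled for test speed: 4-h recording
# spanning both phases (compressed timeline, same structure)
test_preset <- function(name = "wt", ...) {
  genotype_preset(name = name, movement_onset = 16, rhythmic_onset = 17,
                  hatch_time = 19, gasfill_time = 18, ...)
}

make_movement_trace <- function(values, frame_rate = 4, record_start = 16,
                                threshold = 0.01) {
  structure(list(values = values, frame_rate = frame_rate,
                 record_start = record_start, embryo_label = "t",
                 hatch_time = NA_real_, threshold_applied = threshold,
                 threshold_mode = "per_sample", baseline_window = 60L),
            class = "movement_trace")
}

# Minimal stored (uncompressed) ZIP writer, used to build ImageJ RoiSet
# archives for tests without an external zip binary.
crc32_bytes <- function(bytes) {
  tab <- local({
    t <- integer(256)
    for (i in 0:255) {
      c <- i
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L) != 0L) {
          bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320
        } else bitwShiftR(c, 1L)
      }
      t[i + 1L] <- c
    }
    t
  })
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

le_bytes <- function(value, n) {
  out <- raw(n)
  v <- value
  if (v < 0) v <- v + 2^32
  for (i in seq_len(n)) {
    out[i] <- as.raw(v %% 256)
    v <- v %/% 256
  }
  out
}

write_stored_zip <- function(zip_path, files) {
  con <- file(zip_path, "wb")
  on.exit(close(con))
  offsets <- integer(0)
  central <- raw(0)
  pos <- 0
  for (f in files) {
    data <- readBin(f, "raw", file.size(f))
    name <- charToRaw(basename(f))
    crc <- crc32_bytes(data)
    local_hdr <- c(le_bytes(0x04034b50, 4), le_bytes(20, 2), le_bytes(0, 2),
                   le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2),
                   le_bytes(crc, 4), le_bytes(length(data), 4),
                   le_bytes(length(data), 4), le_bytes(length(name), 2),
                   le_bytes(0, 2), name)
    writeBin(local_hdr, con)
    writeBin(data, con)
    central <- c(central,
                 le_bytes(0x02014b50, 4), le_bytes(20, 2), le_bytes(20, 2),
                 le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2),
                 le_bytes(0, 2), le_bytes(crc, 4),
                 le_bytes(length(data), 4), le_bytes(length(data), 4),
                 le_bytes(length(name), 2), le_bytes(0, 2), le_bytes(0, 2),
                 le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 4),
                 le_bytes(pos, 4), name)
    pos <- pos + length(local_hdr) + length(data)
  }
  writeBin(central, con)
  writeBin(c(le_bytes(0x06054b50, 4), le_bytes(0, 2), le_bytes(0, 2),
             le_bytes(length(files), 2), le_bytes(length(files), 2),
             le_bytes(length(central), 4), le_bytes(pos, 4),
             le_bytes(0, 2)), con)
  invisible(zip_path)
}
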