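#' Configuration of the synthetic cyclic-seizure cohort
#'
#' Describes one simulated long-term EEG recording: cyclically recurring
#' stereotyped nonconvulsive seizures whose rhythmic discharge slows
#' linearly from `f_start` to `f_end`, inter-channel coupling with nonzero
#' time lags (so lagged synchrony is detectable by imaginary coherence), an
#' instantaneous volume-conduction mixing matrix (so zero-lag leakage
#' exists as a confound), 1/f background noise, and a programmable
#' multiplicative boost of the coupling gains in the final seconds of every
#' seizure (terminal hypersynchronization).
#'
#' Defaults mirror the cyclic-seizure cohort the pipeline targets: 256 Hz
#' sampling, seizure durations ~118 +/- 34 s (floored at 21 s so the
#' duration filter never rejects them), a ~5 min inter-onset cycle (12
#' seizures/h, comfortably above the >3/h cyclic-seizure definition), and a
#' 6 Hz to 2 Hz ictal chirp.
#'
#' @param fs Sampling rate (Hz, integer).
#' @param n_seizures Number of seizures.
#' @param cycle_period_s Mean inter-onset interval (s).
#' @param duration_mean_s,duration_sd_s,duration_min_s Truncated-normal
#'   seizure-duration distribution (s).
#' @param f_start,f_end Ictal discharge frequency chirp endpoints (Hz).
#' @param coupled_pairs Data frame with columns `a`, `b` (channel labels),
#'   `lag_ms` (delay of `b`'s copy; must be a whole number of samples at
#'   `fs`) and `gain` (amplitude of `b`'s copy relative to `a`'s).
#' @param terminal_boost Factor multiplying the coupling gains during the
#'   final `terminal_window_s` of each seizure (1 = no terminal effect).
#' @param terminal_window_s Length of the boosted terminal window (s).
#' @param mixing 8 x 8 instantaneous mixing matrix applied sample-wise
#'   (volume conduction); must be invertible. Default: identity plus
#'   `mixing_leak` on all off-diagonals.
#' @param mixing_leak Off-diagonal leakage of the default mixing matrix.
#' @param noise_exponent Spectral slope of the background (power ~
#'   1/f^exponent).
#' @param snr Ictal rhythm RMS amplitude relative to the background RMS.
#' @param freq_jitter_hz SD of the slow random jitter on the instantaneous
#'   discharge frequency (gives the rhythm a realistic ~1 Hz bandwidth).
#' @param amp_mod Depth of the slow random amplitude modulation.
#' @param clustered If `TRUE`, draw inter-onset intervals from a
#'   two-component mixture (clusters of short cycles separated by long
#'   gaps) instead of a single jittered cycle.
#' @param interictal_blocks Number of seizure-free baseline blocks of
#'   `baseline_block_s` seconds interleaved with the seizure runs; each
#'   hosts one inter-ictal marker.
#' @param baseline_block_s Length of each baseline block (s; >= 610 so an
#'   inter-ictal marker at its center is >= 5 min from any seizure).
#' @param amplitude_uv Background RMS in microvolts.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @param m Montage.
#' @return Validated object of class `sim_config`.
#' @export
sim_config <- function(n_seizures = 60,
                       fs = 256,
                       cycle_period_s = 300,
                       duration_mean_s = 118,
                       duration_sd_s = 34,
                       duration_min_s = 21,
                       f_start = 6, f_end = 2,
                       coupled_pairs = data.frame(a = "C3", b = "C4",
                                                  lag_ms = 62.5, gain = 0.15),
                       terminal_boost = 1,
                       terminal_window_s = 10,
                       mixing = NULL,
                       mixing_leak = 0.05,
                       noise_exponent = 1,
                       snr = 1,
                       freq_jitter_hz = 0.8,
                       amp_mod = 0.3,
                       clustered = FALSE,
                       interictal_blocks = 3,
                       baseline_block_s = 620,
                       amplitude_uv = 20,
                       seed = 1,
                       m = montage()) {
  if (fs != round(fs) || fs <= 0) stop("fs must be a positive integer", call. = FALSE)
  if (n_seizures < 1) stop("n_seizures must be >= 1", call. = FALSE)
  if (duration_min_s <= 2 * terminal_window_s)
    stop("duration_min_s must exceed twice the terminal window so onset and ",
         "termination windows never overlap", call. = FALSE)
  if (cycle_period_s <= duration_mean_s + 2 * duration_sd_s)
    stop("cycle_period_s must exceed duration_mean_s + 2*duration_sd_s",
         call. = FALSE)
  if (baseline_block_s < 610)
    stop("baseline_block_s must be >= 610 s to host a valid inter-ictal marker",
         call. = FALSE)
  if (interictal_blocks < 2) stop("need >= 2 inter-ictal blocks", call. = FALSE)
  cp <- as.data.frame(coupled_pairs)
  if (nrow(cp)) {
    if (!all(c("a", "b", "lag_ms", "gain") %in% names(cp)))
      stop("coupled_pairs needs columns a, b, lag_ms, gain", call. = FALSE)
    bad <- setdiff(c(cp$a, cp$b), m$labels)
    if (length(bad)) stop("coupled_pairs uses unknown channels: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    lag_samp <- cp$lag_ms * fs / 1000
    if (any(abs(lag_samp - round(lag_samp)) > 1e-9))
      stop("every lag_ms must be a whole number of samples at fs = ", fs,
           call. = FALSE)
  }
  if (is.null(mixing)) {
    mixing <- matrix(mixing_leak, 8, 8)
    diag(mixing) <- 1
  }
  mixing <- as.matrix(mixing)
  if (!all(dim(mixing) == c(8, 8)) || abs(det(mixing)) < 1e-8)
    stop("mixing must be an invertible 8 x 8 matrix", call. = FALSE)
  if (terminal_boost <= 0) stop("terminal_boost must be positive", call. = FALSE)
  structure(list(fs = as.integer(fs), n_seizures = as.integer(n_seizures),
                 cycle_period_s = cycle_period_s,
                 duration_mean_s = duration_mean_s, duration_sd_s = duration_sd_s,
                 duration_min_s = duration_min_s,
                 f_start = f_start, f_end = f_end, coupled_pairs = cp,
                 terminal_boost = terminal_boost,
                 terminal_window_s = terminal_window_s,
                 mixing = mixing, noise_exponent = noise_exponent, snr = snr,
                 freq_jitter_hz = freq_jitter_hz, amp_mod = amp_mod,
                 clustered = clustered,
                 interictal_blocks = as.integer(interictal_blocks),
                 baseline_block_s = baseline_block_s,
                 amplitude_uv = amplitude_uv,
                 seed = as.integer(seed), montage = m),
            class = "sim_config")
}

# Low-pass-smoothed unit-variance Gaussian noise (moving average over
# roughly win_s seconds), for slow frequency jitter / amplitude modulation.
slow_noise <- function(n, fs, win_s = 1) {
  w <- max(1L, as.integer(round(win_s * fs)))
  z <- stats::rnorm(n + w)
  sm <- stats::filter(z, rep(1 / w, w), sides = 1L)[(w + 1L):(w + n)]
  as.numeric(sm) / sqrt(1 / w)
}

# 1/f^a background noise, unit RMS, via FFT amplitude shaping. The FFT runs
# at the next highly composite length and the series is truncated to n.
spectral_noise <- function(n, fs, exponent) {
  m <- stats::nextn(n, c(2L, 3L, 5L))
  z <- stats::rnorm(m)
  Z <- stats::fft(z)
  f <- c(0, seq_len(m - 1)) * fs / m
  f <- pmin(f, fs - f)             # two-sided frequency magnitudes
  shape <- ifelse(f < fs / m, 0, f^(-exponent / 2))
  x <- Re(stats::fft(Z * shape, inverse = TRUE))[seq_len(n)] / m
  x / sqrt(mean(x^2))
}

# One stereotyped ictal discharge: linear chirp with slow frequency jitter
# and amplitude modulation, raised-cosine on/off ramps.
ictal_source <- function(n_samp, fs, f_start, f_end, freq_jitter_hz, amp_mod,
                         ramp_s = 2) {
  t_frac <- seq(0, 1, length.out = n_samp)
  f_inst <- f_start + (f_end - f_start) * t_frac
  if (freq_jitter_hz > 0)
    f_inst <- pmax(0.5, f_inst + freq_jitter_hz * slow_noise(n_samp, fs, 1))
  phase <- 2 * pi * cumsum(f_inst) / fs
  env <- rep(1, n_samp)
  if (amp_mod > 0)
    env <- pmax(0.2, 1 + amp_mod * slow_noise(n_samp, fs, 2))
  nr <- min(as.integer(ramp_s * fs), n_samp %/% 2L)
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    env[1:nr] <- env[1:nr] * ramp
    env[(n_samp - nr + 1L):n_samp] <- env[(n_samp - nr + 1L):n_samp] * rev(ramp)
  }
  sqrt(2) * env * cos(phase)
}

draw_durations <- function(cfg, n) {
  out <- numeric(n)
  for (k in seq_len(n)) {
    d <- stats::rnorm(1, cfg$duration_mean_s, cfg$duration_sd_s)
    while (d < cfg$duration_min_s)
      d <- stats::rnorm(1, cfg$duration_mean_s, cfg$duration_sd_s)
    out[k] <- d
  }
  out
}

draw_intervals <- function(cfg, n, durations) {
  # inter-onset intervals for seizures 2..n of a run
  if (n <= 1L) return(numeric(0))
  ioi <- if (cfg$clustered) {
    short <- stats::rnorm(n - 1L, 0.6 * cfg$cycle_period_s, 0.05 * cfg$cycle_period_s)
    long <- stats::rnorm(n - 1L, 1.9 * cfg$cycle_period_s, 0.15 * cfg$cycle_period_s)
    ifelse(stats::runif(n - 1L) < 0.7, short, long)
  } else {
    stats::rnorm(n - 1L, cfg$cycle_period_s, 0.05 * cfg$cycle_period_s)
  }
  pmax(ioi, durations[-n] + 25)    # keep >= 25 s between termination and next onset
}

#' Simulate a cyclic-seizure EEG cohort recording
#'
#' Builds the full multichannel recording described by a [sim_config()]:
#' per-channel independent 1/f background, one common jittered-chirp source
#' per seizure injected into both members of every coupled pair (the second
#' member delayed by `lag_ms` and scaled by `gain`, with `gain *
#' terminal_boost` during the final `terminal_window_s`), the whole
#' 8-channel frame multiplied sample-wise by the volume-conduction mixing
#' matrix. Seizure runs are interleaved with seizure-free baseline blocks,
#' each carrying one inter-ictal marker at its center.
#'
#' @param config A [sim_config()].
#' @return List with `recording` (an [eeg_recording()]) and `truth`
#'   (class `sim_ground_truth`: `markers`, `coupled_pairs`,
#'   `terminal_boost`, `boosted_phase`, `seed`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  local_seed(cfg$seed, {
    # --- timeline ---------------------------------------------------------
    runs <- cfg$interictal_blocks - 1L
    per_run <- diff(round(seq(0, cfg$n_seizures, length.out = runs + 1L)))
    onsets <- terminations <- numeric(0)
    interictal <- numeric(0)
    t_cursor <- 0
    for (r in seq_len(runs)) {
      interictal <- c(interictal, t_cursor + cfg$baseline_block_s / 2)
      t_cursor <- t_cursor + cfg$baseline_block_s
      nr <- per_run[r]
      if (nr > 0L) {
        dur <- draw_durations(cfg, nr)
        ioi <- draw_intervals(cfg, nr, dur)
        on <- t_cursor + 30 + c(0, cumsum(ioi))
        onsets <- c(onsets, on)
        terminations <- c(terminations, on + dur)
        t_cursor <- on[nr] + dur[nr] + 30
      }
    }
    interictal <- c(interictal, t_cursor + cfg$baseline_block_s / 2)
    t_cursor <- t_cursor + cfg$baseline_block_s
    total_s <- ceiling(t_cursor)
    n <- total_s * cfg$fs
    nc <- length(cfg$montage$labels)

    # --- background -------------------------------------------------------
    sig <- matrix(0, n, nc)
    for (k in seq_len(nc)) sig[, k] <- spectral_noise(n, cfg$fs, cfg$noise_exponent)

    # --- ictal discharges -------------------------------------------------
    cp <- cfg$coupled_pairs
    for (s in seq_along(onsets)) {
      i0 <- as.integer(floor(onsets[s] * cfg$fs)) + 1L
      i1 <- as.integer(floor(terminations[s] * cfg$fs))
      ns <- i1 - i0 + 1L
      src <- cfg$snr * ictal_source(ns, cfg$fs, cfg$f_start, cfg$f_end,
                                    cfg$freq_jitter_hz, cfg$amp_mod)
      if (nrow(cp) == 0L) next
      # terminal boost applies to samples inside the final window
      tb_start <- i1 - as.integer(cfg$terminal_window_s * cfg$fs) + 1L
      for (p in seq_len(nrow(cp))) {
        ia <- match(cp$a[p], cfg$montage$labels)
        ib <- match(cp$b[p], cfg$montage$labels)
        lag <- as.integer(round(cp$lag_ms[p] * cfg$fs / 1000))
        sig[i0:i1, ia] <- sig[i0:i1, ia] + src
        gains <- rep(cp$gain[p], ns)
        gains[(i0:i1) >= tb_start] <- cp$gain[p] * cfg$terminal_boost
        jrows <- (i0 + lag):(i1 + lag)
        keep <- jrows <= n
        sig[jrows[keep], ib] <- sig[jrows[keep], ib] + (gains * src)[keep]
      }
    }

    # --- volume conduction and physical scale -----------------------------
    sig <- sig %*% t(cfg$mixing) * cfg$amplitude_uv
    colnames(sig) <- cfg$montage$labels

    rec <- eeg_recording(sig, cfg$fs, cfg$montage)
    mk <- marker_set(data.frame(onset_s = onsets, termination_s = terminations),
                     interictal = interictal)
    truth <- structure(list(markers = mk, coupled_pairs = cp,
                            terminal_boost = cfg$terminal_boost,
                            boosted_phase = "termination", seed = cfg$seed),
                       class = "sim_ground_truth")
    list(recording = rec, truth = truth)
  })
}

#' Write a simulated cohort to disk
#'
#' Emits `cohort.edf` (signals), `markers.csv` (annotations, the
#' [read_markers()] format) and `ground_truth.json` (coupled pairs,
#' terminal boost, seed) into `dir`; [read_recording()] and
#' [read_markers()] round-trip them.
#'
#' @param recording An `eeg_recording`.
#' @param truth A `sim_ground_truth`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(recording, truth, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  if (file.access(dir, 2L) != 0L)
    stop("output directory not writable: ", dir, call. = FALSE)
  paths <- c(edf = file.path(dir, "cohort.edf"),
             markers = file.path(dir, "markers.csv"),
             truth = file.path(dir, "ground_truth.json"))
  write_edf(recording, paths[["edf"]])
  write_markers(truth$markers, paths[["markers"]])
  jsonlite::write_json(
    list(coupled_pairs = truth$coupled_pairs,
         terminal_boost = truth$terminal_boost,
         boosted_phase = truth$boosted_phase, seed = truth$seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read back a cohort ground-truth file
#' @param path Path to a `ground_truth.json` written by [write_cohort()].
#' @return A list with `coupled_pairs` (data frame), `terminal_boost`,
#'   `boosted_phase` and `seed`.
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("ground-truth file not found: ", path, call. = FALSE)
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  g$coupled_pairs <- as.data.frame(g$coupled_pairs)
  g
}
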