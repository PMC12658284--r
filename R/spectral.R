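#' Spectral estimation parameters
#'
#' Settings of the Welch estimator used for spectrograms, cross-spectra and
#' coherency: segment length in seconds, fractional overlap, taper and
#' per-segment detrending. The defaults (2-s Hann segments, 50% overlap,
#' mean removal) give 0.5 Hz resolution and nine segments per 10-s window,
#' enough averaging for coherency to be informative while still resolving
#' the 1 Hz band edge.
#'
#' @param segment_s Segment length (s). Frequency resolution is
#'   `1/segment_s`.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @param taper Taper name; only `"hann"` and `"rectangular"` are provided.
#' @param detrend `"constant"` (remove each segment's mean) or `"none"`.
#' @return Object of class `spectral_params`.
#' @export
spectral_params <- function(segment_s = 2, overlap = 0.5,
                            taper = c("hann", "rectangular"),
                            detrend = c("constant", "none")) {
  taper <- match.arg(taper)
  detrend <- match.arg(detrend)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)", call. = FALSE)
  if (segment_s <= 0) stop("segment_s must be positive", call. = FALSE)
  structure(list(segment_s = segment_s, overlap = overlap, taper = taper,
                 detrend = detrend),
            class = "spectral_params")
}

#' Frequency-band scheme for the low-frequency synchrony index
#'
#' Delta is the half-open interval [1, 4) Hz, theta the closed [4, 8] Hz
#' (the 4 Hz bin is counted once, in theta), and the low-frequency value is
#' the arithmetic mean of the delta-band and theta-band values.
#'
#' @return Object of class `band_scheme` with `delta`, `theta` interval
#'   endpoints and closure conventions.
#' @export
band_scheme <- function() {
  structure(list(delta = c(1, 4), delta_right_closed = FALSE,
                 theta = c(4, 8), theta_right_closed = TRUE),
            class = "band_scheme")
}

taper_window <- function(L, taper) {
  switch(taper,
         hann = 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L)),
         rectangular = rep(1, L))
}

# Segment starts (1-based) for Welch segmentation.
welch_starts <- function(n, L, overlap) {
  step <- max(1L, L - as.integer(floor(overlap * L)))
  if (n < L) stop("signal shorter than one segment (", n, " < ", L, " samples)",
                  call. = FALSE)
  seq.int(1L, n - L + 1L, by = step)
}

# Tapered, detrended segment FFTs for a samples x channels matrix.
# Returns freqs (one-sided), an nfreq x nseg x nchan complex array, and the
# one-sided PSD scale factors.
welch_fft <- function(xmat, fs, params) {
  xmat <- as.matrix(xmat)
  L <- as.integer(round(params$segment_s * fs))
  starts <- welch_starts(nrow(xmat), L, params$overlap)
  w <- taper_window(L, params$taper)
  nf <- L %/% 2L + 1L
  freqs <- (0:(nf - 1L)) * fs / L
  F <- array(0i, c(nf, length(starts), ncol(xmat)))
  for (s in seq_along(starts)) {
    seg <- xmat[starts[s]:(starts[s] + L - 1L), , drop = FALSE]
    if (params$detrend == "constant")
      seg <- sweep(seg, 2L, colMeans(seg), "-")
    seg <- seg * w
    F[, s, ] <- stats::mvfft(seg)[1:nf, , drop = FALSE]
  }
  scale <- rep(2 / (fs * sum(w^2)), nf)
  scale[1L] <- scale[1L] / 2
  if (L %% 2L == 0L) scale[nf] <- scale[nf] / 2
  list(freqs = freqs, F = F, scale = scale, n_segments = length(starts))
}

#' Short-time Fourier spectrogram
#'
#' One-sided power spectrogram over sliding tapered segments; used to
#' visualize the cyclic recurrence of seizures and the ictal rhythm's
#' slowing from ~6 Hz towards ~2 Hz.
#'
#' @param x Single-channel signal.
#' @param fs Sampling rate (Hz).
#' @param params A [spectral_params()].
#' @return List with `times` (segment centers, s), `freqs` (Hz) and
#'   `power` (nfreq x ntime, >= 0).
#' @export
stft_spectrogram <- function(x, fs, params = spectral_params()) {
  W <- welch_fft(matrix(as.numeric(x), ncol = 1L), fs, params)
  L <- as.integer(round(params$segment_s * fs))
  starts <- welch_starts(length(x), L, params$overlap)
  power <- W$scale * abs(W$F[, , 1L, drop = FALSE])[, , 1L, drop = FALSE]^2
  dim(power) <- dim(W$F)[1:2]
  list(times = (starts - 1L + L / 2) / fs, freqs = W$freqs, power = power)
}

#' Welch auto- and cross-spectra of two signals
#'
#' Segment-averaged one-sided spectral densities. At least two Welch
#' segments are required: with a single segment the magnitude of coherency
#' is identically 1 and carries no information.
#'
#' @param x,y Equal-length signals.
#' @param fs Sampling rate (Hz).
#' @param params A [spectral_params()].
#' @return List with `freqs`, real `sxx`, `syy` and complex `sxy`
#'   (convention `S_xy(f) = <conj(X(f)) Y(f)>`, so a delay of `d` samples in
#'   `y` shows up as phase `-2*pi*f*d/fs`), and `n_segments`.
#' @export
cross_spectra <- function(x, y, fs, params = spectral_params()) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  W <- welch_fft(cbind(as.numeric(x), as.numeric(y)), fs, params)
  if (W$n_segments < 2L)
    stop("need at least 2 Welch segments (got ", W$n_segments,
         "); shorten segment_s or lengthen the window", call. = FALSE)
  X <- W$F[, , 1L]; Y <- W$F[, , 2L]
  list(freqs = W$freqs,
       sxx = W$scale * rowMeans(abs(X)^2),
       syy = W$scale * rowMeans(abs(Y)^2),
       sxy = W$scale * rowMeans(Conj(X) * Y),
       n_segments = W$n_segments)
}

#' Complex coherency from cross-spectra
#'
#' `C_xy(f) = S_xy(f) / sqrt(S_xx(f) S_yy(f))`; bins where either
#' auto-spectrum vanishes are undefined and dropped.
#'
#' @param cs Output of [cross_spectra()].
#' @return Object of class `coherency_spectrum`: list with `freqs` and
#'   complex `values`, `|values| <= 1` up to numerical tolerance.
#' @export
coherency <- function(cs) {
  ok <- cs$sxx > 0 & cs$syy > 0
  structure(list(freqs = cs$freqs[ok],
                 values = cs$sxy[ok] / sqrt(cs$sxx[ok] * cs$syy[ok])),
            class = "coherency_spectrum")
}

band_mask <- function(freqs, band, right_closed) {
  if (right_closed) freqs >= band[1L] & freqs <= band[2L]
  else freqs >= band[1L] & freqs < band[2L]
}

#' Band-averaged imaginary coherence
#'
#' The imaginary coherence of a band is the mean over in-band frequency
#' bins of the absolute imaginary part of coherency. Discarding the real
#' part removes instantaneous (zero-lag) interactions, the volume-conduction
#' confound of scalp EEG; taking the absolute value keeps the index on the
#' 0 (no lagged correlation) to 1 (perfect lagged synchrony) scale.
#'
#' @param coh A `coherency_spectrum`.
#' @param band Numeric interval `c(lo, hi)` in Hz.
#' @param right_closed Whether `hi` itself is included (default `TRUE`).
#' @return Scalar in `[0, 1]`.
#' @export
band_icoh <- function(coh, band, right_closed = TRUE) {
  stopifnot(inherits(coh, "coherency_spectrum"))
  m <- band_mask(coh$freqs, band, right_closed)
  if (!any(m))
    stop(sprintf("no frequency bins inside [%g, %g%s at the available resolution",
                 band[1L], band[2L], if (right_closed) "]" else ")"),
         call. = FALSE)
  mean(abs(Im(coh$values[m])))
}

#' Low-frequency imaginary coherence of two signals
#'
#' The low-frequency (1-8 Hz) synchrony index: the mean of the delta-band
#' and theta-band imaginary coherences.
#'
#' @inheritParams cross_spectra
#' @param scheme A [band_scheme()].
#' @return Scalar in `[0, 1]`.
#' @export
lf_icoh <- function(x, y, fs, params = spectral_params(), scheme = band_scheme()) {
  coh <- coherency(cross_spectra(x, y, fs, params))
  lf_from_coherency(coh, scheme)
}

lf_from_coherency <- function(coh, scheme = band_scheme()) {
  (band_icoh(coh, scheme$delta, scheme$delta_right_closed) +
     band_icoh(coh, scheme$theta, scheme$theta_right_closed)) / 2
}

# All-pairs LF iCOH for a samples x channels window: one FFT pass per
# channel, then pairwise cross products. Equals lf_icoh() pair by pair.
lf_icoh_all_pairs <- function(xmat, fs, params = spectral_params(),
                              scheme = band_scheme()) {
  W <- welch_fft(xmat, fs, params)
  if (W$n_segments < 2L)
    stop("need at least 2 Welch segments (got ", W$n_segments, ")", call. = FALSE)
  nc <- ncol(xmat)
  auto <- sapply(seq_len(nc), function(k) W$scale * rowMeans(abs(W$F[, , k])^2))
  md <- band_mask(W$freqs, scheme$delta, scheme$delta_right_closed)
  mt <- band_mask(W$freqs, scheme$theta, scheme$theta_right_closed)
  out <- matrix(0, nc, nc, dimnames = list(colnames(xmat), colnames(xmat)))
  for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc) {
    sxy <- W$scale * rowMeans(Conj(W$F[, , i]) * W$F[, , j])
    ok <- auto[, i] > 0 & auto[, j] > 0
    co <- sxy[ok] / sqrt(auto[ok, i] * auto[ok, j])
    aim <- abs(Im(co))
    v <- (mean(aim[md[ok]]) + mean(aim[mt[ok]])) / 2
    out[i, j] <- out[j, i] <- v
  }
  out
}

#' Monte-Carlo null quantile of the low-frequency imaginary coherence
#'
#' Finite Welch averaging biases the imaginary coherence of independent
#' signals away from zero; this estimates the null distribution of
#' [lf_icoh()] for independent Gaussian noise pairs and returns its
#' quantile(s), to calibrate "no correlation" thresholds.
#'
#' @param q Probability (vectorized).
#' @param window_s Analysis-window length (s).
#' @param fs Sampling rate (Hz).
#' @param params A [spectral_params()].
#' @param n_reps Monte-Carlo replicates (warns below 100).
#' @param seed Integer seed; the global RNG state is restored afterwards.
#' @return Quantile(s) of the null LF-iCOH distribution.
#' @export
icoh_null_quantile <- function(q, window_s = 10, fs = 256,
                               params = spectral_params(), n_reps = 1000,
                               seed = 1) {
  if (any(q <= 0 | q >= 1)) stop("q must be in (0, 1)", call. = FALSE)
  if (n_reps < 100) warning("n_reps < 100: null quantile will be unstable", call. = FALSE)
  n <- as.integer(round(window_s * fs))
  vals <- local_seed(seed, {
    vapply(seq_len(n_reps), function(i)
      lf_icoh(stats::rnorm(n), stats::rnorm(n), fs, params), numeric(1))
  })
  stats::quantile(vals, q, names = FALSE)
}
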