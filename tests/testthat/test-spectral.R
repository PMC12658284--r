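test_that("spectrogram localizes tones and tracks a slowing chirp", {
  fs <- 64
  t <- (0:(fs * 60 - 1)) / fs
  sp <- stft_spectrogram(cos(2 * pi * 4 * t), fs)
  peak <- sp$freqs[apply(sp$power, 2L, which.max)]
  expect_true(all(peak == 4))
  expect_true(all(sp$power >= 0))
  # the time-averaged spectrogram IS the Welch auto-spectrum
  cs <- cross_spectra(cos(2 * pi * 4 * t), cos(2 * pi * 4 * t), fs)
  expect_equal(rowMeans(sp$power), cs$sxx, tolerance = 1e-12)

  expect_true(all(stft_spectrogram(rep(0, fs * 10), fs)$power == 0))

  # 6 -> 2 Hz chirp over 100 s: the spectral ridge never moves up
  f_inst <- 6 + (2 - 6) * seq(0, 1, length.out = fs * 100)
  chirp <- cos(2 * pi * cumsum(f_inst) / fs)
  sp2 <- stft_spectrogram(chirp, fs, spectral_params(segment_s = 4))
  ridge <- sp2$freqs[apply(sp2$power, 2L, which.max)]
  expect_true(all(diff(ridge) <= 0.25 + 1e-12))  # monotone up to one bin
  expect_lt(ridge[length(ridge)], ridge[1L])

  expect_error(stft_spectrogram(rnorm(10), fs), "shorter than one segment")
})

test_that("cross-spectra: self-coherence is 1, delays show as linear phase", {
  fs <- 64
  set.seed(21)
  x <- rnorm(fs * 10)
  cs <- cross_spectra(x, x, fs)
  expect_equal(cs$sxy, complex(real = cs$sxx), tolerance = 1e-12)
  co <- coherency(cs)
  expect_true(all(abs(abs(co$values) - 1) < 1e-9))

  t <- (0:(fs * 10 - 1)) / fs
  tone <- cos(2 * pi * 4 * t)
  d <- 4L
  y <- c(rep(0, d), tone)[seq_along(tone)]
  cs2 <- cross_spectra(tone, y, fs)
  i4 <- which(cs2$freqs == 4)
  expect_equal(Arg(cs2$sxy[i4]), -2 * pi * 4 * d / fs, tolerance = 1e-3)

  expect_error(cross_spectra(rnorm(fs * 2), rnorm(fs * 2), fs),
               "at least 2 Welch segments")
  expect_error(cross_spectra(rnorm(10), rnorm(11), fs), "equal length")
})

test_that("production Welch/coherency matches the explicit segment-loop DFT oracle", {
  fs <- 64
  set.seed(22)
  x <- rnorm(fs * 10)
  y <- 0.5 * x + rnorm(fs * 10)
  cs <- cross_spectra(x, y, fs)
  or <- oracle_cross_spectra(x, y, fs)
  expect_equal(cs$freqs, or$freqs, tolerance = 1e-12)
  expect_lt(max(abs(cs$sxx - or$sxx)), 1e-10)
  expect_lt(max(abs(cs$syy - or$syy)), 1e-10)
  expect_lt(max(Mod(cs$sxy - or$sxy)), 1e-10)
  expect_lt(abs(lf_icoh(x, y, fs) - oracle_lf_icoh(x, y, fs)), 1e-10)
})

test_that("band iCOH arithmetic: real -> 0, imaginary -> 1, mean of |Im|", {
  fake <- function(f, v) structure(list(freqs = f, values = v),
                                   class = "coherency_spectrum")
  f <- c(1, 2, 3, 5, 7)
  expect_equal(band_icoh(fake(f, rep(1 + 0i, 5)), c(1, 8)), 0)
  expect_equal(band_icoh(fake(f, rep(1i, 5)), c(1, 8)), 1)
  expect_equal(band_icoh(fake(c(2, 3, 5), c(0.2i, -0.4i, 0.6i)), c(1, 8)), 0.4)
  # the 4 Hz bin belongs to theta, not delta
  g <- fake(c(3.5, 4), c(0.2i, 0.8i))
  expect_equal(band_icoh(g, c(1, 4), right_closed = FALSE), 0.2)
  expect_equal(band_icoh(g, c(4, 8)), 0.8)
  expect_error(band_icoh(fake(c(2, 3), c(0i, 0i)), c(10, 12)), "no frequency bins")
})

test_that("LF iCOH is the delta/theta mean and behaves under scaling and symmetry", {
  fs <- 64
  set.seed(23)
  x <- rnorm(fs * 10); y <- rnorm(fs * 10)
  co <- coherency(cross_spectra(x, y, fs))
  sc <- band_scheme()
  expect_equal(lf_icoh(x, y, fs),
               (band_icoh(co, sc$delta, FALSE) + band_icoh(co, sc$theta, TRUE)) / 2)
  expect_equal(lf_icoh(3 * x, -0.2 * y, fs), lf_icoh(x, y, fs), tolerance = 1e-12)
  expect_equal(lf_icoh(y, x, fs), lf_icoh(x, y, fs), tolerance = 1e-12)
  expect_gte(lf_icoh(x, y, fs), 0)
  expect_lte(lf_icoh(x, y, fs), 1)
})

test_that("zero-lag common sources are rejected; quadrature-lagged copies score ~1", {
  fs <- 64
  n <- fs * 10
  s <- make_band_noise(n, fs, 1, 8, seed = 24)
  q99 <- icoh_null_quantile(0.99, 10, fs, n_reps = 400, seed = 25)
  # noiseless instantaneous mixing: coherency is purely real
  expect_lt(lf_icoh(s, 0.7 * s, fs), q99)
  # with independent sensor noise: still at or below the independent null
  set.seed(26)
  expect_lt(lf_icoh(s + 0.5 * rnorm(n), 0.7 * s + 0.5 * rnorm(n), fs), q99)
  # quarter-period (quadrature) lagged copy: near-perfect lagged synchrony
  expect_gt(lf_icoh(s, quadrature_shift(s, fs), fs), 0.9)
})

test_that("the null quantile is seeded, monotone in q, and shrinks with averaging", {
  a <- icoh_null_quantile(c(0.25, 0.5, 0.95), 10, 64, n_reps = 200, seed = 31)
  b <- icoh_null_quantile(c(0.25, 0.5, 0.95), 10, 64, n_reps = 200, seed = 31)
  expect_identical(a, b)
  expect_true(all(diff(a) > 0))
  # longer windows -> more Welch segments -> smaller finite-sample bias
  m10 <- icoh_null_quantile(0.5, 10, 64, n_reps = 200, seed = 32)
  m60 <- icoh_null_quantile(0.5, 60, 64, n_reps = 200, seed = 32)
  expect_lt(m60, m10)
  expect_warning(icoh_null_quantile(0.5, 10, 64, n_reps = 50, seed = 1),
                 "unstable")
  expect_error(icoh_null_quantile(1.5, 10, 64), "in \\(0, 1\\)")
})
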