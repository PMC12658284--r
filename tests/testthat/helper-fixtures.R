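# Shared fixtures and independent oracles for the test suite.

# Band-limited Gaussian noise via FFT masking (two-sided mask keeps the
# series real).
make_band_noise <- function(n, fs, lo = 1, hi = 8, seed = 1) {
  set.seed(seed)
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  f <- c(0, seq_len(n - 1)) * fs / n
  keep <- (f >= lo & f <= hi) | (f >= fs - hi & f <= fs - lo)
  x <- Re(stats::fft(Z * keep, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# Quadrature copy: every positive frequency shifted by a quarter period
# (90 degrees), i.e. the Hilbert transform.
quadrature_shift <- function(x, fs) {
  n <- length(x)
  f <- c(0, seq_len(n - 1)) * fs / n
  H <- rep(0i, n)
  H[f > 0 & f < fs / 2] <- -1i
  H[f > fs / 2] <- 1i
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
}

# --- Welch oracle: explicit segment loop and explicit DFT ----------------
# Independent of the production path: the DFT is a literal O(N^2) sum.
naive_dft <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  as.vector(W %*% x)
}

oracle_cross_spectra <- function(x, y, fs, segment_s = 2, overlap = 0.5) {
  L <- as.integer(round(segment_s * fs))
  step <- L - as.integer(floor(overlap * L))
  starts <- seq.int(1L, length(x) - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))
  nf <- L %/% 2L + 1L
  sxx <- syy <- numeric(nf)
  sxy <- complex(nf)
  for (s in starts) {
    xs <- x[s:(s + L - 1L)]; ys <- y[s:(s + L - 1L)]
    xs <- (xs - mean(xs)) * w; ys <- (ys - mean(ys)) * w
    X <- naive_dft(xs)[1:nf]; Y <- naive_dft(ys)[1:nf]
    sxx <- sxx + abs(X)^2; syy <- syy + abs(Y)^2
    sxy <- sxy + Conj(X) * Y
  }
  scale <- rep(2 / (fs * sum(w^2)), nf) / length(starts)
  scale[1L] <- scale[1L] / 2
  if (L %% 2L == 0L) scale[nf] <- scale[nf] / 2
  list(freqs = (0:(nf - 1L)) * fs / L, sxx = scale * sxx, syy = scale * syy,
       sxy = scale * sxy)
}

oracle_lf_icoh <- function(x, y, fs, segment_s = 2, overlap = 0.5) {
  cs <- oracle_cross_spectra(x, y, fs, segment_s, overlap)
  co <- cs$sxy / sqrt(cs$sxx * cs$syy)
  f <- cs$freqs
  dd <- f >= 1 & f < 4
  tt <- f >= 4 & f <= 8
  (mean(abs(Im(co[dd]))) + mean(abs(Im(co[tt])))) / 2
}

# --- 12-row balanced fixture for the Type II Wald oracle -----------------
# 2 locations x 2 phases x 3 seizures, fixed printed response values.
wald_fixture <- function() {
  d <- expand.grid(phase = factor(c("onset", "termination")),
                   location = factor(c("A", "B")),
                   seizure = factor(1:3))
  d$y <- c(5.738242, 6.469664, 6.016546, 7.60184, 4.745723, 6.179648,
           5.255307, 6.765582, 5.831245, 5.528593, 5.561615, 6.705255)
  d
}

# Brute-force Type II Wald chi-squares by generalized least squares at the
# model's estimated covariance: highest-order term from the full-model
# coefficient block, main effects from the GLS refit without the terms
# containing them.
oracle_type2_wald <- function(fit, data) {
  X <- lme4::getME(fit, "X")
  Z <- as.matrix(lme4::getME(fit, "Z"))
  y <- stats::model.response(stats::model.frame(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  V <- Z %*% t(Z) * vc$vcov[1L] + diag(length(y)) * vc$vcov[2L]
  Vi <- solve(V)
  gls <- function(Xs) {
    C <- solve(t(Xs) %*% Vi %*% Xs)
    list(b = as.vector(C %*% t(Xs) %*% Vi %*% y), C = C)
  }
  asn <- attr(X, "assign")
  full <- gls(X)
  chi <- function(res, idx)
    as.numeric(t(res$b[idx]) %*% solve(res$C[idx, idx]) %*% res$b[idx])
  sub <- gls(X[, asn != 3L, drop = FALSE])
  asn_sub <- asn[asn != 3L]
  c(phase = chi(sub, which(asn_sub == 1L)),
    location = chi(sub, which(asn_sub == 2L)),
    `phase:location` = chi(full, which(asn == 3L)))
}

# Synthetic synchrony table built directly (no signals): known effects for
# inference-level tests.
make_table <- function(n_seizures = 8, effect = 0, effect_location = "C3",
                       sd = 0.3, seed = 1, level_values = TRUE,
                       patient_id = "p01") {
  set.seed(seed)
  locs_e <- montage()$labels
  locs_r <- names(default_region_map())
  rows <- list()
  for (s in seq_len(n_seizures)) {
    u <- rnorm(1, 0, 0.2)                      # seizure intercept
    for (ph in ictal_phases()) {
      ve <- u + rnorm(length(locs_e), 0, sd)
      if (ph == "termination")
        ve[locs_e == effect_location] <- ve[locs_e == effect_location] + effect
      vr <- u + rnorm(length(locs_r), 0, sd)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patient_id, seizure_index = s, phase = ph,
        level = c(rep("electrode", 8L), rep("region", 5L)),
        location = c(locs_e, locs_r), value = c(ve, vr))
    }
  }
  out <- do.call(rbind, rows)
  out$phase <- factor(out$phase, levels = ictal_phases())
  out
}

# Tiny simulated cohorts used across tests (cheap: few short seizures).
tiny_effect_config <- function(seed = 7, n_seizures = 5, boost = 1, ...) {
  cohort_effect_config(n_seizures = n_seizures, terminal_boost = boost,
                       seed = seed, ...)
}
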