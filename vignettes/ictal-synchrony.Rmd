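---
title: "Quantifying ictal-phase EEG synchrony with low-frequency imaginary coherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ictal-phase EEG synchrony with low-frequency imaginary coherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Patients in super-refractory status epilepticus can develop *cyclic
seizures*: stereotyped nonconvulsive electrographic seizures recurring at
regular intervals (more than three per hour), visible on long-term
reduced-montage ICU EEG. A recurring observation across seizure models is
that synchronization between brain regions *rises* shortly before a seizure
ends, suggesting that hypersynchronization is part of the termination
mechanism itself. `ictalsync` implements a complete, testable pipeline for
asking that question of 8-channel scalp EEG: does synchrony in the final
seconds of a seizure (the *termination* phase) exceed the other ictal
phases, and where on the scalp?

## The synchrony estimator

The connectivity measure is the **low-frequency imaginary coherence
(LF-iCOH)**. For two channels \(x, y\), Welch-averaged spectra give the
coherency

\[ C_{xy}(f) = \frac{S_{xy}(f)}{\sqrt{S_{xx}(f)\,S_{yy}(f)}}, \qquad
   |C_{xy}(f)| \le 1 . \]

Scalp EEG is contaminated by *volume conduction*: one cortical generator
projects instantaneously to several electrodes, which inflates any
zero-lag measure of association. Instantaneous coupling is purely real in
\(C_{xy}\), so discarding the real part removes it. Per frequency band the
package takes the mean over in-band bins of \(|\mathrm{Im}\,C_{xy}(f)|\);
the absolute value keeps the index on a 0 (no lagged correlation) to 1
(perfect lagged synchrony) scale, which a signed imaginary part could not
satisfy. The LF index is the arithmetic mean of the delta-band
(\([1,4)\) Hz) and theta-band (\([4,8]\) Hz) values; the 4 Hz bin is
assigned once, to theta.

Spectral estimation defaults (configurable via `spectral_params()`): 2-s
Hann segments, 50 % overlap, per-segment mean removal. That yields 0.5 Hz
resolution — enough to resolve the 1 Hz band edge — and nine segments per
10-s analysis window. At least two segments are enforced: with one segment
\(|C_{xy}|\equiv 1\) identically and coherency is uninformative. Mean
removal matters because DC offsets otherwise leak into the bins adjacent
to 1 Hz. No additional filtering is applied inside the pipeline: clinical
acquisition is already bandpassed, and the synthetic data are generated
in-band.

Finite averaging biases \(|\mathrm{Im}\,C|\) of *independent* signals away
from zero; `icoh_null_quantile()` calibrates that floor by Monte-Carlo
simulation of independent Gaussian pairs under a fixed seed, and all
"no-correlation" claims in the tests are made against those quantiles
rather than against zero.

## From recording to synchrony table

Seizure onset/termination markers define four 10-s windows per seizure —
pre-ictal \([t_{on}-10, t_{on})\), onset \([t_{on}, t_{on}+10)\),
termination \([t_{term}-10, t_{term})\), post-ictal
\([t_{term}, t_{term}+10)\) — plus two windows around every inter-ictal
marker (placed at least 5 min from any seizure). Windows are half-open in
samples, the marker sample belonging to the following window, so abutting
windows never double-count; with the >20-s duration filter, onset and
termination windows can abut but never overlap. Seizure selection retains
seizures strictly longer than 20 s, honors a manual `exclude` flag (the
stand-in for visual artifact review, which is not automated here), and
warns — rather than fails — below 50 retained seizures so that small
cohorts remain analyzable.

Each window yields a symmetric \(8\times 8\) LF-iCOH matrix over the 28
electrode pairs (diagonal 0). The inter-ictal matrices are averaged into a
per-recording baseline \(Z_{ic}\), and every ictal matrix \(Z_n\) is
adjusted entry-wise to \((Z_n - Z_{ic})/Z_{ic}\): 0 means "at baseline",
positive values hypersynchronization. The adjustment requires every
baseline entry to be positive; the estimator's noise floor guarantees that
in practice, and a degenerate baseline below \(10^{-6}\) raises an error
naming the pair.

Two reductions feed the models. **Regional averages**: five regions
(anterior, centrotemporal, posterior, left, right), each the mean of five
designated electrode pairs. The published region-to-pair assignment is not
machine-readable, so the map is explicit configuration
(`default_region_map()`), anchored on each region's own electrodes with
hemisphere regions using only within-hemisphere pairs; analyses log the
map in force and accept replacements. **Electrode totals**: the row sum of
the seven off-diagonal adjusted entries of each electrode. Note the bounds
this implies: a single adjusted entry is \(\ge -1\), a regional average
\(\ge -1\), an electrode total \(\ge -7\).

Both reductions consume *adjusted* matrices by default (a raw mode exists
for descriptive plots), and the result is a long table — one row per
(seizure, phase, location) — so a cohort of \(S\) complete seizures yields
exactly \(20S\) region rows and \(32S\) electrode rows.

## Inference

`fit_lmm()` fits, by REML, `value ~ phase * location` with a random
intercept per seizure (per-patient tables) or crossed random intercepts
for patient and seizure-within-patient (pooled tables). Fixed-term
significance comes from Type II Wald chi-square tests (each term tested
after all terms not containing it); `dunnett_vs_termination()` computes,
per location, the three contrasts of termination against the other phases
with exact multivariate-t Dunnett adjustment per location family. The
per-location family (three contrasts) mirrors an analysis run "at each
localization"; it is deliberately not one global family across locations.

Two documented approximations:

* **Degrees of freedom.** Inference is large-sample (infinite-df Wald and
  normal-theory Dunnett). Kenward-Roger corrections are second-order at
  the problem sizes involved here (hundreds to thousands of windows, with
  dozens of random-effect groups); the calibration suite verifies directly
  that the resulting type-I error is nominal.
* **Response transform.** "Transform when appropriate" is operationalized
  deterministically: fit the identity model; if the residual skewness
  exceeds 1, refit with \(\log(v - lb)\) where \(lb\) is the level's
  theoretical lower bound (\(-1\) for regions — the familiar
  \(\log(1+v)\) — and \(-7\) for electrode totals), falling back to
  \(\sqrt{v - lb}\) when values touch the bound, where the log is
  undefined. The choice is recorded on the fitted object.

A location is *called* terminally hypersynchronized when termination
exceeds the comparison phases with adjusted \(p < 0.05\) **and** a
positive contrast sign. Whether "exceeds" means all three other phases or
any one of them is genuinely ambiguous in the source analysis; the strict
all-three rule is the default and the any-one rule is available
(`rule = "any"`), with both reportable side by side. The all-three rule is
conjunctive, hence conservative: its null call rate sits well below the
per-family \(\alpha\), which the calibration suite checks explicitly.

## The synthetic cohort generator

No public recordings of this kind exist, so the generator is a first-class
module with ground truth, built to contain exactly the features the
estimator claims to separate:

* **Background**: per-channel independent Gaussian noise FFT-shaped to
  \(1/f\), unit RMS, scaled to 20 µV.
* **Seizures**: durations from a truncated normal (default mean 118 s, SD
  34 s, floor 21 s — the floor keeps every synthetic seizure above both
  the 20-s duration filter and twice the 10-s terminal window), onsets on
  a jittered cycle (default 300 s, i.e. 12/h; an optional two-component
  mixture emulates clustered seizures). The duration defaults come from
  the published per-patient summaries shipped as `cohort_summary()`.
* **Discharge**: one common source per seizure — a cosine whose
  instantaneous frequency ramps linearly 6 → 2 Hz with slow Gaussian
  jitter (SD 0.8 Hz) and amplitude modulation (depth 0.3), with 2-s
  raised-cosine ramps to avoid edge artifacts. The jitter gives the
  rhythm a realistic ~1 Hz bandwidth, so in-band coherence is carried by
  several frequency bins rather than a single line.
* **Coupling**: the source is injected into both members of each
  configured pair, the second copy delayed by a whole number of samples
  (default 62.5 ms — a quarter period at the 4 Hz band center, which
  maximizes \(|\mathrm{Im}\,C|\)) and scaled by `gain` (default 0.15, a
  receiving electrode seeing an attenuated propagated discharge). During
  the final 10 s of every seizure the gain is multiplied by
  `terminal_boost` — the programmable terminal-hypersynchronization
  effect.
* **Volume conduction**: the 8-channel frame is multiplied sample-wise by
  a near-identity mixing matrix (default off-diagonal leakage 0.05), so
  zero-lag leakage exists as a genuine confound.
* **Baseline blocks**: seizure runs are interleaved with \(\ge 610\)-s
  seizure-free blocks, each hosting one inter-ictal marker at its center,
  which keeps every marker \(\ge 300\) s from all seizure boundaries.

Everything is deterministic given the configuration (one seed, restored
RNG state). The coupling parameters (gain 0.15, jitter 0.8 Hz, SNR 1) were
fixed once, at design time, so that a 3× terminal boost is a detectable
but not trivial effect at cohort scale; they are ordinary configuration
fields, not fitted quantities.

**The statistical null cohort has zero coupling gains** (pure background,
seizure markers intact). This is deliberate: with coupling present, even a
constant (unboosted) gain produces *true* phase and phase-by-location
effects — coupled ictal windows genuinely differ from noise-only pre- and
post-ictal windows — so such a cohort is not a null for any of the tests
of interest. Only the coupling-free cohort makes all four phase windows
exchangeable.

One calibration subtlety is worth spelling out. The modeled values of one
window — eight electrode totals, five regional averages — are reductions
of the *same* 28 matrix entries, so they are positively correlated across
locations within each (seizure, phase) cell. In location contrasts that
shared component cancels, while the iid-residual mixed model (random
intercepts for seizure/patient only, as specified) prices it into the
residual variance; the phase-by-location interaction test is therefore
*conservative* at the totals level — its null rejection rate falls below
the nominal 5 % — and the calibration suite asserts the correct one-sided
bound for it. The Dunnett contrasts compare phases *within* a location,
where the shared component genuinely contributes to the contrast variance,
so their per-family error rate is calibrated at \(\alpha\) (asserted
two-sided against the binomial confidence interval). An extra
per-(seizure, phase) random intercept would restore exact interaction
calibration but departs from the specified model; detection claims rest on
the Dunnett contrasts, which are calibrated as is.

What the generator does **not** emulate: real artifact structure
(movement, electrode pops, ICU devices), biophysical head geometry (the
mixing matrix is a scalar leakage pattern, not a lead field), multifocal
seizure morphologies, nonstationary baselines, or medication effects.
Passing calibration on these cohorts therefore demonstrates that the
pipeline recovers the effects it models — not that those are the only
effects present in clinical data.

## Numerical and scale choices

* Sampling: the generator defaults to the clinical 256 Hz. The replicate
  calibration suites run at 64 Hz with ~45-s seizures on a 150-s cycle:
  the analysis only ever probes 10-s windows at seizure boundaries with
  spectral content below 8 Hz, so these reductions change compute, not the
  statistical structure. The calibration problem sizes are 200 null
  cohorts of 20 seizures and 100 boosted cohorts of 60 seizures (the
  acceptance script reruns a 100/50 version).
* Welch segments must fit at least twice in a window; errors are raised,
  not papered over, when a window is too short.
* The "perfect lagged synchrony" fixture is a *quadrature* copy — a
  quarter-period shift applied at every frequency (Hilbert transform) —
  because a constant time lag cannot exceed ~0.7 LF-mean \(|\mathrm{Im}
  C|\) across a whole octave of band (the phase \(2\pi f\tau\) cannot sit
  near 90° at every in-band frequency simultaneously).
* EDF output is 16-bit with the physical range rounded to 4 significant
  digits so the 8-character ASCII header holds it exactly; round-trip
  error is bounded by the 16-bit half-step. Marker times are float seconds;
  markers between samples resolve to the nearest earlier sample.
* The Dunnett multivariate-t quadrature uses a fixed internal seed, making
  adjusted p-values reproducible run to run; they are additionally floored
  at the raw p-value (the mathematical constraint a ~1e-4 quadrature
  tolerance can otherwise violate).

## Known limitations

Monopolar signals are analyzed as stored; the reference electrode of the
clinical montage is unknown and no re-referencing is attempted. The
region map is a configuration default, not the published assignment. The
8-electrode montage limits spatial claims to coarse regions. Large-sample
df slightly understate uncertainty in very small cohorts (use the
calibration suite at your cohort size before trusting calls there). The
generator's stationary 1/f background makes the inter-ictal baseline
easier to estimate than in real ICU recordings, where artifact pruning of
inter-ictal markers is manual.
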