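# ictalsync

Quantifies brain synchronization across the phases of **cyclic seizures**
— stereotyped nonconvulsive electrographic seizures recurring more than
three times per hour, as seen in super-refractory status epilepticus —
from reduced-montage (8-electrode, 10–20 system) scalp EEG, and tests
whether synchrony rises in the final seconds of each seizure (*terminal
hypersynchronization*) and where on the scalp it does.

It is written for clinical neurophysiologists and methods researchers who
want the complete chain — estimator, baseline adjustment, reductions,
mixed-model inference, and a ground-truthed simulator to validate all of
it — as tested, reusable code rather than a one-off script.

## Method at its core

For each 10-s analysis window anchored on the seizure markers
(pre-ictal, onset, termination, post-ictal, plus inter-ictal baseline
windows), the package computes the **low-frequency imaginary coherence**
between all 28 electrode pairs:

* coherency from Welch-averaged cross-spectra,
  `C_xy(f) = S_xy(f) / sqrt(S_xx(f) S_yy(f))`;
* per band, the mean of `|Im C_xy(f)|` over in-band bins — discarding the
  real part removes instantaneous (volume-conducted) coupling;
* LF-iCOH = mean of the delta ([1,4) Hz) and theta ([4,8] Hz) band values.

Each window's 8×8 matrix `Z_n` is adjusted against the inter-ictal
baseline `Z_ic` (the mean over all inter-ictal windows) as
`(Z_n − Z_ic) / Z_ic`, then reduced to five regional averages (5 electrode
pairs each) and eight per-electrode totals (row sums). A REML linear
mixed-effects model `value ~ phase * location + (1 | seizure)` (crossed
patient/seizure intercepts for pooled cohorts) is tested with Type II
Wald chi-square statistics, and Dunnett-adjusted contrasts of the
termination phase against the other three phases decide, per location,
whether termination synchrony is significantly elevated.

Because no public recordings of this kind exist, the package includes a
first-class synthetic cohort generator (`sim_config()`,
`simulate_cohort()`): 1/f background, volume-conduction mixing, a jittered
6→2 Hz ictal chirp shared by lag-coupled electrode pairs, and a
programmable boost of the coupling gain in the final 10 s of every seizure
— with exact ground truth for calibration.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
cohort (60 seizures, C3–C4 coupling lagged 62.5 ms, terminal boost ×3):

```sh
Rscript analysis/01_simulate.R     # writes results/cohort/ (EDF + markers + truth)
Rscript analysis/02_connectivity.R # windows -> LF-iCOH matrices -> synchrony table
Rscript analysis/03_inference.R    # mixed models, Dunnett contrasts, calls
Rscript analysis/04_calibration.R  # type-I / power on replicate cohorts
```

`02_connectivity.R` prints the phase profile of the adjusted electrode
totals — the terminal elevation sits exactly where the coupling lives:

```
Mean adjusted LF-iCOH by phase (electrode totals):
    pre_ictal onset termination post_ictal
C3      0.314 0.625       1.264      0.283
C4      0.344 0.974       1.475      0.334
Fp1     0.245 0.275       0.187      0.338
...
```

(0 means "at the inter-ictal baseline"; 1.26 means LF-iCOH 126 % above
baseline.) `03_inference.R` then prints the deviance tables and calls:

```
=== electrode-level model (transform: identity) ===
           term     chisq df            p
          phase  70.06118  3 4.141497e-15
       location 283.11276  7 2.433754e-57
 phase:location 179.98714 21 2.983961e-27

Dunnett vs termination -- positive calls: C3, C4
```

The strong phase-by-location interaction and the positive calls at C3 and
C4 only (the region-level model calls `centrotemporal`) recover the
planted effect and its topography.

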