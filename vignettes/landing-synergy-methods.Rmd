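---
title: "Methods: muscle synergy analysis of single-leg landings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: muscle synergy analysis of single-leg landings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landsyn)
```

## Scientific model

`landsyn` analyses the modular organisation of leg-muscle activity during
single-leg drop landings on stable (SG) and unstable (UG) ground. The
central assumption is the muscle synergy model: the matrix of
amplitude-normalised EMG envelopes $V$ ($m = 13$ muscles $\times$
$n = 300$ cycle points) factorises as

$$ V \approx M P, \qquad M \in \mathbb{R}^{m \times p}_{\ge 0},
   \; P \in \mathbb{R}^{p \times n}_{\ge 0}, $$

where the columns of $M$ are *motor modules* (time-invariant muscle
weightings) and the rows of $P$ are *motor primitives* (module activation
over the landing cycle). The 13-muscle set spans the hip
(`ME`, `MA`, `FL`, `RF`), knee (`RF`, `VM`, `VL`, `ST`, `BF`) and ankle
(`TA`, `PL`, `GM`, `GL`, `SO`); see `muscle_groups()` for the
flexor/extensor partitions used by the coactivation index.

## Processing stages

### EMG conditioning (`condition_emg`, `normalize_amplitude`)

Raw EMG is high-pass filtered (4th-order Butterworth, 50 Hz cutoff),
full-wave rectified, and low-pass filtered (4th-order Butterworth, 20 Hz)
into a linear envelope. Both filters are applied with `signal::filtfilt`,
i.e. forward and backward, so each stage is zero-phase and the effective
attenuation order doubles. The `signal` package's `butter()` returns
transfer-function (b, a) coefficients rather than second-order sections;
at a 1 kHz sampling rate with 20/50 Hz cutoffs a 4th-order design is
well-conditioned in double precision, which the test suite verifies
through stop-band and zero-phase properties. Envelopes are amplitude
normalised per muscle to the maximum found over a reference series of
trials (the stable-ground series in the full pipeline), so values are
unitless fractions of the reference maximum and may exceed 1 in other
conditions.

### Landing segmentation and time normalisation (`segment_landing`, `normalize_trial`)

Touchdown is the first sample of vertical ground reaction force (vGRF)
strictly above 20 N. Stance ends when the vGRF, after the first strict
local minimum following the impact peak, first settles into the body-weight
$\pm 2.5\,\%$ band. The interval of interest spans the 300 ms before
touchdown (flight) plus the stance phase; each portion is linearly
interpolated onto a fixed grid — 100 flight points and 200 stance points —
so every landing occupies the same 300-point cycle with touchdown at
point 101.

### Synergy extraction (`extract_synergies`, `nmf_factorize`, `select_rank`)

For each candidate rank $p = 1..13$ the factorisation minimises the squared
Frobenius reconstruction error by Lee–Seung multiplicative updates
(implemented in C++ for the inner loop). Each rank uses 10 uniform random
restarts; iterations stop once the $R^2$ gain stays below $10^{-5}$ for 20
consecutive iterations. In addition to the random restarts, each rank seeds
one candidate from the previous rank's best factors plus a small positive
component ("nested warm start"). This is a deliberate numerical choice: it
makes the $R^2$-versus-rank curve structurally non-decreasing, whereas
purely random restarts occasionally leave high-rank fits in local minima
slightly below the preceding rank.

The model order is the smallest rank at which the $R^2$ curve becomes
linear to its right: the smallest $k$ whose trailing points $k..13$ are fit
by a least-squares line with MSE below $10^{-5}$. Factors are normalised so
each primitive has unit maximum, with the scale moved onto the module
(`normalize_factors`), leaving $M P$ unchanged.

### Classification (`classify_synergies`)

Primitives pooled across trials of a condition are clustered by
Hartigan–Wong k-means (20 random start sets) for $k = 1..13$; the total
within-cluster sum of squares is min–max normalised and the cluster count
chosen by an elbow rule: the smallest start index whose trailing segment is
fit by a least-squares line with MSE below $10^{-3}$. A naive reading of
the elbow as "the longest trailing segment interpolable by its endpoint
chord" fails in practice — once the WSS is near zero at the true $k$, the
chord over $k..13$ already fits, and the rule systematically returns
$k - 1$. The least-squares reading used here is the one consistent with
the rank-selection rule and recovers the planted cluster count on
synthetic cohorts.

Modules are then clustered at the same imposed $k$, module labels aligned
onto primitive labels by the contingency-maximising permutation, and each
partition is scored by $( \overline{\mathrm{FWHM}}_{\text{cluster}} +
\overline{\mathrm{CoA}}_{\text{cluster}} ) / 300$. If the two scores differ
by more than 0.05 the module partition is deemed unreliable and only the
primitive partition is kept. Synergies whose primitive and module labels
agree are *fundamental*; the rest are *combined*. With $k = 3$ clusters the
functional names `touchdown` < `weight_acceptance` < `stabilization` are
assigned by ascending centroid centre of activity.

### Metrics (`fwhm`, `coa`, `overlaps`, `coactivation_index`, `cop_ellipse_area`)

* **FWHM** — after subtracting the cycle minimum, the number of points
  strictly above half the maximum (all supra-threshold lobes count).
* **CoA** — the cycle is wrapped onto the unit circle and the primitive
  treated as a circular mass distribution; the CoA is the angle of its
  centre of mass mapped back to cycle points. Raw values are used as
  weights, without minimum subtraction — for nonnegative envelopes the
  baseline is part of the distribution, and subtracting it would make the
  statistic undefined for broad primitives.
* **Overlaps** — cycle points where at least two primitives exceed their
  own half-maximum.
* **Coactivation index** — $\mathrm{CaI} = \bar F / (\bar F + \bar E)$ from
  the pairwise-normalised mean flexor and extensor module weights at a
  joint; 0.5 is perfect balance, 0 pure extensor, 1 pure flexor drive.
* **CoP ellipse** — the 95 % confidence ellipse area
  $\pi \chi^2_{0.95,2} \sqrt{\det \Sigma}$ of the stance-phase
  centre-of-pressure covariance.

## Synthetic trial generator

No recordings ship with the package; `synthesize_trial()` and
`synthesize_cohort()` generate seeded trials with known ground truth so
every stage is testable end to end.

* **Primitives** are truncated Gaussians on the 300-point cycle
  ($\sigma = \text{width}/2.355$, so `width` is the FWHM), by default
  centred at points 90, 120 and 210 with widths 50, 55 and 70 — a
  pre-activation burst, a weight-acceptance burst and a late stabilisation
  burst.
* **Modules** load plantar flexors, knee extensors and a mixed
  dorsiflexor/hamstring group respectively, with a 0.05 baseline on all
  muscles.
* **EMG** is synthesised as envelope-modulated carriers: white noise
  band-passed to 20–450 Hz, scaled to unit RMS, multiplied by the true
  envelope $M P$ mapped from the cycle onto real time. Additive envelope
  noise is Gaussian, truncated at zero, at a configurable SNR (default
  20 dB). The carrier is zero-mean and broadband, so the conditioning
  stage faces realistic rectification and filtering behaviour.
* **Mechanics**: the vGRF is a smooth spline through randomised control
  points — flight below 20 N, an impact peak near 3 body weights, a dip,
  then settling into the $\pm 2.5\,\%$ band — built without additive
  broadband noise so the segmentation invariants hold by construction;
  randomness enters through peak heights, timings and stance duration
  (SG $\approx 0.49$ s, UG $\approx 0.63$ s on average). The CoP is an
  AR(1) mean-reverting walk whose innovation scale is 0.6× smaller on
  unstable ground, reproducing the smaller UG sway ellipse. Joint moments
  are gamma-shaped bursts with condition-typical peaks and times to peak.

The generator is *plausible, not person-specific*: it reproduces the
qualitative structure the analysis targets (three synergies, landing-shaped
kinetics, condition contrasts) and the exact invariants the estimators
assume, but it does not model motor-unit physiology, electrode crosstalk,
or fatigue. Its role is verification: planted parameters in, recovered
parameters out.

## Reproducible workflow

The `analysis/` directory holds numbered drivers over the package API:

1. `01_simulate.R` — simulate 52 landings per condition, write CSV/JSON
   trial fixtures under `results/trials/`.
2. `02_run_pipeline.R` — read the trials, run `run_pipeline()` (drop first
   and last landing, condition, segment, extract, classify), write the
   artifact tree under `results/run/`.
3. `03_report.R` — summarise the SG/UG comparison into `results/report.md`.

All randomness flows from a single integer seed fanned out per stage via
`sample.int`, so reruns are bit-reproducible.

```{r example, eval = FALSE}
library(landsyn)
res <- run_pipeline(pipeline_config(seed = 1L, n_trials = 12L))
res$summary$k
res$classification$SG
head(res$metrics)
```

## Limitations

* Problem sizes (13 muscles, 300-point cycle, 100 + 200 split) are fixed
  choices of this analysis, though most functions accept general
  dimensions.
* The elbow and rank-selection thresholds ($10^{-3}$, $10^{-5}$) are
  tuned to normalised curves; they are exposed as configuration but not
  adaptive.
* Zero-phase filtering is non-causal and therefore unsuitable for online
  use; edge transients mean the first and last ~0.5 s of a record should
  not be interpreted.
* The CoA uses raw weights; for primitives with large additive offsets it
  is biased toward the cycle's centre of mass rather than the burst.
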