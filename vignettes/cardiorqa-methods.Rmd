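---
title: "Models and methods behind cardiorqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cardiorqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cardiorqa)
```

`cardiorqa` studies how cardiac and autonomic dysfunction expresses itself
in the *nonlinear* dynamics of a single-lead ECG.  Classical heart rate
variability (HRV) statistics summarise the tachogram — the sequence of
R-to-R intervals — but cannot separate a change in autonomic modulation
from a change in the heart's own electrical behaviour.  The package
therefore pairs a controllable simulator of rat ECG with a recurrence
quantification analysis (RQA) pipeline, and scores real or simulated
recordings by projecting their recurrence signature onto the simulated
reference conditions.

## The synthetic ECG model

### Tachogram synthesis

The RR series is generated in the spectral domain.  A bimodal target power
spectrum

$$S(f) = r\,e^{-(f - f_{LF})^2/2\sigma_{LF}^2} + e^{-(f - f_{HF})^2/2\sigma_{HF}^2}$$

is sampled on the beat-frequency grid (the beat series is treated as
sampled at the mean beat rate, $\bar{HR}/60$ Hz), each spectral line gets a
uniformly random phase, and the inverse FFT yields a real heart-rate
modulation.  The series is then *affinely rescaled* so the instantaneous
heart rate has exactly the requested sample mean and SD, and converted to
RR in ms as $60000/HR$.  Defaults emulate standard rat heartbeat dynamics:
mean 350 bpm, SD 50 bpm.

The weight $r$ is the LF/HF ratio (HF weight fixed at 1), exercised over
the grid $\{0, 0.5, 1, 1.5\}$ in the condition study.  Published rat
spectral bands vary; we fix the LF peak at 0.35 Hz (width 0.1 Hz) and the
HF peak at 1.5 Hz (width 0.3 Hz), conventional values for rodent HRV, and
expose all four as `tachogram_spec()` arguments.  With the 350 bpm default
the beat-grid Nyquist frequency (about 2.9 Hz) comfortably contains both
bands.  An HF-dominated tachogram ($r = 0$) oscillates close to the beat
scale and so decorrelates quickly; raising $r$ moves spectral mass to slow
modulations and raises the lag-one autocorrelation — the property the test
suite checks.

Tachogram "measurement" noise is additive white Gaussian noise whose SD is
`level` times the *peak-to-peak range* of the clean RR series, at levels
$\{0, 0.33, 0.66, 0.99\}$.  We read "percent of maximum amplitude" as the
peak-to-peak range of the signal being noised; an alternative reading
(maximum deviation from the mean) differs only by a constant factor and is
available by scaling `level`.  Noised intervals are floored at 40 ms —
far below any physiological rat RR — so the series stays positive.

### PQRST templates

Each beat is a sum of five Gaussian bumps on a cycle angle
$\theta \in [-\pi, \pi)$:

$$v(\theta) = \sum_{w \in \{P,Q,R,S,T\}} a_w\,
  \exp\!\left(-\frac{(\theta - \theta_w)^2}{2 b_w^2}\right)$$

with the reference (DET) parameters

| wave | $\theta_w$ (deg) | $a_w$ | $b_w$ |
|------|------------------|-------|-------|
| P    | $-70$            | 1.2   | 0.25  |
| Q    | $-15$            | $-5$  | 0.1   |
| R    | 0                | 30    | 0.1   |
| S    | 15               | $-7.5$| 0.1   |
| T    | 100              | 0.75  | 0.4   |

The four conditions differ only where their pathology lives: **LQT**
widens the T wave ($b_T = 0.6$), emulating delayed repolarisation;
**AF** collapses the P wave ($a_P = 0.2$, $b_P = 0.125$) *and* overwrites
the P/PQ angular segment ($[-90°, -30°]$, ending before the Q onset) with
white noise of SD 0.2 template units, emulating fibrillatory atrial
activity; **NSE** keeps the DET morphology but raises the additive trace
noise to 100 % of the maximum absolute amplitude (all other conditions
carry 1 %).  We deliberately implement AF with *both* mechanisms — a
residual low P wave plus PQ noise — because suppressed-but-present atrial
activity is the more realistic electrogram; either mechanism can be
disabled through the `condition_params()` fields.  We also retain the Q
wave for all conditions: rat ECG often shows small Q deflections and the
reference parameter set defines one, so "rat-like" simplification is
expressed through rate and morphology parameters rather than by deleting a
wave.

Beats are *sequenced*, not integrated: beat $k$ spans one full cycle
resampled to `round(fs * RR_k / 1000)` points and the beats are
concatenated.  This keeps every beat's morphology exact at any RR and
makes the zero-noise DET trace strictly periodic, at the price of a known
artifact: the R peak sits at the centre of its cycle, so the R-to-R
spacing of the *rendered* trace equals the average of adjacent source RR
intervals (a one-beat moving average).  HRV statistics in the package are
therefore computed from the source tachogram, not re-detected from
rendered traces, unless the user explicitly asks for the detection route.
A limit-cycle ODE backend (continuous phase dynamics) would remove the
artifact and remains a possible extension.

### What the simulator does not emulate

Real recordings carry baseline wander, electrode motion artifacts,
ectopic beats, respiration-locked amplitude modulation and
nonstationarity across minutes.  None of these are modelled.  Passing the
package's tests therefore demonstrates correctness of the *methods* and
their behaviour under controlled noise/modulation — not robustness to
every artifact class of animal electrophysiology.

## HRV and Poincaré descriptors

`sdnn()` and `rmssd()` use the sample ($n-1$) convention.  `poincare()`
computes SD1/SD2 as the sample SDs of the rotated coordinates
$(x - y)/\sqrt2$ and $(x + y)/\sqrt2$ of the lag-$\ell$ return map.  Under
these conventions the identities $SD1 = RMSSD/\sqrt2$ and
$SD1^2 + SD2^2 = 2\,SDNN^2$ hold only up to $O(1/n)$ edge terms, so the
tests assert them at $n = 1000$ with 1 % tolerance rather than exactly.
No NN filtering (ectopy rejection) is applied: the simulator produces
none, and a pre-filter can be applied to the tachogram before the
statistics.

## The recurrence pipeline

Phase space is reconstructed by delay embedding
($x_i, x_{i+\tau}, \ldots, x_{i+(m-1)\tau}$).  The delay $\tau$ is the
first lag at which the average mutual information (AMI) of the series and
its lagged copy drops to $\le AMI(0)/e$; AMI is computed from a joint
histogram with Sturges-rule bins ($\lceil 1 + \log_2 n\rceil$ per axis,
shared edges).  For strongly deterministic signals AMI may never cross
the threshold; the selector then falls back to the AMI-minimising lag with
a warning.  The dimension $m$ is the first with a Kennel
false-nearest-neighbour fraction below 0.1 (tolerances $r_{tol} = 10$,
$a_{tol} = 2$, common defaults the source material leaves unstated).  Both
parameters are selected per recording as the median over up to ten epoch
windows and then held fixed across that recording's epochs, so epochs stay
comparable.

Distances are Euclidean and normalised by the maximum phase-space
diameter, putting every signal on a common $[0, 1]$ scale; the recurrence
threshold is $\varepsilon = 0.09$ of that diameter.  The recurrence plot
is $RP_{ij} = H(\varepsilon - DM_{ij})$, i.e. 1 iff $DM_{ij} <
\varepsilon$.

Ten factors are computed from the binary matrix and its maximal
diagonal/vertical line-length histograms (`rqa_factor_names`).  Numerical
conventions, fixed once:

* Minimum qualifying line length $\ell_{min} = 3$ for both diagonals and
  verticals.
* A Theiler window of 1 excludes the line of identity from the *diagonal*
  histogram (otherwise determinism saturates at 1 on any signal);
  vertical lines are counted over the full matrix.
* Determinism uses the standard normalisation: diagonal mass at
  $d \ge \ell_{min}$ over diagonal mass at $d \ge 1$.
* The return-time factors are computed per column from the rows of its
  recurrence set: T1 averages all successive gaps (sojourn points
  included); T2 first collapses each consecutive run to its first point
  (sojourn points excluded).  On a noiseless sine, T2 recovers the period.
* A factor whose qualifying structure is absent is reported as 0 and
  flagged in the `undefined` attribute rather than as `NA`, keeping factor
  matrices dense for PCA; the flags are available for masking.

A TREND-style drift factor is deliberately not part of the vector: the
ten factors above form the canonical set the projection protocol is
defined on.

Every factor is pinned to a brute-force oracle — explicit cell-by-cell run
enumeration on random binary matrices — in the test suite, so the
vectorised implementation cannot silently drift from the definitions.

## Cohort analysis and the projection protocol

Per-epoch factor vectors from all conditions are pooled into one matrix
(rows = epochs, columns = the ten factors).  Because the factors span
orders of magnitude (rates in $[0,1]$, lengths in samples), columns are
z-scored before the eigendecomposition; zero-variance columns are dropped
with a warning.  Loadings get a deterministic sign convention (largest
absolute loading positive) so runs are comparable.  New recordings are
*projected* with the fitted standardisation and loadings — never refit —
and scored by the Euclidean distance of their centroid to each reference
condition centroid in the PC1–PC2 plane.  Distances are taken in 2-D
because the first two components carry the overwhelming share of the
variance in the pooled factor matrix; the `dims` argument generalises
this.

The companion statistics follow the nonparametric route throughout:
Kolmogorov–Smirnov normality per group, Kruskal–Wallis across more than
two groups with a Tukey–Kramer studentised-range comparison of mean ranks
as post hoc (an approximation consistent with common statistical
environments), Mann–Whitney for two groups, and an average-linkage
Euclidean clustergram of the standardized factor matrix.

## Problem sizes and numerical choices

The condition study (`aecg_factor_study()`) defaults to 20 epochs of 2 s
at 250 Hz per grid cell — 500 samples per epoch, 1280 epochs over the
4 × 4 × 4 grid.  These sizes were chosen so a full study runs in minutes
on a laptop while each epoch still contains 10–12 beats and several
hundred embedded points, enough for stable line-length histograms at
$\varepsilon = 0.09$.  Epoch length, count, sampling rate, AMI lag range
and the FNN dimension cap are all arguments; nothing in the method depends
on these defaults.  Longer epochs mainly lengthen diagonal lines and grow
the $O(N^2)$ recurrence matrix; they do not change the ordering of the
conditions in factor space.

Degenerate inputs are handled explicitly rather than by `NA` propagation:
constant series give zero AMI and zero FNN (with warnings), a zero
phase-space diameter yields an all-zero distance matrix flagged
`degenerate`, a constant tachogram noised at level $> 0$ falls back to a
mean-scaled noise SD, and RR floors guarantee positivity everywhere.

## Known limitations

* The projection protocol is a *similarity score*, not a classifier: no
  decision boundary, calibration or cross-validation is provided, and no
  diagnostic claim should be read into centroid distances.
* Frequency-domain HRV estimation from data is out of scope; the LF/HF
  ratio exists only as a simulator input.
* The R-peak detector is amplitude-based and tuned for R-dominated rodent
  traces; heavily corrupted recordings need a dedicated detector, which
  can be injected via `threshold_policy`.
* Epoch-level RQA assumes within-epoch stationarity; drifting recordings
  should be segmented upstream.
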