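# cardiorqa

Nonlinear dynamics of rodent electrocardiograms: a simulation and analysis
toolkit for separating autonomic modulation from cardiac dysfunction in
single-lead ECG.

Classical heart rate variability (HRV) statistics — SDNN, RMSSD, the
Poincaré descriptors SD1/SD2 — summarise the tachogram (the R-to-R
interval series) but respond to measurement noise and autonomic modulation
in ways that mask genuine cardiac morphology changes.  `cardiorqa`
addresses this with recurrence quantification analysis (RQA): the signal
is delay-embedded into phase space
(x_i, x_{i+τ}, …, x_{i+(m−1)τ}), with τ chosen at the first drop of the
average mutual information below AMI(0)/e (Sturges-binned histograms) and
m by the first Kennel false-nearest-neighbour fraction below 0.1.
Distances are normalised by the maximum phase-space diameter and
thresholded at ε = 9 % of it, RP_ij = H(ε − DM_ij), and ten recurrence
factors are computed per epoch: recurrence rate (RecR), determinism (DTM),
mean and maximum diagonal length (⟨D⟩, Dmax), diagonal-length entropy
(ENTR), laminarity (LAM), trapping time (TT), maximum vertical length
(Vmax) and the type-1/type-2 mean return times (T1, T2).

A built-in simulator renders rat ECG (350 ± 50 bpm) from Gaussian PQRST
templates sequenced over spectrally synthesised tachograms, in four
reference conditions — regular/deterministic (DET),
atrial-fibrillation-like (AF: suppressed P wave, noised PQ segment),
long-QT-like (LQT: widened T wave) and noise-dominated (NSE) — across
grids of tachogram noise (0/33/66/99 % of RR range) and LF/HF spectral
balance (0/0.5/1/1.5).  Per-epoch factor vectors from the grid are pooled,
z-scored and decomposed by PCA; a new recording is scored by projecting
its factors into that space and measuring the Euclidean distance of its
centroid to each condition centroid in the PC1–PC2 plane.

## Worked example

```r
library(cardiorqa)

# 1. simulate two conditions on the same autonomic background
spec <- tachogram_spec(mean_hr = 350, sd_hr = 50, lf_hf_ratio = 0.5,
                       n_beats = 300, seed = 1)
tac  <- build_tachogram(spec)
det  <- synthesize_ecg(condition_params("DET"), tac, fs = 250, seed = 2)
af   <- synthesize_ecg(condition_params("AF"),  tac, fs = 250, seed = 2)

# 2. classical HRV from the tachogram
round(hrv_summary(tac), 2)
#>    sdnn rmssd   sd1   sd2
#> 1 26.49 35.49 25.14 27.81

# 3. per-epoch recurrence factors (delay/dimension chosen per recording)
f_det <- ecg_rqa(det, epoch_s = 2, n_epochs = 6, m_max = 6)
f_af  <- ecg_rqa(af,  epoch_s = 2, n_epochs = 6, m_max = 6)
round(head(f_det[, c("tau", "m", "recr", "dtm", "lam", "tt", "t2")], 3), 3)
#>   tau m  recr   dtm   lam     tt     t2
#> 1   1 4 0.692 0.986 0.990 31.894 38.643
#> 2   1 4 0.705 0.995 0.995 32.567 41.290
#> 3   1 4 0.705 0.995 0.993 32.755 38.937

# 4. PCA of the pooled factor matrix and centroid distances to DET
pooled <- rbind(cbind(condition = "DET", f_det), cbind(condition = "AF", f_af))
model  <- pca_fit(factor_matrix(pooled))
sprintf("PC1+PC2 explain %.1f%% of the factor variance",
        100 * sum(model$explained[1:2]))
#> [1] "PC1+PC2 explain 70.9% of the factor variance"
centroid_distances(model$scores, pooled$condition, "DET")
#>   label   pc1      pc2 distance
#> 2   DET -0.84  0.00645     0.00
#> 1    AF  0.84 -0.00645     1.68
```

The HRV row reads in milliseconds: this background (LF/HF 0.5, no added
tachogram noise) gives an SDNN of ~26 ms around the 171 ms mean RR.  In
the factor table, both recordings are highly recurrent and deterministic
(the simulated beats repeat), but the AF epochs separate cleanly from DET
along PC1 — the centroid distance of 1.68 score units versus 0 for the
reference — which is exactly the contrast the projection protocol is
designed to expose.

A thin command-line wrapper ships with the package (see
`system.file("cli", "cardiorqa", package = "cardiorqa")`) with
`simulate`, `hrv`, `rqa`, `project` and `fixtures` subcommands.

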