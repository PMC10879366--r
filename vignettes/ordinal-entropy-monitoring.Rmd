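---
title: "Causal ordinal-entropy monitoring of anesthesia EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal ordinal-entropy monitoring of anesthesia EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During induction of and emergence from general anesthesia a patient crosses
between responsiveness and unresponsiveness, and EEG-based monitors try to
track that crossing in real time. `ordeeg` implements an ordinal-analysis
pipeline for this setting built around two scores: **permutation entropy
(PE)**, the Shannon entropy of the distribution of local rank-order
patterns of a single frontal channel — a probabilistic measure of signal
irregularity — and **symbolic transfer entropy (STE)**, the transfer
entropy between the ordinal-pattern sequences of two channels — a directed
measure of fronto-parietal information transfer, the mechanism most often
invoked for anesthetic-induced unconsciousness.

Every processing step is *causal*: no output at time $t$ uses input after
$t$. This is the property that makes the pipeline compatible with online
patient monitoring, and it is bought with one fixed, known delay in the
resampling chain (500 ms, below).

## The processing chain

**Resampling (250 → 200 Hz).** Input EEG at 250 Hz is upsampled to
1000 Hz by stuffing three zeros between samples (gain ×4 folded into the
filter), band-limited to 0–30 Hz with an order-1000 windowed-sinc (Hamming)
FIR, and decimated by keeping every fifth filtered sample. Because the
impulse response is symmetric, the filter is linear-phase: all frequencies
are delayed by exactly 500 samples at 1000 Hz, i.e. **500 ms**, and
relative timing between channels is preserved exactly. The chain is
strictly causal. Output sample $k$ is timestamped at the newest input it
can depend on (sample times are `start + (k-1)/200`), so timestamps are
availability times: the signal content at a timestamp reflects the input
500 ms earlier. The coefficient vector is renormalized to exact unit DC
gain, and the design is verified at construction: at most 1 dB droop up to
90 % of the cutoff, at least 40 dB attenuation over the 100–500 Hz alias
band of the 200 Hz output (the Hamming design achieves > 50 dB). The
decimation keeps filtered samples at indices ≡ 0 (mod 5); a different phase
would shift timestamps by under 5 ms. The first second of output is flagged
unsettled (the 500 ms start-up transient plus margin) and no analysis
window may start inside it.

**Ordinal encoding (m = 5, τ = 1).** Each 200 Hz channel is mapped to the
sequence of ordinal patterns of five consecutive samples: the code of a
window is the lexicographic rank (0-based, 0…119) of the permutation of
time indices that sorts the values ascending. Any fixed bijection between
patterns and integers would do, since only pattern *frequencies* enter the
entropies; the lexicographic convention is fixed here so that brute-force
enumeration oracles can verify the encoder. Ties are broken by temporal
order (the earlier sample ranks lower), which makes the encoding
deterministic; ties are measure-zero on real-valued EEG and the synthetic
generator adds measurement noise so they stay so. Codes are invariant under
any strictly increasing transform of the signal — amplitude calibration
cannot affect the scores.

**Segmentation (30 s windows, 1 s shift).** Pattern sequences are cut into
sliding data blocks of 30 s of underlying EEG shifted by 1 s. A pattern
belongs to a block when *all* of its underlying samples fall in the
window, so a 6000-sample window yields $6000 - (m-1)\tau = 5996$ patterns
per channel. Each block is timestamped at the right edge of its window —
the first instant at which its rightmost sample exists, which for
recordings starting at 0 puts blocks on the integer grid 30 s, 31 s, …

**Entropy estimation.** All estimators are plug-in (relative-frequency)
estimators reported in bits. Transfer entropy from source $X$ to target
$Y$ at transfer delay $\delta$ is estimated as

$$T_{X\to Y} = H(Y_t, Y_{t+\delta}) - H(Y_t) - H(X_t, Y_t, Y_{t+\delta}) + H(X_t, Y_t),$$

with **all four entropies computed as marginals of the single empirical
distribution of triples $(X_t, Y_t, Y_{t+\delta})$ over the common index
range $t = 1 \ldots n-\delta$**. The counting recipe does not by itself fix
the index range of each term; the common-range choice is what makes the
estimate an (empirical) conditional mutual information and therefore
non-negative by construction, which the test suite asserts on thousands of
random blocks. Per block, STE is computed for the four fronto-parietal
pairs Fp1→P3, Fp1→P4, Fp2→P3, Fp2→P4 and their four reverses, at six
transfer delays $\delta = 7\ldots12$ pattern steps (35–60 ms at 200 Hz) —
48 estimates per block. The reported scores are `STE_FP` (mean of the 24
fronto-parietal estimates), `STE_PF` (mean of the 24 reverses), `STE_UND`
(their sum — the undirected total), `STE_MEAN` (mean of all 48, i.e.
`STE_UND/2`; both aggregations are conventional and differ only by the
factor 2), and `PE` (permutation entropy averaged over Fp1 and Fp2).
Plug-in entropies are biased low by roughly $(K-1)/(2N\ln 2)$ for $K$
occupied cells and $N$ observations; with $N \approx 6000$ this is ~0.014
bits for PE, while the STE values carry a larger, state-dependent bias.
None of it is corrected: the classification analysis only compares scores
against a threshold learned from the same estimator, so a common bias is
immaterial. Scores are in bits; normalization of PE by $\log_2 120$ would
only rescale and is not applied.

**Delays are delays.** $\delta$ is applied on the pattern-index grid at
200 Hz, so $\delta = 7$ probes couplings at 35 ms; the synthetic
generator's coupling lag of 40 ms falls inside the probed 35–60 ms range
by design. Transfer entropy per block uses only within-block tuples.

## Responsiveness classification

Scores are sampled at four time points per patient: **T1** = LoR − 15 s
and **T2** = LoR + 30 s around loss of responsiveness, **T3** = RoR − 15 s
and **T4** = RoR + 30 s around return. With right-edge timestamps and 30 s
windows, the block at T1 covers [LoR − 45, LoR − 15] — entirely
pre-anesthetic — and the block at T2 covers [LoR, LoR + 30] — entirely
post-LoR; T1/T4 are labelled responsive, T2/T3 unresponsive. The block
nearest each target time is used and must lie within 0.5 s.

For each score a single decision threshold is selected to maximize the
accuracy $(t_p + t_n)/(t_p + f_p + t_n + f_n)$ of the **LoR contrast**
(T1 vs T2), and that threshold is reused for the RoR and combined
contrasts. Candidate thresholds are the midpoints between consecutive
distinct pooled scores plus one candidate below the minimum and one above
the maximum; accuracy is piecewise constant in the threshold, so this grid
is exhaustive (the tests verify optimality against a dense scan). Ties are
broken toward the smallest candidate, and classification is strict:
"positive for wakefulness" means score *strictly above* the threshold.

Confidence intervals are percentile bootstrap intervals from 10,000
resamples drawn at the **patient** level (a patient's four time points
travel together — the only exchangeable unit here), with the threshold
held fixed inside replicates. Re-selecting the threshold per replicate
would propagate selection optimism into the interval; holding it fixed
matches the analysis being bootstrapped but means the intervals inherit
the optimism of the original threshold selection — a deliberate, documented
caveat. Score-vs-score comparisons use *paired* resampling (both
accuracies recomputed on the same patient resample), which narrows the
interval exactly when the scores are positively correlated across
patients, as the tests demonstrate. The percentile method (rather than
BCa) is the simplest interval consistent with this design.

## The synthetic cohort

No clinical EEG ships with the package, so validation runs on a seeded
synthetic cohort designed to carry the two effects the pipeline claims to
detect, with everything else stationary:

* each channel blends an **awake** process — AR(2) with spectral peak at
  10 Hz, pole radius 0.95 — and an **anesthetized** process — AR(2) peaked
  at 1.5 Hz, radius 0.98, three-fold innovation amplitude: a slow, large,
  more regular oscillation. AR(2) is the simplest stationary process with
  a controllable resonance;
* the blend weight is a product of two logistics of width 10 s, falling
  from awake to anesthetized around LoR and back around RoR, emulating
  transitions on the ~1 min scale;
* parietal channels receive the mean frontal signal lagged by 10 samples
  (40 ms), with gain 0.4 while awake and 0.05 while anesthetized — the
  directed fronto-parietal coupling contrast;
* white measurement noise at 5 % of the awake SD keeps ordinal ties
  measure-zero;
* LoR is drawn uniformly in [60, 120] s, RoR in [duration − 120,
  duration − 60] s; per-patient seeds are `master seed + patient index`,
  so cohorts are bit-reproducible.

The default duration is 300 s — the shortest span that comfortably holds
both randomized transitions plus a maintained anesthetized segment. The
frozen validation cohort is 20 patients at these defaults; on it, awake
PE and STE exceed their anesthetized values in at least 19/20 patients,
the pre-LoR median of STE_FP exceeds STE_PF in at least 19/20, and the
LoR accuracy of PE reaches at least 0.9 (in fact 1.0: the designed effect
sizes separate the states perfectly, unlike clinical EEG).

What the generator does **not** emulate: biophysically realistic EEG
(no neural mass dynamics), artifacts, EMG, electrode noise, burst
suppression, substance-specific emergence heterogeneity, or
between-patient spectral variability. Passing the end-to-end tests
therefore shows that the pipeline *recovers designed effects of realistic
shape and timing*, not that it attains any particular accuracy on
clinical recordings — on real data both scores are expected to overlap
substantially between states.

## Numerical and design choices

* **Tie rule** in ordinal encoding: stable (earlier index lower) — pure
  determinism, no statistical motivation needed at measure-zero ties.
* **TE index range**: common range for all four entropy terms (see above);
  tiny negative rounding residues are clamped to 0.
* **Degenerate inputs**: constant windows give PE = 0 and STE = 0; all-zero
  count vectors, empty windows, misaligned sequences, non-finite samples
  and wrong sampling rates raise informative errors rather than silently
  proceeding.
* **Threshold grid**: midpoints between distinct order statistics are the
  canonical representatives of the accuracy function's flat pieces; the
  below-min/above-max candidates cover the all-positive / all-negative
  rules.
* **Bootstrap determinism**: every resampling routine takes an explicit
  seed and restores the RNG state afterwards; at B = 10,000 the interval
  bounds drift by well under 0.01 between seeds.
* **EDF support** uses a minimal classic-EDF (16-bit) reader/writer;
  signals round-trip within one digital quantization step.
* **Compiled kernel**: the per-block 48-estimate STE computation is
  implemented in C++ with shared per-target marginals; the exported R
  `transfer_entropy()` is the reference implementation, and the suite
  asserts the two agree to 1e-12 along with a brute-force tabulation
  oracle.

## Problem sizes

The shipped tests and the acceptance script use the 20-patient, 300 s
frozen cohort (≈ 270 blocks per recording, ≈ 13,000 STE estimates per
patient), 10,000-fold bootstraps, 1000-block non-negativity sweeps, and
120-replicate bias Monte-Carlos; these sizes were chosen so the designed
effects are measured with comfortable margins while the whole suite stays
fast on a single CPU.

## Known limitations

* The accuracy threshold is learned and evaluated on the same cohort;
  the reported accuracies are apparent accuracies, not out-of-sample ones.
* Plug-in STE at block size 5996 with up to 120³ occupied triple cells is
  bias-dominated; only *contrasts* of STE between states are meaningful,
  not its absolute level.
* The causal chain's 500 ms delay plus the 30 s window means a state
  change is fully reflected in the scores only ~30 s after it occurs —
  inherent to the design, not a defect.
* No artifact rejection, re-referencing or notch filtering is provided.
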