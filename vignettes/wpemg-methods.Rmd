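---
title: "Methods: wavelet-packet features and boosted committees for EMG classification"
author: "wpemg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet-packet features and boosted committees for EMG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Needle electromyography distinguishes three broad diagnostic situations by
the morphology of motor unit action potentials (MUAPs): normal muscle
(MUAPs around 1 mV and 9 ms, two to four phases), myopathy (short, small,
polyphasic MUAPs, as surviving fibres per unit dwindle) and neuropathy
(long, large MUAPs from collateral reinnervation, with fewer recruitable
units). `wpemg` implements an automated pipeline for this three-class
decision: fixed-length frames of the raw signal are summarised by
wavelet-packet subband statistics and classified by committee methods
(bagging, AdaBoost.M1, MultiBoosting) over interpretable base learners.

Clinical EMG archives are rarely redistributable, so the package includes a
synthetic MUAP-train generator whose class profiles encode the textbook
contrasts above. Everything downstream of the generator is agnostic to where
the recordings came from: any directory of one-sample-per-line text files
with a manifest can be processed.

## The synthetic generator

A recording is
\[
x(t) = \sum_{u=1}^{U} \sum_{k} m_u(t - t_{u,k}) + \varepsilon(t),
\]
band-limited after superposition. Each motor unit $u$ draws one MUAP
template $m_u$ and fires at times $t_{u,k}$ given by a renewal process with
Gaussian-jittered inter-pulse intervals (mean $1/f$, standard deviation
$\text{jitter}/f$, truncated positive). $\varepsilon$ is white Gaussian
noise.

The MUAP template is a train of `n_phases` alternating-sign Gaussian lobes
spanning `duration_ms`, rescaled to peak at `amplitude_mv`. For an odd phase
count of three or more the two end lobes are halved so the alternating lobe
areas cancel analytically and the waveform returns to baseline with
essentially zero net area; a monophasic template is a single lobe and
necessarily carries net area (a zero-area waveform must cross zero). The
number of baseline crossings is exactly `n_phases` − 1 by construction.

Default class profiles (per-recording draws, truncated at zero):

| class | amplitude (mV) | duration (ms) | phases | units | rate (Hz) |
|---|---|---|---|---|---|
| Normal | 1.0 ± 0.3 | 9 ± 2 | 2–4 | 12 | 10 |
| Myopathy | 0.4 ± 0.15 | 5 ± 1.5 | 4–6 | 12 | 12 |
| Neuropathy | 1.6 ± 0.5 | 14 ± 3 | 2–4 | 5 | 8 |

Morphology defaults follow the clinical contrasts; firing rates encode the
early recruitment of myopathy (more units at higher rates for a given
effort) and the reduced recruitment of neuropathy. Firing jitter defaults
to a coefficient of variation of 0.2, typical of semi-steady voluntary
contraction. The additive noise floor defaults to 0.01 mV (10 µV RMS), the
order of a clinical needle-EMG baseline; it is deliberately small relative
to even myopathic MUAPs so the classes remain separable by design — the
generator's purpose is to exercise the pipeline, not to calibrate clinical
difficulty.

Acquisition defaults mirror a standard protocol: 20 kHz sampling for 5 s,
analogue band 5 Hz – 10 kHz. Band-limiting uses a zero-phase 4th-order
Butterworth filter (applied forward and backward) so MUAP shapes are not
phase-distorted. Because the default upper band edge coincides with the
Nyquist frequency, where a digital band-pass is undefined, the filter
degenerates to the high-pass at 5 Hz alone whenever the upper edge reaches
99% of Nyquist: discrete samples carry no energy above Nyquist, so the
analogue upper edge is vacuous digitally. Twelve-bit quantization is
available behind a flag but off by default; it is irrelevant to the methods
under test.

What the generator does **not** emulate: volume conduction and electrode
geometry, needle repositioning, recruitment dynamics with effort,
within-recording nonstationarity, firing-rate modulation, motor-unit
synchronisation, and between-subject variability beyond the per-recording
parameter draws. Consequently a classifier's accuracy on the synthetic
benchmark says the pipeline can exploit class-dependent MUAP statistics; it
is not an estimate of clinical performance.

## Framing and features

Recordings are cut into non-overlapping rectangular frames of 2048 samples
starting at sample 0, the trailing remainder discarded (a 5 s recording at
20 kHz yields 48 frames). Sample and frame indices are 0-based. An overlap
parameter exists but defaults to 0.

Each frame is decomposed by a level-4 wavelet packet transform. The
transform is a periodized orthogonal filter bank: with scaling filter $h$
and quadrature mirror $g[n] = (-1)^n h[L-1-n]$, one analysis step maps a
length-$N$ block to two length-$N/2$ blocks by circular filtering and
dyadic downsampling. Periodization keeps the operator exactly orthogonal at
every even block length, which gives machine-precision Parseval energy
conservation and perfect reconstruction — both enforced by tests. The
default wavelet is Daubechies-4 (`db4`), a common choice for EMG; `haar`,
`db2`, `db8`, `sym4` and `sym8` are available. Terminal subbands are
reported in frequency (sequency) order — the Gray-code permutation of the
filter-bank order that accounts for the spectral mirroring of each detail
branch — so that "adjacent subbands" means adjacent frequency bands.

Six statistics summarise the coefficients $y_1,\dots,y_M$ of each of the 16
terminal subbands:

* mean absolute value $\frac{1}{M}\sum |y_j|$,
* average power $\frac{1}{M}\sum y_j^2$,
* population standard deviation $\sigma = \sqrt{\frac{1}{M}\sum (y_j-\bar y)^2}$
  (divisor $M$, no Bessel correction),
* skewness $\frac{1}{M}\sum ((y_j-\bar y)/\sigma)^3$,
* kurtosis $\frac{1}{M}\sum ((y_j-\bar y)/\sigma)^4$ — **raw**, without the
  −3 excess term,
* and, between frequency-adjacent subbands, the ratio
  $\sum |y_j| \,/\, \sum |z_j|$.

That is $16 \times 5 + 15 = 95$ features per frame, in deterministic column
order (five statistics per subband in frequency order, then the ratios).
Degenerate cases return 0 with a warning rather than NaN: skewness and
kurtosis of a zero-variance subband, and ratios with a zero denominator.
Classifiers require finite features; the warning preserves visibility. An
`all_nodes` option widens the set to every node of every level (30 subbands,
179 features).

## Base learners

All learners share one contract: a fitted model predicts a label and scores
a query with a nonnegative per-class vector summing to 1 whose argmax equals
the prediction; every tie anywhere (votes, posteriors, leaf majorities)
resolves to the smallest class index in the fixed order Normal < Myopathy <
Neuropathy.

**Gain-ratio tree.** Binary splits on continuous features at midpoint
thresholds. At each node every candidate feature contributes its best
threshold by weighted information gain; among features whose gain is at
least the mean candidate gain, the split with the highest gain ratio (gain
divided by the split entropy) wins. Growth stops at purity, exhausted
splits, or the configured depth/leaf limits; trees are unpruned by default.
Instance weights enter the entropies directly. Categorical multiway splits
and the MDL numeric-split correction of full C4.5 are out of scope. The
split search is compiled (C++), with an exhaustive-enumeration oracle in the
test suite.

**Random tree / random forest.** The random tree draws a fresh uniform
feature subset (default $\lceil\sqrt d\,\rceil$) at every node; the forest
fits `n_trees` such trees on bootstrap resamples drawn with probabilities
proportional to the instance weights and votes unweighted.

**Gaussian naive Bayes.** Weighted class priors, per-feature class-conditional
Gaussians with weighted means and variances floored at $10^{-9}$; posteriors
computed in log space.

**k-NN.** Euclidean distance, weighted vote among the k nearest. Features
are z-scored by default for k-NN and adapter learners (statistics fit on
training data only) and left raw for trees and naive Bayes, which are
scale-equivariant or per-feature anyway.

Learners that cannot consume weights (external adapters) are fit on a
deterministic weight-proportional resample (largest-remainder method), which
reduces to the identity for uniform weights. ANN and SVM are supported only
through the adapter contract; their internals are not re-implemented here.

## Committee methods

**Bagging** fits each of $T$ members on an independent bootstrap resample;
members vote with weight 1.

**AdaBoost.M1** starts from the dataset's weights (uniform by default).
After a round with weighted error $\varepsilon_t \in (0, \tfrac12)$,
correctly classified instances are multiplied by
$\beta_t = \varepsilon_t/(1-\varepsilon_t)$, weights renormalize to sum $n$,
and the member votes with $\log(1/\beta_t)$. A round with
$\varepsilon_t \ge \tfrac12$ is discarded and stops the stream (falling back
to the unweighted base model if it was the first round); $\varepsilon_t = 0$
keeps the member with the capped weight $\log(1/\beta_{\min})$,
$\beta_{\min} = 10^{-10}$, and stops. These edge rules follow the canonical
description; the multiclass variant is plain M1 — no SAMME
$\log(K-1)$ correction.

**Wagging** perturbs instance weights instead of resampling: the default
continuous-Poisson model draws $-\log U$, $U\sim\mathrm{Uniform}(0,1)$; the
Gaussian model draws $\max(0,\, 1 + \mathcal N(0, s))$ with zeros floored at
$10^{-10}$ (scale $s = 2$ by default). Weights renormalize to sum $n$.

**MultiBoosting** partitions the $T$ rounds into $\lceil\sqrt T\,\rceil$
contiguous sub-committees with block ends at $\lceil k\,T/n_{\text{sub}}\rceil$
(for $T = 10$: sizes 3, 2, 3, 2). Each sub-committee starts from fresh
wagging weights; within a block the AdaBoost update runs as above, except
that $\varepsilon \ge \tfrac12$ or $\varepsilon = 0$ ends only the block.
With one sub-committee and the noise model `"none"` the trainer reproduces
AdaBoost member by member — an equality the tests assert exactly.

Every trainer seeds the RNG once and lets member fits consume the continuing
stream, so each is a pure function of (data, spec, seed) and the degenerate
configurations above coincide bit for bit with their simpler counterparts
(a one-member committee equals the base model fit at the same seed).

## Evaluation

Stratified k-fold cross-validation (default 10) deals each class's shuffled
indices round-robin, so per-fold class counts deviate from proportionality
by at most 1; `k = n` is special-cased to leave-one-out singleton folds,
where stratification is vacuous. Out-of-fold predictions are pooled into a
single confusion matrix (micro aggregation) for the headline metrics, with
per-fold accuracies reported alongside; the choice of pooled rather than
averaged headline numbers is a documented convention, not a claim about any
external protocol.

Metrics: accuracy $100\cdot\mathrm{tr}(C)/N$; per-class one-vs-rest
precision, recall and F ($0/0$ defined as 0 with a warning);
prevalence-weighted averages across classes (the WEKA convention) for the
single reported precision/recall/F/AUC; per-class AUC from the Mann–Whitney
rank sum with half-credit for ties; Cohen's kappa
$(P_0 - P_e)/(1 - P_e)$ with $P_e = \sum_c r_c c_c / N^2$, the degenerate
$P_e = 1$ case defined as 0.

Frame-level stratification replicates the common protocol but lets frames of
one recording span training and test folds — an optimistic bias when
recordings differ systematically. A `grouping = "recording"` mode assigns
whole recordings to folds instead; it is provided and tested, not silently
substituted.

## Numerical and design choices

* Periodic extension only: the orthogonal mode with exact Parseval and
  clean dyadic coefficient counts (frame length must be divisible by
  $2^{\text{level}}$); symmetric/zero padding would break both and are not
  implemented.
* Midpoint thresholds between distinct sorted values; split acceptance
  requires strictly positive gain beyond $10^{-12}$.
* All tie-breaks deterministic (smallest class index, smallest feature
  index, smallest threshold).
* Degenerate-feature policies return 0 with warnings (see above); features
  are never NaN/Inf.
* One global pipeline seed fans out to stage seeds by fixed offsets
  (simulate +1, cross-validation +2), so stages are independently
  reproducible.
* Test problem sizes: the unit suite runs on frames of 256–2048 samples and
  datasets of tens to hundreds of instances; the end-to-end benchmark uses
  the full default configuration (51 recordings of 5 s at 20 kHz, 2448
  frames by 95 features) — sizes chosen as representative of the target
  acquisition protocol while keeping the suite quick on one CPU.

## Known limitations

* The simulator's realism limits (listed above) bound what any synthetic
  benchmark can show.
* Boosting a strong, low-bias base learner such as an unpruned random
  forest often terminates after one round with zero training error; the
  committee then equals a single forest, and boosting adds nothing. The
  gain from AdaBoost is visible with weak learners (stumps, shallow trees).
* C4.5 fidelity is partial by design: no pruning, no categorical splits,
  no MDL correction.
* No significance testing across pipeline configurations; reported metric
  differences are descriptive.
* ARFF I/O targets the feature-table schema (numeric attributes plus one
  nominal class); arbitrary ARFF files are out of scope.
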