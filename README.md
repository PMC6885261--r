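# wpemg

Wavelet-packet features and ensemble classification for electromyography
(EMG) signals.

`wpemg` is an R toolkit for the three-class electrodiagnostic decision —
**Normal**, **Myopathy**, **Neuropathy** — from single-channel EMG
recordings. It is aimed at biomedical-signal researchers who want a fully
seeded, end-to-end reference pipeline: a synthetic motor-unit action
potential (MUAP) train simulator (clinical EMG archives are rarely
redistributable), delimited-text recording I/O, wavelet-packet feature
extraction, native interpretable classifiers, committee meta-algorithms, and
a cross-validation harness with the standard metric suite.

## Method

Recordings are cut into non-overlapping rectangular frames of 2048 samples.
Each frame is decomposed by a level-4 wavelet packet transform (periodized
orthogonal filter bank, `db4` by default), giving 16 uniform terminal
subbands in frequency order. Each subband's coefficients *y₁…y_M* are
summarised by

- mean absolute value (1/M) Σ|yⱼ|
- average power (1/M) Σyⱼ²
- population standard deviation σ = √[(1/M) Σ(yⱼ − ȳ)²]
- skewness (1/M) Σ((yⱼ − ȳ)/σ)³
- raw kurtosis (1/M) Σ((yⱼ − ȳ)/σ)⁴

plus the ratio Σ|yⱼ| / Σ|zⱼ| between frequency-adjacent subbands — 16·5 +
15 = **95 features per frame**.

Feature tables are classified by a base learner — gain-ratio (C4.5-style)
decision tree, Gaussian naive Bayes, k-NN, random tree, random forest, or
any external estimator via an adapter — optionally wrapped in a committee:

- **bagging** — bootstrap resamples, equal votes;
- **AdaBoost.M1** — instance weights; after a round with weighted error ε,
  correct instances are scaled by β = ε/(1−ε) and the member votes with
  log(1/β);
- **MultiBoosting** — ⌈√T⌉ AdaBoost sub-committees, each restarted from
  random "wagging" instance weights (continuous-Poisson −log U by default).

Performance is reported from pooled out-of-fold predictions of a stratified
10-fold cross-validation: accuracy, per-class and prevalence-weighted
precision/recall/F, one-vs-rest rank-based AUC, and Cohen's kappa
K = (P₀ − P_e)/(1 − P_e).

## Worked example

```r
library(wpemg)
recs <- simulate_dataset(default_class_profiles(), n_recordings_per_class = 4,
                         config = simulation_config(duration_s = 1, seed = 7))
frames <- frame_recordings(recs, frame_length = 2048)   # 9 frames/recording
tab <- extract_features(frames, wpd_config())           # 108 x 95 features
report <- cross_validate(
  pipeline_spec(random_forest_spec(n_trees = 25), ensemble = "adaboost", T = 10),
  tab, cv_config(k_folds = 5, seed = 9))
print(report)
```

```
Accuracy: 88.89%   kappa: 0.8333   AUC: 0.9167
Weighted precision/recall/F: 0.8896 / 0.8889 / 0.8888
Confusion (rows = truth):
            predicted
true         Normal Myopathy Neuropathy
  Normal         29        0          7
  Myopathy        0       36          0
  Neuropathy     5        0         31
Per-fold accuracy (%): 87.5 85.7 85.7 90.5 95.2
```

This deliberately small run (twelve 1-second recordings) shows the
small-sample regime: myopathic frames are easy (small, polyphasic, dense
activity), while the Normal/Neuropathy boundary takes more data. The default
configuration — 17 recordings per class, 5 s at 20 kHz, 2448 frames — is run
by the pipeline commands below and scores well into the 90s.

The same pipeline is scriptable from a shell via the bundled CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "wpemg", package = "wpemg"))')" \
    run --config inst/extdata/default-config.yaml --output-dir out
```

(`simulate`, `extract` and `evaluate` also run individually; every artifact
— recordings + manifest, feature CSV/ARFF, JSON/text metric reports,
confusion CSV — lands in the output directory, and a rerun with the same
config reproduces them byte for byte.)

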