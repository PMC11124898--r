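# enose

Early detection of rotting produce with a metal-oxide (MOS) electronic nose,
under ambient-gas interference.

An electronic nose is an array of partially selective gas sensors plus
pattern recognition. Rotting tissue releases reducing volatiles (alcohols,
aldehydes, ketones, sulfides, alkanes) that raise the conductivity of heated
oxide sensors; the hard part is doing the classification *inside a storage
facility*, where class-irrelevant ambient odours inflate every sensor's
response and widen the overlap between class feature ranges.

`enose` implements the complete analysis chain for a 12-sensor array
(90 s injection + 90 s cleaning at 1 Hz, 60 s clean-air baseline window):

* **Baseline correction** to relative conductivity,
  `x_t(i) = R_air(i) / R_S(i,t)`, cancelling part of long-term drift.
* **Curve features** — per sensor: mean, max, injection area, stable-window
  mean, max/mean first difference, max second difference, and the five
  largest DFT magnitudes (DC excluded) — 144 features per sample.
* **MIME-(SVM-RFECV) feature selection**: a mutual-information filter,
  `MIME(F_i) = I(F_i,y) − α/m Σ I(F_i,F_j) − β/m Σ I(F_i,F_j|y)`,
  followed by a seeded recursive-elimination wrapper around a
  cross-validated SVM.
* **Class-overlap discretization**: each feature's range is segmented at
  class-range endpoints so pure and overlap regions get distinct tags,
  then one-hot encoded — overlap regions (where ambient redundancy lives)
  collapse to single tags.
* **Ensemble CNN**: a 144-point grid of two-conv-layer 1-D networks
  (kernel sizes {3,5,7,9}/{3,5,7}, stride 2, dense (n,200),(200,3) head),
  the grid optimum plus its 9 nearest neighbours as base classifiers, and a
  small convolutional meta-network fusing their 30 concatenated class
  probabilities.
* **Evaluation harness**: stratified 60/10/30 splits (180/30/90 at the
  study size of 300 samples), 5 seeded repeats, SVM/LR/KNN/single-CNN
  baselines, raw-vs-discretized comparison, confusion matrices.

No dataset of this kind is public, so the package includes a **synthetic
simulator** with saturating-exponential adsorption/desorption kinetics,
class peak amplitudes anchored to the published response characteristics of
such an array, and a common-mode lognormal ambient-interference model that
makes the storage environment genuinely harder than the laboratory. The
whole pipeline is testable end to end without any download.

## Worked example

Simulate a storage-facility study (300 samples, 3 balanced classes), select
features on the first training split, then compare classifiers with and
without discretization over 5 repeated splits:

```r
library(enose)

env  <- environment_config("storage")
recs <- simulate_dataset(100, env, seed = 42)
tab  <- extract_features(recs)              # 300 x 144 feature table

split <- stratified_split(tab$label, substream_seed(42, "repeat-1"))
norm  <- fit_normalizer(tab[split$train, ])
tn    <- apply_normalizer(tab, norm)
sel   <- select_features(tn[split$train, ],
                         cfg = selection_config(min_features = 12,
                                                seed = substream_seed(42, "selection")))

tsel <- tab[c("sample_id", "label", "environment", sel$selected)]
tcfg <- train_config(learning_rate = 0.01, epochs = 150)
ecfg <- ecnn_config(optimal_spec = list(k1 = 3, c1 = 16, k2 = 3, c2 = 32),
                    train_cfg = tcfg)
report <- run_experiment(tsel, models = c("svm", "lr", "knn", "cnn", "ecnn"),
                         conditions = c("raw", "discretized"),
                         n_repeats = 5, seed = 42,
                         ecnn_cfg = ecfg, train_cfg = tcfg)
print(report)
```

```
E-nose evaluation ( 5 repeats )
  svm   | raw         68.67 +/- 1.65 | discretized 82.00 +/- 2.65 | delta +13.33
  lr    | raw         75.11 +/- 5.13 | discretized 84.00 +/- 3.30 | delta +8.89
  knn   | raw         78.00 +/- 3.37 | discretized 81.33 +/- 1.99 | delta +3.33
  cnn   | raw         80.89 +/- 2.88 | discretized 83.11 +/- 3.96 | delta +2.22
  ecnn  | raw         82.44 +/- 0.93 | discretized 82.67 +/- 2.90 | delta +0.22
```

Read: mean test accuracy (%) ± sd over the 5 repeats, per feature
condition; `delta` is the accuracy change from discretization. In the noisy
storage environment every model gains from discretization, the ensemble CNN
is the strongest raw-feature model, and the same pipeline on laboratory-mode
data (`environment_config("laboratory")`) classifies near-perfectly (~99.8%
across models). Storage data also shows a much larger mean inter-class
range-overlap fraction than laboratory data (`class_overlap_fraction`),
which is exactly what the discretizer segments on.

## Command line

A thin CLI over the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/enose.R simulate  --env storage --n-per-class 100 --seed 1 --out runs/sim
Rscript inst/cli/enose.R featurize --in runs/sim --out runs/features.csv
Rscript inst/cli/enose.R evaluate  --in runs/features.csv --seed 1 --out runs/report.json
Rscript inst/cli/enose.R pipeline  --env storage --seed 1 --out runs/full
```

## Method vignette

`vignettes/enose-methods.Rmd` documents the model and its assumptions, the
simulator's calibration and what it does and does not emulate, estimator
conventions, and the design decisions (stacking mode, discretization
boundaries, selection floor) in detail.
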