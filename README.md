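# autoqc — reconstruction-based quality control for high-throughput microscopy

High-throughput microscopy produces more frames than anyone can inspect, and
the failure modes are diverse: air bubbles, dust artifacts, axial defocus
(Z-shift), illumination defects, contamination. `autoqc` flags problematic
frames **without any labelled examples of failures**: a reconstruction model
is trained only on curated normal images; at test time, frames the model
cannot reconstruct faithfully are flagged, and the per-pixel reconstruction
error localizes the problem.

The core quantity is the anomaly score map

Λ = L_test(x, x̂),  x̂ = f_θ(x′),

the per-pixel error between a frame `x` and its reconstruction `x̂` from a
corrupted version `x′`. An image-level anomaly score AS aggregates Λ (max,
mean, or max of sliding-patch means); a frame raises an alarm iff
AS > AS\*, and alarmed frames get a localization mask Λ > λ\*. Both
thresholds are fitted on a small labelled validation split (AS\* by exact
accuracy scan, λ\* by a Dice-maximizing quantile grid search).

Five model families implement the same `reconstruct()` contract:

| model     | idea |
|-----------|------|
| `ae`      | convolutional denoising autoencoder, p-norm loss |
| `vae`     | variational AE, posterior-mean inference, weighted KL term |
| `fanogan` | WGAN-GP generator/critic + encoder trained with the izi_f loss |
| `ddpm`    | diffusion denoiser predicting the clean image x₀ directly, one evaluation at a fixed timestep t_test |
| `pddpm`   | patch-conditioned diffusion: noise one patch, keep clean context, merge sliding-patch reconstructions |

A synthetic benchmark generator (brightfield-like scenes of sparse dark
cells, five injectable anomaly classes with exact ground-truth masks) makes
the whole pipeline testable end-to-end with no external data, and a
curation mode ranks an unlabeled pool by anomaly confidence for dataset
cleaning.

## Worked example

```r
library(autoqc)

# 1. a seeded synthetic benchmark: 32 training normals, 16 normal and
#    10 abnormal test frames (2 per anomaly class), plus a validation split
man <- make_benchmark("bench", n_train = 32, n_pos = 16,
                      n_neg_per_kind = 2, base_seed = 1)

# 2. train the pDDPM and the AE baseline on the normals, fit thresholds on
#    the validation split, evaluate on the test split
res <- benchmark_study(man, models = c("ae", "pddpm"), seed = 1)
res$table
#>   method       acc     auc      dice     auprc
#> 1     ae 0.7307692 0.68125 0.4226064 0.5376748
#> 2  pddpm 0.8846154 0.80000 0.5247530 0.7212421
```

Reading the pDDPM row: at the alarm threshold fitted on the validation
split, 23 of 26 test frames are classified correctly (ACC 0.88); ranking
frames by raw anomaly score separates normal from abnormal with AUROC
0.80 — eight of the ten anomalous frames (bubbles, dust, contamination,
illumination) score above every normal frame, while the two defocused
frames score *below* the normal band (blur removes reconstructible image
energy; see the vignette's limitations). The predicted masks overlap the
ground truth with mean Dice 0.52, and the pooled pixel-level
precision-recall area is 0.72. The AE baseline trails on every metric.

Individual frames are inspected with the two-stage alarm workflow:

```r
model <- res$models$pddpm
m <- anomaly_map(model, load_image(man$test_negative$image[1]))
decision <- classify(m, res$thresholds$pddpm)
decision$is_abnormal   # alarm flag; decision$mask holds the localization
```

`rank_pool()` scores an unlabeled image pool and returns it
most-abnormal-first — the workflow used to curate large uncurated
collections before training downstream models.

A thin command-line front end wraps these functions:

```sh
Rscript inst/cli/autoqc.R make-benchmark --out bench --seed 11
Rscript inst/cli/autoqc.R train --model pddpm --data bench --out pddpm.ckpt
Rscript inst/cli/autoqc.R fit-thresholds --ckpt pddpm.ckpt --data bench --out th.yaml
Rscript inst/cli/autoqc.R evaluate --ckpt pddpm.ckpt --manifest bench --thresholds th.yaml --out report.json
Rscript inst/cli/autoqc.R rank --ckpt pddpm.ckpt --pool unlabeled/ --out ranked.csv
```

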