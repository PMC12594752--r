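---
title: "Reconstruction-based quality control for microscopy: models, scores and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction-based quality control for microscopy: models, scores and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

High-throughput microscopy (multi-well time-lapse assays, large screening
campaigns) produces image volumes far beyond what manual quality control can
cover, and the failure modes are diverse: air bubbles introduced during
pipetting, dust in the light path, axial defocus ("Z-shift"), mis-calibrated
or uneven illumination, and biological contamination. Supervised artifact
classifiers require labelled examples of each failure mode and miss the ones
nobody anticipated.

`autoqc` takes the unsupervised, reconstruction-based route. A model
$f_\theta$ is trained **only on curated normal images** to reconstruct a
clean image $x$ from a corrupted version $x'$:

$$\min_\theta \frac{1}{N}\sum_i L_{\mathrm{train}}\!\left(x_i,\hat x_i\right),
\qquad \hat x_i = f_\theta(x_i').$$

At test time the model reconstructs every incoming frame. A frame the model
has "seen the likes of" is reconstructed faithfully; an abnormal frame is
reconstructed *as if it were normal*, because normal data is all the model
knows. The pixel-wise anomaly score map is the reconstruction error

$$\Lambda = L_{\mathrm{test}}(x, \hat x),$$

by default the absolute per-pixel error (`score_map()`), and large values
flag likely-abnormal pixels without any prior knowledge of the failure mode.

## From score maps to decisions

Three aggregators turn $\Lambda$ into a scalar anomaly score
(`aggregate_score()`): the maximum, the mean, and the *patch maximum* — the
maximum over sliding-window patch means, which trades off the max's
sensitivity to single-pixel noise against the mean's dilution of small
anomalies. Patch windows slide with a configurable stride and the final
window along each axis is edge-aligned so every pixel is covered.

Decision thresholds are learned on a small labelled validation split, as a
practitioner would do:

* **AS\*** (`fit_as_threshold()`): a greedy scan over candidate thresholds —
  midpoints between consecutive sorted unique validation scores plus the
  extremes; accuracy can only change at data points, so this scan is exact.
  The alarm rule is strict: a frame is flagged iff $AS > AS^*$. Ties are
  broken toward the smaller threshold (favour sensitivity).
* **λ\*** (`fit_lambda_threshold()`): a grid search maximizing the mean Dice
  coefficient of $\Lambda > \lambda$ against the validation masks, over 200
  evenly spaced quantiles of the pooled score values (the quantile grid
  adapts to the score scale of whichever model produced the maps). Ties are
  broken toward the larger threshold (favour specificity). Dice of an empty
  prediction against an empty mask is defined as 1, against a non-empty mask
  as 0.

`classify()` implements the two-stage workflow: alarm first, and only for
alarmed frames a binarized localization mask (`binarize()`, strict
inequality).

## Model families

All five families implement one contract — `reconstruct(model, image)`
returns a same-shape image in $[0,1]$, deterministically (stochastic
encoders use their posterior mean; diffusion models draw corruption noise
from a fixed seed).

* **AE** — convolutional encoder/decoder with a `latent_dim`-dimensional
  bottleneck, trained on the mean per-pixel $p$-norm error (default $p=1$,
  which is robust to fine cell texture). Training inputs are corrupted with
  additive Gaussian noise (`corruption_noise_sigma`, default 0.1); the
  target stays clean. Setting the corruption to 0 recovers plain
  autoencoding.
* **VAE** — the encoder emits $\mu_\phi(x)$ and $\sigma^2_\phi(x)$
  (variance through an exponential map, so positivity is structural); the
  loss adds `kl_weight` times the closed-form diagonal-Gaussian KL
  divergence to the standard-normal prior. Inference decodes the posterior
  mean, keeping score maps deterministic.
* **f-AnoGAN** — a WGAN with gradient penalty (critic updated
  `critic_steps` times per generator update, penalty weight `gp_weight`)
  fitted on normal images, followed by an encoder trained with generator
  and critic frozen under the izi_f loss
  $\frac1n\|x-G(E(x))\|^2+\frac{\kappa}{n_d}\|f(x)-f(G(E(x)))\|^2$, where
  $f(\cdot)$ is the critic's penultimate activation.
* **DDPM** — the forward process corrupts in the model's internal
  $[-1,1]$ frame via
  $x_t=\sqrt{\bar\alpha_t}\,x_0+\sqrt{1-\bar\alpha_t}\,\epsilon$
  (`forward_diffuse()`); a U-Net denoiser $f_\theta(x_t,t)$ is trained to
  predict the **clean image directly** (not the noise) with
  $t\sim\mathcal U(1,T)$. Reconstruction is a *single* denoiser evaluation
  at one fixed timestep `t_test` — no iterative sampling chain — which
  makes screening-scale deployment practical.
* **pDDPM** — the patch-conditioned variant: during training one random
  patch per sample is noised while the surrounding context stays clean (the
  network also receives a noised-region indicator channel); the loss
  applies on the patch. At inference a patch grid slides over the image
  (edge-aligned final rows/columns), each patch is noised at `t_test` and
  denoised with clean context, and overlapping patch predictions are merged
  by unweighted per-pixel averaging — the simplest merge that maps a
  constant denoiser to a constant reconstruction and is invariant to patch
  visit order.

### Network scale

No architecture is canonical for this problem class, so the package uses
deliberately small networks sized for a single CPU: two
down/up-sampling levels at base width 16 for the AE/VAE/encoder and
generator, a U-Net with two pooling levels (widths 16/32, sinusoidal
timestep embeddings projected to per-channel biases at each level) for the
diffusion models, and an MLP critic for f-AnoGAN. The MLP critic is a
deliberate choice: for piecewise-linear dense networks the gradient-penalty
term admits an exact closed-form parameter gradient (the activation's
second derivative vanishes almost everywhere), so WGAN-GP training needs no
automatic double differentiation. All widths and depths are configurable
through `train_config()`; the gradient implementations are verified against
central finite differences in the test suite.

### Noise-schedule scaling

The conventional linear schedule ramps $\beta$ from $10^{-4}$ to
$2\times10^{-2}$ over $T=1000$ steps. `noise_schedule()` keeps those
endpoint semantics but defines them on a `reference_steps = 1000` grid and
scales $\beta$ by `reference_steps / n_steps` (capped below 1) when a
shorter schedule is requested. The cumulative signal level $\bar\alpha$ at
a given fraction $t/T$ is then approximately independent of $T$: a
$T=100$ desk-scale schedule corrupts like the reference schedule rather
than like a 10× milder one. Without this compensation a short schedule
leaves so much signal at `t_test = T/2` that the denoiser can copy a
degraded input straight through the noise, which blunts anomaly response.
`t_test` defaults to $T/2$ and is exposed in `diffusion_config()`, as are
the patch size and stride (defaults: half the image side, half the patch).
Because no single timestep suits every data regime, `benchmark_study()`
additionally selects `t_test` by validation AUROC over the a-priori grid
$T \cdot \{1/8, 1/4, 1/2, 3/4\}$ (`select_t_test()`); only validation
data informs the choice.

## The synthetic benchmark

`make_benchmark()` emulates the situation the package targets — brightfield
fields of sparse dark cells on a bright background — so the whole pipeline
is testable without any external data. Normal scenes
(`generate_normal()`) place non-overlapping dark ellipses (radii 2–5 px,
random orientation) on a bright background (level 0.75, cell darkness
0.35) with sigmoidal edge profiles and additive Gaussian camera noise
(sd 0.02); a polarity flag produces fluorescence-like scenes (dark
background, bright blobs) for curation-style workflows. Identical scene
specifications (including the seed) are bit-identical.

Five anomaly injectors (`inject_anomaly()`) mirror the common failure
modes, each with an exact ground-truth mask and a severity in $(0,1]$ that
scales the perturbation monotonically and vanishes as severity approaches
zero:

* *air bubble* — dark refraction ring with a brightened interior disc;
* *artifact* — 1–3 small dark high-contrast blobs or streaks (dust);
* *Z-shift* — global Gaussian blur, std $= 4 \times$ severity px (severities
  0.125–1 span the 0.5–4 px range typical of visible defocus);
* *illumination* — global gain, linear ramp, or radial vignette;
* *contamination* — soft-edged bright Gaussian spots, truncated to exactly
  zero beyond 3 sd so the mask is exact.

Localized anomalies leave every pixel outside their mask bit-identical.
Whole-frame degradations (Z-shift, illumination) carry all-ones masks:
defocus has no localizable boundary, and real-world masks of such defects
are rough delineations at best. Benchmark severities are drawn uniformly
from $[0.5, 1]$ — clearly visible defects, matching how reference QC sets
are assembled; anomalies are injected one per image, matching per-type
benchmark categorization.

What the generator does **not** emulate: physically accurate optics (no
PSF model, no refraction ray-tracing), cell motion, sensor-specific noise
statistics, or the long-tailed variability of real biology. Passing the
bundled end-to-end tests therefore demonstrates that the machinery works
and ranks model families sensibly at desk scale — not that any particular
metric value will transfer to a given microscope.

## Evaluation protocol

`evaluate_method()` reports the four benchmark metrics: classification
accuracy at AS\* and AUROC (rank-based, ties counted ½) over all test
frames with "abnormal" as the positive class; mean Dice at λ\* and pixel
AUPRC over the abnormal test frames only, where ground-truth masks exist.
AUPRC uses step-wise summation over distinct thresholds (linear
interpolation between PR points inflates the area) and pools pixels across
images by default (`auprc_mode = "per_image"` averages instead). Dice is
computed at the single fitted λ\*, consistent with a deployed two-stage
workflow, not as a best-threshold-per-image oracle.

## Numerical and edge-case conventions

* Strict `>` everywhere a threshold is compared (alarm and binarization).
* AS\* ties → smaller threshold; λ\* ties → larger threshold.
* Dice 0/0 → 1; empty-vs-non-empty → 0.
* Scores are non-negative by construction; score maps are reported in the
  canonical $[0,1]$ intensity frame even though diffusion internals use
  $[-1,1]$.
* Integer images are normalized by the dtype maximum (255 / 65535); float
  images are min-max scaled per image, which removes absolute-intensity
  information — a caveat when absolute exposure is itself the signal of
  interest.
* One seed in `train_config()` controls weight initialization, data order
  and corruption noise; equal seed and configuration reproduce equal
  weights. Inference-time corruption noise in the diffusion models is
  seeded separately (default: the model's training seed).
* Cells that cannot be placed without overlap after 200 retries, geometry
  outside the frame, non-finite training losses, and single-class
  threshold-fitting inputs all raise immediate errors rather than degrade
  silently.

## Problem sizes used in the bundled studies

The package's own end-to-end study (also what `scripts/acceptance.R`
reruns) uses 64×64 scenes: 32 training normals, 16 positive and 10
negative test frames (2 per anomaly class), a validation split of 8
normals plus 1 abnormal per class, a $T=100$ schedule, the default 32 px
patch grid with stride 16 for the pDDPM, 100 training epochs for the
diffusion models and 60 for the baselines, and `t_test` selected on the
validation split. These sizes were chosen so the full study trains and
evaluates in minutes on one CPU while still exercising every stage; unit
tests use 32×32 scenes and smaller networks. With more compute, all of
the same entry points scale to larger images, deeper networks and longer
schedules unchanged.

## Known limitations

* Smoothing-type degradations (defocus) remove exactly the image energy —
  sensor noise and sharp cell edges — that sets a reconstruction-error
  detector's baseline on normal frames. On the synthetic benchmark this
  makes defocused frames score *below* the normal band rather than above
  it, at every timestep, patch size and training length we measured: a
  one-sided anomaly score cannot flag an anomaly whose effect is to make
  images easier to reconstruct. This is the dominant error mode of the
  desk-scale study (the other four anomaly classes separate perfectly
  from the normals) and is intrinsic to raw reconstruction error, not to
  a particular model; production QC pipelines pair such detectors with a
  dedicated focus metric, which is out of scope here.
* The f-AnoGAN family reconstructs through the generator's range, which
  on tiny training sets has a fidelity floor of its own (mean absolute
  error around 0.08 on a 3-image set even when the latent code is
  optimized directly against the frozen generator); GAN training is also
  non-monotone in its step count. Its reconstructions are therefore
  coarser than the autoencoders', as reflected in the test suite's
  model-specific tolerance.
* Whole-frame anomalies make pixel-level Dice coarse (the mask is the
  entire frame), so λ\* trades off global against localized classes.
* The curation mode ranks; it does not label. Its output is a reading
  order for a human curator, not a decision.
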