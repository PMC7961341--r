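---
title: "Subject-generalized EEG emotion models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subject-generalized EEG emotion models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Emotion classifiers trained on multichannel EEG tend to learn the *subject*,
not the emotion: between-subject variability (skull geometry, electrode
placement, idiosyncratic band-power distributions) is far larger than the
within-subject differences between emotional states. A model fit on a pool
of subjects then performs near chance on a person it has never seen. This
package implements a bilateral variational domain-adversarial network — a
model that attacks this problem with two complementary regularizers on a
shared emotion-classification backbone — together with the full spectral
preprocessing pipeline, a synthetic multi-subject generator, and the
leave-one-subject-out (LOSO) evaluation protocol.

## From raw EEG to hemispheric images

1. **Windowing.** Labeled trials are cut into 15 s windows with 50%
   overlap (`sliding_windows()`); labels apply to whole trials and are
   inherited by every window. Trailing partial windows are dropped so every
   network input has identical shape; window starts are snapped down to
   integer sample indices.
2. **Band power.** Each window's per-channel power spectral density is
   estimated with DPSS (multitaper) tapers — time half-bandwidth 2.5, four
   tapers, so at least three well-concentrated tapers fit a 15 s window —
   and summarized as the mean PSD over the alpha (8–13 Hz), beta
   (13–30 Hz) and gamma (30–50 Hz) bands (`band_power()`). The tapers come
   from the standard symmetric tridiagonal eigenproblem and are cached per
   window length.
3. **Topographs.** Band powers are interpolated over a unit head disc
   (thin-plate spline with an affine term: exact at electrodes, reproduces
   constant and linear fields; pixels outside the disc are 0) on a 64×64
   grid, then each band is min–max scaled to 0–255 *per band, per sample*
   and rounded (ties away from zero). Per-sample scaling makes every image
   self-normalized, which is the sense in which the encoding "acts as
   normalization"; it also means absolute power levels are deliberately
   discarded. A constant band encodes to all zeros.
4. **Hemisphere split.** The image is cut at the vertical midline into a
   3×64×32 left and right half (`split_hemispheres()`); concatenation
   restores the original exactly. Midline electrodes are not duplicated.

The electrode montage is an azimuthal-equidistant projection of idealized
10–10 spherical angles (`standard_montage()`), with the outer 10–20 ring at
radius 0.9 of the unit disc.

## The model

Each hemisphere image (scaled to [0,1]) enters its **own** convolutional
variational encoder: three strided 3×3 convolution + batch-norm stages, a
dense stage, and two dense heads producing the posterior mean and
log-variance of a J-dimensional Gaussian code (J = 64 by default). Sampling
uses the reparameterization `z = mu + exp(log_var/2) * eps`. Mirrored
transposed-convolution decoders (exact adjoints of the encoder
convolutions) reconstruct the input; the reconstruction loss is mean
squared error per pixel, and the KL divergence from the standard-normal
prior is weighted by a coefficient beta that ramps linearly from 0 (100
epochs by default).

The two latent codes are stacked as a 2×J one-channel map — the only shape
on which 2×2 convolutions can mix hemispheres — and passed through two 2×2
convolution stages plus two dense stages into the 128-dimensional bilateral
embedding. An emotion classifier (dense 256–256–64 + softmax) and a subject
discriminator (gradient reversal + the same stack) share that embedding.
The gradient-reversal layer is the identity forward; during backpropagation
it multiplies the discriminator's upstream gradient by −lambda, so the
shared layers are trained to *resist* subject classification while the
discriminator itself is trained to succeed. Lambda ramps linearly (50
epochs by default).

The combined objective is

    L = recon_l + beta*KL_l + recon_r + beta*KL_r + L_emotion - lambda*L_subject

whose saddle-point structure (minimize over encoders/decoders/extractor/
classifier, maximize over the discriminator) is realized by the interleaved
updates below.

### Interleaved training

Per batch, three updates in fixed order:

1. **Reconstruction step** — encoders and decoders on
   `recon + beta*KL` (labels untouched);
2. **Discriminator step** — the discriminator alone on the subject
   cross-entropy, with the shared path frozen;
3. **Adversarial classification step** — encoders, extractor and classifier
   on `L_emotion - lambda*L_subject`, the subject term flowing through the
   gradient-reversal contract.

Inside the training loop steps 2–3 share one forward pass of the frozen
shared path (arithmetically identical, since step 2 cannot modify it). A
stratified validation split (15% by default, jointly stratified by subject
and class) drives early stopping on emotion validation accuracy; among
epochs tied at the best accuracy the *latest* checkpoint is kept, because
on easy data the accuracy saturates long before the regularizers have
finished shaping the embedding. Unsupervised VAE pretraining
(`pretrain_vaes()`) is available as a warm start and uses the same beta
ramp.

Two stabilization knobs are exposed, both defaulting to 1 (plain single-rate updates):
`disc_lr_mult` (a two-time-scale update — the discriminator trains with a
larger learning rate than the shared path) and `disc_steps` (inner
discriminator iterations per batch). Without them the discriminator in
small-scale runs collapses into permanent confusion, after which the
reversed gradient carries no information; the adversarial formulation
itself anticipates tuning the adversary when the embedding is not
sufficiently domain-invariant.

### Ablation variants

`make_variant()` maps names to component switches: **BiCNN** (classifier
path only), **BiVAE** (+ variational regularizer), **BiDANN**
(+ discriminator, no KL), **L-/R-VDANN** (single-hemisphere input on a 1×J
map), **BiVDANN** (everything). Variants without the variational
regularizer use deterministic embeddings (no latent sampling) — with no KL
anchor, free-scale sampling noise only destabilizes training.

## Numerical and implementation choices

- The network engine is compiled (RcppArmadillo), single precision, with
  transposed convolutions implemented as exact adjoints of the forward
  convolutions ("same" padding, extra pad on the bottom/right). Batch
  normalization uses per-batch statistics in training and running averages
  (momentum 0.9) at evaluation; buffers are only updated by the step that
  trains the owning component.
- The decoder's output activation is a rational softsign-based squash
  `0.5*(1 + u/(1+|u|))`, `u = x/2` — bounded to (0,1) with the logistic
  slope at 0 — chosen over the logistic because it vectorizes on baseline
  SIMD targets where scalar `exp` dominated the training profile.
- The posterior log-variance head is initialized at −3 (sigma ≈ 0.22) so
  early latent samples are informative rather than pure noise; the KL term
  pulls sigma toward 1 as beta ramps.
- Cross-entropy clamps the selected probability at 1e-12. All randomness
  (weight init, shuffling, latent draws) flows from one integer seed
  through a private generator, so a (seed, config, data) triple reproduces
  training bitwise on one machine.
- `arch_config(pool = k)` inserts a fixed average-pooling stem (and a
  mirrored nearest-neighbour upsampling output stage), letting scaled-down
  configurations run the convolution pyramid on reduced maps without
  changing the input/output contracts. Inside the training loop pooled
  data are precomputed once and reconstruction is penalized at the pooled
  resolution — the upsampled gradient is identical up to the constant
  block-size factor.
- At inference `z := mu`, batch-norm uses running statistics, and
  predictions are deterministic.
- A joint (non-interleaved) optimization mode was considered and not
  shipped: interleaving is the procedure under study, and an unexercised
  joint path would be dead code.

## The synthetic generator

`generate_topographs()` emulates exactly the structure that makes
cross-subject EEG emotion recognition hard:

- a **subject-invariant, class-dependent lateralized alpha effect**: a fixed
  left–right antisymmetric fronto-temporal template added to the alpha band
  with a sign/magnitude per class (`class_effect`) — the synthetic stand-in
  for lateralized emotional processing;
- **strong subject offsets**: per subject and band, a smooth random field
  (low-order cosine harmonics, unit variance over the disc) scaled by
  `subject_effect`, drawn once and added to every sample of that subject;
- **pixel noise** (`noise_sd`), plus a shared smooth baseline per band.

`subject_effect / class_effect` (`effect_ratio()`) is the single
identifiability dial: at 0 an unregularized classifier generalizes across
subjects; as it grows, subject offsets dominate the per-sample min–max
normalization and an unregularized model's held-out-subject accuracy
degrades toward chance while its embeddings cluster by subject.

Defaults (8 subjects, 2 classes, 200 samples per subject, class effect 1,
subject effect 2, noise 1.0) were fixed so that the within-subject task is
solvable but an unregularized bilateral CNN generalizes poorly across
subjects — the regime the method targets. `generate_eeg()` produces the
same decomposition as band-limited sinusoid amplitudes at the electrode
positions, so the complete windowing → multitaper → interpolation pipeline
reproduces the designed band-power structure end to end.

What the generator does **not** emulate: 1/f spectra, artifacts (EMG/EOG),
nonstationarity within trials, inter-session variability, or label noise.
Passing the scaled-down experiments therefore demonstrates that the
machinery behaves as designed under the stated effect structure — not that
any particular accuracy will be attained on a real request-access dataset.

## Evaluation protocol

`run_loso()` trains one model per fold (all samples of one subject held
out), with the validation split carved from the training subjects only —
anything else would leak the test domain. Per-subject accuracies are
aggregated as mean and standard deviation *across subjects*.
`embedding_report()` extracts deterministic embeddings, fits a post-hoc
multinomial linear probe on subject identity (its own 70/30 split of the
frozen embeddings; linear, because it measures linearly decodable subject
information — the quantity the usual t-SNE/MDS cluster plots show
qualitatively), and runs per-dimension one-sample Kolmogorov–Smirnov tests
against a Gaussian with that dimension's sample mean and sd (the
estimated-parameter caveat applies; the fraction of rejections at
alpha = 0.05 is a comparative, not calibrated, measure of normality).
Embeddings are exported as plain CSV for external visualization tools.

## Scaled-down experiment configuration

The package's reference experiment (used by the acceptance suite and
`scripts/acceptance.R`) runs the generator defaults through a reduced
architecture chosen once for a single-CPU budget: latent 16, conv channels
(4, 8, 8), dense 64, bilateral embedding 8, heads (32, 32, 16), pooling
stem 2, batch 64, 60 epochs, Adam 1e-3, beta plateau 0.05 with a 40-epoch
ramp, lambda plateau 1.5 with a 20-epoch ramp (the default 100/50-epoch ramps
rescaled to a 60-epoch budget), `disc_lr_mult = 5`, `disc_steps = 10`
(`experiment_arch()`, `experiment_config()`). The bilateral embedding is
kept narrow on purpose: inactive embedding dimensions are where residual
subject information accumulates (see the limitations below), and beta is
small because the reconstruction loss is a per-pixel mean — on that scaling
a KL weight of 1 corresponds to a far stronger bottleneck than in the
summed-loss convention and collapses the posterior.

## Known limitations

- The subject probe on scaled-down adversarial models remains well above
  chance even when the discriminator itself is at chance: diagnostic
  decompositions show the *class direction* of the embedding is essentially
  subject-clean, while inactive residual dimensions — which batch
  normalization keeps at unit variance — retain subject information that
  the reversed gradient fails to remove once the discriminator is confused.
  This is a known failure mode of gradient-reversal training; the package
  reports it honestly rather than switching to a different (non-reversal)
  invariance penalty.
- Multitaper bandwidth, montage angles and interpolation are reasonable
  conventional choices, not fitted to any particular acquisition system.
- Bitwise reproducibility holds per machine/BLAS, not across platforms.
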