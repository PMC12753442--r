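---
title: "Methods: multi-modal contrastive fusion for lymph-node metastasis prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-modal contrastive fusion for lymph-node metastasis prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The prediction problem

Nodal status in cervical cancer is established surgically, yet fewer than a
fifth of early-stage patients are node-positive. `lnmfusion` implements a
preoperative predictor that consumes three routinely available inputs per
patient — one CT-like grayscale image, one ultrasound-like grayscale image,
and a vector of laboratory indicators — and outputs a probability of
lymph-node metastasis. The statistical setting is unforgiving: cohorts are
small (the motivating cohort has 127 patients) and heavily imbalanced
(~12.6% positive), so the design leans on three mitigations: transferable
encoders, an auxiliary contrastive objective that aligns modalities patient
by patient, and class-balanced mini-batch sampling.

## Model and objective

Each modality has its own encoder producing a D = 512 representation:

* **Images.** A residual convolutional backbone ending in global average
  pooling. In fidelity mode this is an 18-layer ResNet-style network (7×7/2
  stem, 3×3/2 max-pool, four stages of two residual blocks at widths
  64/128/256/512) consuming 224 px inputs, whose pooled width is already
  512. For CPU-scale work a reduced-depth variant is provided (3×3/2 stem at
  width 8, two residual blocks at widths 16 and 32, then a linear map to
  512) consuming 32–64 px inputs. Grayscale inputs are replicated to the
  backbone's channel count, the convention that keeps the architecture
  compatible with three-channel pretrained weights.
* **Clinical vector.** Two affine layers `F -> 256 -> 512` with a rectifier
  between them and none after the second, since the output feeds both the
  projection head and the linear classifier and clamping it to the positive
  orthant there would discard half the space.

Projection heads (`512 -> 256 -> 128`, rectifier between) map each
representation into the contrastive space. For an ordered pair of modalities
(a, b) and batch row i, with cosine similarity and temperature τ,

$$\mathcal{L}(Z_a^{(i)}, Z_b^{(i)}) = -\log
  \frac{\exp(\mathrm{sim}(Z_a^{(i)}, Z_b^{(i)})/\tau)}
       {\sum_{j \ne i} \exp(\mathrm{sim}(Z_a^{(i)}, Z_b^{(j)})/\tau)}$$

and the combined term averages the three ordered pairs CT→clinical,
US→clinical, CT→US. The fused representation is the concatenation
`[H_ct || H_us || H_clin]` (width 3D = 1536) passed through a single affine
layer to two class scores; the training objective is exactly
`cross-entropy + contrastive`, and the equality is asserted at every
optimization step and in the per-epoch logs.

### The InfoNCE denominator

The loss above excludes the positive pair from its normalizing sum (the sum
runs over j ≠ i). This is the package default because it is the literal form
of the source formulation; the more common convention that includes the
positive term is available via
`contrastive_config(include_positive_in_denominator = TRUE)`. The two differ
by a bounded monotone reparameterization of the per-anchor loss — notably
the literal form can go negative (its closed-form value for a two-sample
batch with positive similarity 1 and cross similarity −1 is −2) while the
conventional form is non-negative. Both modes are tested against a
double-loop oracle. A symmetrized variant ((a→b) + (b→a))/2 per pair exists
behind `symmetrize = TRUE`, default off; within-modality negatives are never
used. These choices are flagged rather than guessed because the available
description does not settle them.

## Training protocol

* **Split:** stratified 80/10/10. Sizes follow round-half-up of 0.8n (train)
  and 0.1n (test) with validation taking the remainder — for n = 127 this
  gives 102/12/13 — and classes are apportioned to splits by largest
  remainder, with one positive forced into validation and test whenever the
  class can afford it. Stratification is the package's own default (a plain
  random 10% split of 16 positives is empty of positives about a quarter of
  the time, leaving sensitivity undefined); `stratified = FALSE` restores
  the unstratified behavior.
* **Sampling:** inverse-class-frequency weights, drawn with replacement, so
  each batch of 8 is class-balanced in expectation. The 1:1 target is a
  design choice; the source protocol states only that underrepresented
  classes are upweighted.
* **Optimizer:** Adam at lr 1e-3 (β₁ = 0.9, β₂ = 0.999, no weight decay),
  cosine-annealed to zero over the configured epochs (30 by default), no
  restarts. Moment defaults and zero decay are conventional fill-ins.
* **Checkpointing:** validation accuracy is computed each epoch in
  evaluation mode (center crop, batch-norm running statistics); the weights
  from the earliest epoch attaining the maximum are returned.
* **Augmentation:** random crop with area fraction uniform on (0.7, 1.0)
  (aspect preserved, location uniform, sides rounded up to whole pixels)
  followed by bilinear resize to the encoder side; evaluation uses the full
  image. The crop range is exposed in `encoder_config()` because the source
  protocol names random cropping without parameters.
* **Normalization:** clinical features are min-max scaled to [0,1] with
  bounds fitted on the training split only; held-out values are clipped.
  Constant features map to 0. Fitting on the whole cohort would leak split
  information into the encoder input.

The default clinical feature vector has 12 entries: the eight raw
indicators (age, SCC-Ag, CA125, CA19-9, neutrophils, lymphocytes, platelets,
albumin) plus the four derived indices (NLR, PLR, SII, PNI). FIGO stage is
excluded by default: in cohorts of this kind its association with nodal
status is near-deterministic, and including it collapses the prediction task
to reading the stage. It can be added via
`clinical_feature_names(include_stage = TRUE)`.

### Derived indices

NLR = neutrophils/lymphocytes, PLR = platelets/lymphocytes,
SII = platelets × neutrophils / lymphocytes (all counts in 10⁹/L), and
PNI = albumin (g/L) + 5 × lymphocytes. The PNI multiplier defaults to the
conventional 5: published baseline values near 50 with albumin near 42 are
consistent only with that form, although the index is sometimes printed as a
plain sum; `pni_multiplier = 1` gives the literal sum.

## What the synthetic generator does and does not emulate

`generate_cohort()` draws cohorts whose *statistical structure* matches the
modelled setting: exact class counts (16/111 of 127 by default), laboratory
values from truncated normals centered inside the standard reference ranges
(neutrophils 1.8–6.3 and lymphocytes 1.1–3.2 ×10⁹/L, platelets 125–350
×10⁹/L, albumin 40–55 g/L, markers below their clinical thresholds), a
positive-class shift of `effect_clin` standard deviations upward for SCC-Ag,
neutrophils and platelets and downward for lymphocytes and albumin, and an
ordinal FIGO stage almost deterministically associated with the label
(mirroring the published cross-tabulation, which is why it is excluded from
the default feature vector). Images are a smooth low-frequency background
plus, for positives, an additive Gaussian blob of amplitude `0.1 × effect`
at a random location, plus pixel noise (heavier for the US flavour). The
default effect amplitudes are 1 — enough for each modality to be individually
informative without making the task trivial.

What this buys: every pipeline stage, including fusion and the contrastive
term, is testable end to end with no data download, and planted-signal
recovery and null calibration become checkable claims. What it does not buy:
nothing about scanner physics, anatomy, volumetric context, or the
correlation structure of real laboratory panels is emulated, so passing
tests demonstrate that the machinery optimizes and evaluates correctly — not
that the model would reach any particular accuracy on real patients. The
headline metrics of the motivating clinical study derive from a private
cohort and are deliberately not reproduction targets.

The generator writes/reads cohorts as 8-bit grayscale PNG plus CSV
(manifest + clinical table), round-tripping within 1/255. DICOM input is not
supported: no DICOM reader exists in the package's dependency footprint, and
PNG is lossless at the tested bit depth.

## Numerical and degenerate-input choices

* Cosine similarity errors on rows with norm below 1e-12 rather than
  silently ε-guarding; a zeroed projection head therefore fails loudly.
* InfoNCE is computed with per-row max subtraction, and its batch must have
  n ≥ 2 (the literal denominator needs at least one negative).
* ROC ties advance TPR and FPR jointly, so the trapezoidal area equals the
  pairwise concordance probability with half-credit ties — asserted against
  a brute-force oracle and an established ROC implementation.
* Hard predictions take the argmax of the two class scores with ties broken
  toward the negative class.
* The Mann-Whitney z uses tie-corrected variance and a 0.5 continuity
  correction toward zero, with sign following `U₁ − n₁n₂/2`; a fully tied
  comparison returns z = 0, p = 1. These conventions are documented
  constants; published z values in this setting cannot adjudicate them
  without raw data.
* The Pearson chi-square applies no continuity correction — the reproduction
  of the reference baseline table's printed statistics (92.045, 0.341, ...)
  forces the uncorrected form even where expected cells drop below 5 —
  and Fisher's exact test is offered separately. Two published marker rows
  whose counts do not sum to the group sizes are excluded from reproduction
  tests.
* K-S normality routing uses the estimated-parameter dialect
  (`ks.test` against a normal with the sample's mean and SD), the behavior
  of common clinical statistics software; its conservatism only affects
  which summary a variable gets, not any test statistic.
* Batch norm uses population variance within batches, momentum 0.1 running
  statistics for evaluation mode.
* One global seed fans out to per-stage sub-seeds via a multiplicative hash
  of the stage name, so cohort generation, splitting, initialization and
  sampling are independently reproducible; identical configurations
  reproduce cohorts, splits and metric trajectories bit for bit on CPU.

## Problem sizes used in validation

The test suite and acceptance script run the signal-recovery experiment at
n = 200, 12.5% prevalence, 64 px images, reduced-depth backbone, 10 epochs,
3 seeds (held-out accuracy ≥ 0.85 expected in at least 2); the null
experiment trains on zero-signal cohorts of the same shape and measures AUC
on an independent 400-patient zero-signal cohort — evaluating on the
13-patient test split would leave the null AUC with a standard error near
0.2, too wide to distinguish a broken model from sampling noise — and the
ablation-direction experiment (fused mean AUC within 0.05 of the best single
modality) runs at n = 120, 32 px, 6 epochs over CT-only, US-only,
clinical-only and fused configurations. These sizes are the package's chosen
desk-scale study conditions; the 224 px ResNet-18 path is exercised for
shape and finiteness contracts.

## Known limitations

* No pretrained backbone weights ship with the package; `init = "file"`
  loads user-supplied weights, and random initialization is the default.
  Transfer from a large medical corpus — a pillar of the motivating study —
  is therefore out of scope here.
* One 2-D image per modality per patient; selecting a representative slice
  from a CT volume or US exam is left to the user.
* The classifier is a single affine layer on the 1536-d fusion; richer heads
  were not explored.
* CT and US encoders default to independent weights
  (`share_image_backbone = TRUE` shares them); the source formulation writes
  distinct functions but does not state whether weights were tied.
* Training is single-threaded CPU; there is no GPU path.
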