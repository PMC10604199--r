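---
title: "Multi-channel MRI/PET/clinical fusion for MTLE classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-channel MRI/PET/clinical fusion for MTLE classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mesial temporal lobe epilepsy (MTLE) is the most common cause of refractory
focal epilepsy. Its imaging signature is subtle and multi-modal: hippocampal
sclerosis appears as decreased volume and increased density on structural T1
MRI, and as reduced glucose metabolism (hypometabolism) on interictal
FDG-PET — usually lateralised to one hemisphere. Some patients are
MRI-negative and only the PET asymmetry betrays the epileptogenic zone.
Clinical presentation adds independent evidence: seizures of mesial temporal
origin typically begin with upper-abdominal aura and a feeling of fear.

`epifuse` implements a classification pipeline that fuses these three
sources — co-registered T1 MRI and FDG-PET volumes plus a short
clinical/demographic vector — in one multi-channel 3D convolutional network,
with a separate bilateral PET-asymmetry block whose subject-level
"PET-positive" decision is appended to the clinical vector. Because clinical
MTLE data cannot be redistributed, the package ships a synthetic
brain-phantom cohort generator with planted, parameterised disease effects;
every stage of the pipeline is exercised and tested against that generator's
ground truth.

## Preprocessing

**SUVR.** PET uptake values carry arbitrary between-subject scale (dose,
weight, scanner calibration). `compute_suvr()` divides each atlas region's
mean uptake by the mean uptake of the cerebellar reference regions,
yielding the standardized uptake value ratio

$$\mathrm{SUVR}_i = \frac{\overline{\mathrm{SUV}}_i}
{\overline{\mathrm{SUV}}_{\mathrm{cerebellum}}},\qquad i = 1,\dots,R,$$

over an AAL-style parcellation (R = 90 in template use; the phantom atlas
uses a configurable R ≥ 3). The ratio is invariant under global positive
rescaling and maps the reference itself to exactly 1 — both are tested
properties. `suvr_normalize()` applies the same reference voxel-wise so the
network's PET input is on the SUVR scale. MRI has no analogous physiological
reference, so each MRI volume is divided by its own mean intensity before
cohort-level z-scoring; T1 intensities are arbitrary units and this is the
conventional proxy.

**Cubes.** Both volumes are partitioned into 48×48×48-voxel cubes
(`extract_cubes()`), zero-padding the high side of each axis to the next
multiple of the stride and enumerating cubes in lexicographic origin order.
The default stride equals the cube size, so every padded voxel is covered
exactly once — the suite asserts voxel-sum conservation for awkward widths
such as 50.

**Region-pair features.** The regional SUVR profile can be expanded into a
region-pair matrix. The package defines it as the log-ratio matrix
$M_{ij} = \log(\mathrm{SUVR}_i/\mathrm{SUVR}_j)$, which is antisymmetric,
and keeps the strict upper triangle in row-major order (length
$R(R-1)/2$; 4005 for R = 90). The pair-matrix definition is a documented
package choice: log-ratios use only quantities the pipeline already
computes and make the upper triangle non-redundant. These features can be
appended to the clinical channel (`use_roi_features`), but are off by
default because their benefit is not established.

**Clinical vector.** `standardize_clinical()` maps the record to
`(symptom_abdominal, symptom_fear, age_z, sex, education_z)`; age and
education are z-scored with statistics from the training fold only, binary
fields pass through, and the optional PET-positivity flag is appended last
(length 5 without it, 6 with). A zero training standard deviation falls back
to centring.

## The bilateral PET-asymmetry block

`split_and_pair()` divides the SUVR-normalised PET volume at the geometric
midplane of the left-right axis (inputs are template-registered by
contract, so no per-subject midline estimation is attempted; odd widths
drop the single midline plane), reflects the right hemisphere, tiles both
hemifields into 48³ cubes and forms difference cubes
`left − mirrored right`. Perfect bilateral symmetry gives exactly zero
difference cubes, and swapping hemispheres negates every difference cube —
both exact identities in the tests.

A small 3D CNN (two convolutions with ReLU and pooling, a third pooling
stage, dropout, dense logit) scores each difference cube; every pair
inherits its subject's EP/HC label, an accepted source of label noise since
patient hemifields also contain healthy tissue. `aggregate_subject_flag()`
turns pair scores into the subject flag: by default a majority of pairs
above 0.5, with an `"any"` rule exposed for very focal signals. On the
default phantom geometry the target structure straddles all four mirrored
cube pairs, so the majority rule recovers planted lateralisation reliably.

## The fusion network

The architecture follows a fixed layer plan. Each image modality has its own
branch: three 3D convolutions (3³ kernels, ReLU), three pooling stages and
dropout. Branch outputs are concatenated channel-wise into a trunk of two 3D
convolutions, three pooling stages and dropout, then flattened. The clinical
vector passes through two 1D convolutions, two pooling stages and dropout.
The concatenated image and clinical features enter an integrated head — two
1×1 convolutions (dense layers) with feature normalisation and dropout —
ending in a sigmoid. Disabling channels removes the corresponding branch,
which is how the single-channel and image-only ablations are built. A
subject whose volumes tile into several cubes gets one probability: per-cube
logits are averaged before the sigmoid.

Training uses batch size 1 and binary cross-entropy with ReLU activations,
a maximum of 500 epochs and early stopping after 1000 iterations without
training-loss improvement. Within that protocol the package makes four
optimisation choices, each found necessary on phantom cohorts of realistic
size (tens of subjects) and each exposed in configuration:

* **Average pooling** is the default pooling operation. The discriminative
  image signal is a regional shift in mean intensity (hypometabolism,
  density change); average pooling propagates it with dense gradients,
  whereas deep max-pooling chains pass gradients through single voxels and
  stall on small cohorts. Max pooling remains available.
* **Adam** is the default optimiser (learning rate 1e-3). The image and
  clinical branches produce gradients differing by ~10³ in magnitude;
  per-parameter adaptive steps absorb this. Plain SGD is available, and
  `reference_train_config()` restores the reference protocol exactly
  (SGD, learning rate 0.1, no warm-up) — at batch size 1 that learning rate
  frequently diverges, which is why it is not the default.
* **Feature whitening stands in for batch normalisation.** Batch statistics
  do not exist at batch size 1, so the head standardises each input feature
  with statistics computed over the whole training set, refreshed at every
  epoch, with a floor on the standard deviation and clipping of extreme
  normalised values. Gradients treat the statistics as constants, as in
  inference-statistics batch normalisation. This step is load-bearing: the
  flattened image features are spatial averages whose between-subject
  variation is ~1% of their mean, and without per-feature whitening the
  logit separation grows too slowly to be usable.
* **Probe-then-fine-tune schedule.** Training starts with a head-only
  warm-up (`head_warmup`, default 400 full-batch iterations) on cached
  frozen-branch features — a linear probe, optimised full-batch because the
  features are cached and full-batch descent converges smoothly where
  sample-by-sample updates oscillate — followed by optional end-to-end
  fine-tuning (`epochs`; 0 keeps the probe solution) in which everything
  below the head uses a scaled learning rate (`branch_lr_scale`, default
  0.05) plus decoupled weight decay on the head. Warm-starting the head
  keeps residual gradients small, so branch features do not outrun the
  whitening statistics between refreshes. At cohort sizes of a few dozen
  subjects the probe dominates what the model learns; the batch-1
  fine-tuning phase mainly adds variance, which is why the evaluation
  protocols in this package keep it short or off.
* **Aligned modular initialisation.** Every component (each image branch,
  each modality's trunk group, the clinical branch, the head) draws its
  initial weights from its own deterministic stream, and the trunk is
  assembled block-diagonally from per-modality trunks whose width scales
  with the number of fused modalities. Consequently a branch has the same
  initial weights whether built alone or inside the fused model: the fused
  model starts from exactly the union of the single-channel models'
  features, ablation comparisons differ only by what is present (not by
  draw order), and end-to-end training is free to populate the
  cross-modality blocks.

Unstated architectural constants (channel widths 8/16/32, kernel 3³,
pooling 2³, dropout 0.5, head width 16) are defaults of `model_config()`;
only the layer counts are fixed. Ties at probability exactly 0.5 predict
positive.

## Evaluation

`metrics_from_counts()` reports accuracy and sensitivity in their standard
forms and two variants of specificity and F1. The "as-printed" specificity
is TP/(TP+FP) — algebraically precision, not specificity. The package
reports it under that explicit name next to the standard TN/(TN+FP) rather
than silently correcting it, and consequently the as-printed F1 (harmonic
mean of sensitivity and as-printed specificity) coincides identically with
the standard F1 of precision and recall — asserted exactly in the tests.
Zero-denominator metrics are reported as `NA`, never clamped. AUC is the
rank-based (Mann-Whitney) estimator with ties counted half, cross-checked
against an all-pairs oracle and against pROC.

`cross_validate()` runs seeded stratified 5-fold cross-validation. Every
training-derived quantity — image and clinical standardisation statistics,
the asymmetry classifier and its flags, the model weights — is recomputed
inside each fold from the training subjects only; the report carries
fingerprints of that fold-local state, which the tests compare against
independent recomputation to demonstrate the absence of leakage. A fixed
stratified split (`fixed_split_evaluate()`) is available as the alternative
protocol.

## The phantom generator

`make_phantom_atlas()` builds a deterministic template: an ellipsoidal
brain, a mirrored pair of "hippocampal" target ellipsoids, a
midline-symmetric "cerebellar" reference and filler bands. Mirror symmetry
of the target pair is exact by construction. `generate_cohort()` then draws
subjects:

* **Controls** are bilaterally symmetric up to additive Gaussian noise
  (`noise_sd`, default 0.05 on a tissue intensity of ~1).
* **Patients** carry, on one lateralised side, MRI atrophy — the target
  ellipsoid shrinks by `atrophy_frac` in volume, the lost rim takes CSF-like
  intensity and the remaining interior brightens ("increased density") —
  and PET hypometabolism — uptake reduced by `hypometab_frac` in the target
  and by half that fraction in a dilated mesial-temporal penumbra,
  reflecting the lobar extent of interictal hypometabolism.
* **Anatomical variability:** per-subject mirror-symmetric jitter of
  internal structure centres (sd 1% of the volume dimension) and sizes
  (3% log-sd), emulating inter-subject variability and residual
  registration error. The outer brain envelope does not jitter because
  template registration normalises overall brain size and position.
* **Nuisance scales:** each PET volume gets a lognormal global scale
  (sd 0.25, removed by SUVR), each MRI a milder one (sd 0.05, removed by
  per-volume mean normalisation).
* **Clinical data:** symptom flags are Bernoulli at class-specific rates
  (defaults 0.8 for patients, 0.2 for controls), ages come from one
  distribution for both classes (age matching), sex is balanced, education
  is Normal(12, 3) years.

Defaults describe the emulated study: 15 patients and 15 controls, 96³
template-space voxels, 30% planted effects. The generator writes NIfTI
volumes, a CSV manifest and a machine-readable ground-truth table
(`ground_truth()`), and is bit-reproducible from its spec and seed.

What the phantom does *not* model: MRI/PET physics (partial volume, PSF,
scanner noise spectra), cortical folding, real anatomical shape, or
correlated multi-focal pathology. Passing tests therefore demonstrate that
the pipeline recovers planted effects of realistic size and direction under
idealised geometry — not clinical performance.

## The ablation fixture

The channel-ablation check (fused model versus each single channel) uses a
cohort with *complementary* planted signals: 40% of patients are
MRI-negative and, independently, 40% are PET-negative
(`mri_negative_frac`, `pet_negative_frac`), with symptom rates 0.7 vs 0.3.
This mirrors the clinical reality that some MTLE patients show no
structural abnormality and only the PET asymmetry (or the clinic) betrays
them — and it is the regime in which fusion has genuine information to
gain: no single channel sees every patient, so single-channel AUCs are
capped while the fused model can combine partial evidence. On redundant
fixtures (every patient positive in every channel) the best single channel
already saturates and fusion can at most match it.

## Test and verification scale

The test suite and the acceptance script run the full pipeline at reduced
scale, chosen as a deliberate package decision so that simulations remain
desk-size: asymmetry-block checks use the default 96³ dims with 40 subjects
(30% deficit) and a 200-pair null; fusion-model checks use 48³ volumes (one
cube per modality), channel widths (2, 4, 8), 20 training and 20 held-out
subjects (ablations: 60 training and 60 held-out subjects, probe-only
training), and medians over five seeds for the ablation ordering. The
published-scale protocol (90-region atlas, 500 epochs, full widths) is
reachable through the same configuration objects.

## Known limitations

* With tens of subjects the network operates mostly in the linear-probe
  regime; the end-to-end fine-tuning phase refines rather than re-learns
  features. Larger cohorts would shift that balance.
* The asymmetry block assumes template-space inputs; a mis-registered
  midline would contaminate every difference cube.
* The log-ratio ROI pair matrix is one defensible definition among several;
  it is exposed but not switched on by default.
* Clinical-channel performance is bounded by the overlap of symptom rates
  between classes; with the default rates the Bayes AUC of the two flags
  alone is about 0.85.
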