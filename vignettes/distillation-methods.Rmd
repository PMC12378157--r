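---
title: "Distilling frozen vision backbones into compact medical image classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distilling frozen vision backbones into compact medical image classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meddistill)
```

## The problem

Compact convolutional networks are the practical choice for classifying small
medical images (the MedMNIST family standardizes such tasks at 28x28 pixels
across pathology, X-ray, dermatoscopy, OCT, ultrasound, microscopy and CT
modalities), but their capacity limits what they can learn from scarce labels.
Very large self-supervised vision backbones generalize broadly but are
expensive to run and, used as frozen feature extractors with a linear head,
are not consistently better on specialized medical tasks.

Knowledge distillation couples the two: a large, frozen, linear-probed
*teacher* produces temperature-softened class distributions ("soft targets")
for every training image, and a compact trainable *student* learns from both
those soft targets and the ground-truth hard labels. The student inherits the
teacher's inter-class similarity structure while staying small.

## The model

For an image with logit vector $z = (z_1, \dots, z_m)$ over $m$ classes, the
temperature softmax is

$$P^{soft}_i = \frac{e^{z_i/t}}{\sum_j e^{z_j/t}},$$

where the temperature $t > 0$ controls softness: large $t$ flattens the
distribution and exposes how the teacher ranks the *wrong* classes, which is
the information a one-hot label lacks.

The distillation loss is the forward Kullback-Leibler divergence from the
teacher's temperature-$t$ distribution $P^T$ to the student's $P^S$, scaled
by $t^2$:

$$L_{distill} = t^2 \sum_i P^T_i \ln \frac{P^T_i}{P^S_i}.$$

The $t^2$ factor compensates the $1/t$ shrinkage of soft-target gradients so
the balance between loss terms is temperature-invariant. The hard-label loss
$L_{ce}$ is the ordinary cross-entropy on the temperature-1 softmax for
single-label tasks, and the mean per-label binary cross-entropy on sigmoid
probabilities for binary and multi-label tasks. The training objective is the
convex combination

$$L_{total} = \alpha\, L_{ce} + (1-\alpha)\, L_{distill}, \qquad \alpha \in [0,1].$$

Two conventions deserve note. First, the source description of the
distillation term carries a sign/argument inconsistency (a leading minus
would make the loss non-positive, and the divergence arguments flip between
definition and use); this package implements the standard form above —
forward KL from the fixed teacher to the student — which is the quantity a
minimizer sensibly targets. Second, softmax-based soft targets are undefined
for multi-label tasks; `multilabel_soft_loss()` extends the same idea by
treating each label's temperature-scaled sigmoid as a two-point distribution
and averaging the $t^2$-scaled binary KL divergences over labels. Both are
package decisions, flagged as such.

All losses are per-sample batch means in nats, so $\alpha$ has the same
meaning at any batch size; logarithms are floored at $10^{-12}$.

## Two-phase training

1. **Linear probing** (`fit_linear_probe()`): the teacher backbone stays
   frozen; only a linear head is trained on its penultimate features with the
   task's hard loss. Features are computed once (the backbone never changes)
   and standardized internally using train-split statistics; the affine
   standardization is folded back into the returned head, so the result is an
   ordinary linear head on raw features. Without this conditioning step a
   fixed-learning-rate head cannot reach calibrated logits on backbones whose
   feature scale is small, even when its ranking (AUC) is already excellent.

2. **Distillation** (`distill()`): every minibatch passes through the frozen
   teacher (logits cached across epochs — valid because the teacher is
   frozen; a config flag disables the cache) and the student, which is
   updated by Adam on $L_{total}$. Training follows a multi-step schedule —
   base learning rate 0.001, multiplied by 0.1 at the start of epochs 50 and
   75 of a 100-epoch run (0-based indexing) — with early stopping once the
   monitored validation metric has not strictly improved for `patience`
   epochs (default 15), and the best-validation checkpoint is returned (ties
   resolve to the earlier epoch). Validation AUC is the default monitor; on
   cleanly separable synthetic data AUC saturates within a few epochs, and
   monitoring accuracy (`monitor = "acc"`) is then the sharper choice.

`train_supervised()` is the reference arm: hard labels only. At
$\alpha = 1$ it reproduces `distill()` step for step at the same seed — the
distillation term is computed but enters the gradient with exact weight zero
— which the test suite asserts as a reduction identity, along with the
$\alpha = 0$ identity (training is then label-free) and the large-$t$ limit
(soft targets become uniform).

## Architectures

The training engine implements exact backpropagation (verified against
central finite differences) for the `"tiny"` architecture: three 3x3
convolution blocks (8/16/32 channels) with average pooling, global average
pooling, and a linear head — about 24k parameters. This is the desk-scale
model used for both roles throughout the tests.

The reference architectures are provided as constructors with exact
parameter-shape accounting, evaluation-mode forward passes, and checkpoint
I/O:

* `build_student("resnet50", task)` — the bottleneck-block residual network
  with a task-sized head (23M parameters at MedMNIST head sizes; batch-norm
  running statistics are buffers, not parameters, which is the convention
  under which the published sizes land);
* `build_vit_backbone()` — vision transformers with patch size 14 at the
  published widths/depths/heads 384/12/6, 768/12/12 and 1024/24/16 (22M, 86M,
  304M), MLP ratio 4, per-block layer-scale, class token, and position
  embeddings on the 37x37 grid of the native 518-pixel pretraining
  resolution, interpolated bilinearly for other input sides.

Gradient-based training of the ResNet-50 student end-to-end is outside the
desk scale this package targets (it is a GPU-scale computation); `distill()`
says so explicitly if asked. Parameter counting never allocates weights:
constructors build shape tables, and `count_parameters()` walks them.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` emits the MedMNIST NPZ dialect (six arrays:
`train/val/test_images`, `train/val/test_labels`; unsigned 8-bit images
`n x 28 x 28` or `n x 28 x 28 x 3`; labels `n x 1` integer or `n x m` 0/1)
with controllable task kind, class count, noise and seed. Class $k$ places a
bright Gaussian blob (amplitude 150 over a background of 20, spread
`blob_sigma = 2.5` px) at angle $2\pi k/m$ on a ring of radius `side/4`
about the image centre; multi-label tasks draw each label independently
(probability 0.3) and superpose the active blobs; ordinal tasks encode rank
by blob *radius* at a fixed angle, so adjacent grades are the most
confusable — a monotone confusability structure chosen because ordered
severity grades behave that way. I.i.d. Gaussian pixel noise (`noise_sigma`,
8-bit intensity units) is added and clipped to [0, 255].

This generator makes every pipeline stage testable offline with known ground
truth: class evidence is spatially localized (so heatmap tests have an
oracle), separability degrades monotonically with noise, and identical specs
give bit-identical data. It does **not** emulate the appearance statistics of
any medical modality — textures, anatomy, label noise, class imbalance, or
distribution shift. Passing tests demonstrate that the algorithms are
implemented correctly, not that the measured effect sizes transfer to real
medical images.

## The distillation-benefit study

`distill_benefit_study()` packages the scaled-down version of the paper-scale
claim that distillation improves the student. Conditions (fixed as study
design, with the reasoning recorded here):

* 4 classes, 800/150/400 train/val/test, `noise_sigma = 110`. The noise was
  calibrated on the supervised baseline alone so that the task is genuinely
  hard (baseline accuracy well below ceiling — at noise 50 the tiny student
  is perfect and the comparison would be vacuous).
* The teacher backbone is a tiny CNN pretrained once by supervised training
  on a disjoint sample of 3000 images from the same distribution, then
  frozen. This plays the role of the abundantly pretrained large backbone:
  the teacher's advantage is that it has seen ~4x more data than the student
  ever will.
* Per seed: fresh task data; the frozen teacher is linear-probed on the 800
  training images; one student is distilled at $t = 2$, $\alpha = 0.2$, and a
  second trained at $\alpha = 1$, with the same seed.
* Both arms train 40 epochs, learning rate 0.001 dropped by 10 at epochs 20
  and 30 (the reference schedule's 50/75-of-100 proportions), batch 128,
  early stopping on validation AUC with patience 15. The $\alpha = 0.2$ arm
  warms up more slowly than the $\alpha = 1$ arm (its hard-label gradient is
  5x smaller), so schedules short enough to truncate that warm-up bias the
  comparison against distillation.

The acceptance suite asserts that the mean test accuracy of the distilled arm
over five seeds is at least that of the baseline arm; `scripts/acceptance.R`
reports both means and the gain.

## Evaluation conventions

AUC and accuracy follow the MedMNIST benchmark conventions: binary AUC is the
rank-based (Mann-Whitney) statistic with ties counted half; multi-class and
ordinal AUC is the unweighted one-vs-rest macro average over classes present
(absent classes are skipped and reported); multi-label AUC averages per-label
AUCs over labels with both outcomes. Accuracy is argmax with ties to the
lowest index for single-label tasks, and a 0.5 sigmoid threshold per label for
binary/multi-label (multi-label accuracy averages per-label accuracies).
Probabilities are always formed at temperature 1. The implementation is
checked against a brute-force pairwise-concordance oracle to $10^{-9}$.

## Visualization

`embed_features_2d()` is an exact t-distributed stochastic neighbor embedding
(perplexity-calibrated Gaussian affinities via bisection; Student-t output
kernel; momentum gradient descent with early exaggeration), written in the
package because no t-SNE implementation is available in the supporting stack;
it is quadratic in $n$ and intended for desk-scale inputs. The seed is
mandatory and fully determines the result.

`gradcam_heatmap()` produces class-evidence maps by gradient-weighted class
activation mapping on the last convolutional block. Both supported CNNs end
in global average pooling plus a linear head, for which the gradient of a
class logit with respect to the last convolutional map is the head weight
spread uniformly over space — the gradient-weighted map therefore has the
closed form $\mathrm{relu}(\sum_k w_{c,k} A_k)$, computed exactly rather
than by numeric backpropagation. Maps are rectified, bilinearly upsampled to
the input size, and max-normalized; an all-zero map (a class whose logit
ignores the input) is returned as zeros and flagged degenerate.

A limitation worth knowing: localization of heatmap mass onto the class blob
is a property of the *task*, not just the method. A multi-label-trained
model must detect each blob positively — any combination of blobs occurs —
and its maps concentrate half or more of their mass within the 2-sigma blob
disc (under 10% of the image area). A single-label-trained model may
legitimately encode a class by the absence of the other classes' blobs, and
its maps can be diffuse; the test suite therefore checks mass concentration
on a multi-label model and checks translation equivariance (the map's centre
of mass follows the blob) as the model-direction smoke test.

## Numerical and design notes

* Determinism: every stochastic component draws through a named substream of
  one master seed (`derive_seed()`), so data, initialisation and shuffling
  are independently reproducible. Identical runs are bit-identical.
* The learning-rate schedule is computed by sequential multiplication so the
  decimal reference values 0.001/0.0001/0.00001 are reproduced exactly in
  double precision.
* Softmax uses max-subtraction; logits up to at least 1e4 in magnitude are
  safe. KL terms use the convention 0 ln 0 = 0 and error on support
  violations.
* NPY/NPZ I/O is implemented in the package (NPY v1.0; stored-entry zip with
  CRC-32 taken from a gzip trailer) because the supporting stack has no NPY
  reader; archives are written deterministically (fixed timestamps), so
  identical bundles give identical files.
* Bilinear resizing uses the corners-not-aligned convention; at equal source
  and target side it is the identity, which the preprocessing contract test
  pins down.
* Ordinal tasks cannot be distinguished from multi-class by label shape, so
  they must be declared (`task_override = "ordinal"` or the CLI's
  `--task-override`); they train and evaluate with the single-label
  cross-entropy conventions.
* Problem sizes in the test suite (hundreds of images, tens of epochs,
  the 40-epoch benefit study) are the package's chosen desk scale: large
  enough for the properties under test to be meaningful, small enough to run
  comfortably on one CPU.

## Known limitations

* The reference ResNet-50/ViT architectures are forward/counting contracts
  here; training them requires hardware this package does not target.
* The synthetic generator's simplicity means measured accuracies and benefit
  sizes say nothing quantitative about real MedMNIST datasets.
* The multi-label soft-target loss is this package's extension (the source
  method leaves the multi-label case unspecified).
* Exact t-SNE is O(n^2) per iteration; embedding more than a few thousand
  points is impractical.
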