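# meddistill

Knowledge distillation from frozen vision backbones into compact
convolutional classifiers for MedMNIST-style 28x28 medical images, as a
tested R package with a command-line interface.

## The problem

Compact CNNs are the practical models for small standardized medical images
(binary, multi-class, multi-label and ordinal tasks in the MedMNIST mould),
but scarce labels limit what they learn. Large pretrained vision backbones
generalize broadly but are expensive and, frozen behind a linear probe, not
reliably better on specialized tasks. Distillation combines them: a frozen,
linear-probed *teacher* supplies temperature-softened class distributions,
and a small trainable *student* learns from those soft targets together with
the ground-truth labels.

## The method

With logits $z$ over $m$ classes and temperature $t > 0$,

$$P^{soft}_i = \frac{e^{z_i/t}}{\sum_j e^{z_j/t}},$$

the distillation loss is the $t^2$-scaled forward Kullback–Leibler divergence
from the teacher's softened distribution $P^T$ to the student's $P^S$,

$$L_{distill} = t^2 \sum_i P^T_i \ln\frac{P^T_i}{P^S_i},$$

and the training objective mixes it with the task's hard-label loss
(cross-entropy, or mean per-label binary cross-entropy for binary and
multi-label tasks):

$$L_{total} = \alpha\,L_{ce} + (1 - \alpha)\,L_{distill}.$$

Training is two-phase: `fit_linear_probe()` fits the teacher's linear head on
frozen backbone features; `distill()` then trains the student with Adam under
a multi-step learning-rate schedule (0.001, x0.1 at epochs 50 and 75 of a
100-epoch run) with early stopping on a validation metric and
best-checkpoint selection. `train_supervised()` is the hard-label-only
reference arm, identical to `distill()` at alpha = 1 step for step.

Everything runs offline on synthetic MedMNIST-dialect data with known
class-conditional structure (`synthetic_spec()` / `generate_dataset()`), and
the package reads and writes the six-key NPZ dialect (`read_npz()`,
`write_npz()`, `load_medmnist_npz()`). Evaluation follows the MedMNIST
conventions (macro one-vs-rest AUC, per-label accuracy; `evaluate_model()`).
Reference architectures — ResNet-50 and the patch-14 vision transformers at
widths 384/768/1024 — are provided as constructors with exact parameter
accounting (23M / 22M / 86M / 304M) and evaluation-mode forward passes;
gradient training runs on the desk-scale `"tiny"` CNN. Feature maps can be
embedded in 2-D (`embed_features_2d()`) and explained with class-evidence
heatmaps (`gradcam_heatmap()`).

## Worked example

The packaged distillation-benefit study runs the whole pipeline — pretrain a
tiny teacher backbone on 3000 disjoint synthetic images, freeze it, probe its
head per seed, then distill a fresh student (t = 2, alpha = 0.2) and train a
hard-label baseline with the same seeds — and compares test accuracy arm by
arm (about 9 minutes on one CPU):

```r
library(meddistill)
res <- distill_benefit_study(seeds = 1:5)
res
#>    seed       arm test_acc  test_auc
#> 1     1 distilled   0.7650 0.9881716
#> 2     1  baseline   0.7175 0.9872000
#> 3     2 distilled   0.9650 0.9950028
#> 4     2  baseline   0.8825 0.9917337
#> 5     3 distilled   0.8950 0.9886424
#> 6     3  baseline   0.9125 0.9937385
#> 7     4 distilled   0.9625 0.9909182
#> 8     4  baseline   0.8950 0.9975906
#> 9     5 distilled   0.7550 0.9830413
#> 10    5  baseline   0.7325 0.9826308
tapply(res$test_acc, res$arm, mean)
#>  baseline distilled
#>    0.8280    0.8685
```

The distilled student's mean test accuracy exceeds the supervised baseline by
about 4 points on this 4-class task (pixel noise 110 on the 8-bit scale,
where the baseline sits well below ceiling); the frozen teacher itself tests
at 0.987 on its pretraining distribution. Loss components are available
directly:

```r
total_loss(hard = 0.6931, distill = 0.4438, distill_config(temperature = 2,
                                                           alpha = 0.2))
#> <kd_loss> total 0.493660 = alpha*hard(0.693100) + beta*distill(0.443800)
```

The same pipeline is scriptable from a shell via `inst/cli/meddistill`
(subcommands `simulate`, `probe`, `distill`, `evaluate`, `ablate`, `embed`,
`heatmap`, `count-params`), e.g.

```sh
inst/cli/meddistill simulate --task multiclass --classes 4 \
  --n-train 200 --n-val 50 --n-test 50 --seed 1 --out demo.npz
inst/cli/meddistill count-params --model s14
#> s14: 22,056,192 parameters (22 M)
```

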