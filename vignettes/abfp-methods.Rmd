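---
title: "Attention-balanced feature pyramids for low-contrast lesion detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-balanced feature pyramids for low-contrast lesion detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abfp)
```

## The problem

Small, low-contrast lesions — the motivating case is gastrointestinal
stromal tumors in abdominal CT slices — are hard targets for anchor-based
detectors. They vary widely in size and shape, their edges are blurred, and
their gray values sit close to the surrounding tissue. Detector necks such
as the feature pyramid network (FPN) fuse multi-scale backbone features
through a top-down sequence of pairwise additions, which privileges
*adjacent* levels: by the time information from a non-adjacent level
arrives it has been diluted through several merges. For targets whose scale
is unpredictable, that imbalance between deep semantic levels and shallow
detail levels costs accuracy.

This package implements a remedy, the attention-balanced feature pyramid
(ABFP): give every level the *same* aggregated view of all levels, refined
by attention, at no per-level cost.

## The model

Write the uniform-channel pyramid as $\{P_2,\dots,P_5\}$ (finest first,
resolution halving per level, shared channel count $C$). The neck performs
four steps.

**Rescale and integrate.** Every level is rescaled to the spatial shape of
one intermediate level and the rescaled maps are averaged with equal
weights,

$$\bar C = \frac{1}{N} \sum_{l} \mathrm{resize}(P_l),$$

producing the *balanced semantic map* $F_b$. The average is deliberately
unweighted and parameter-free. Downscaling uses non-overlapping max pooling
whose stride equals the (integer) scale factor — a two-octave jump pools
$4\times4$ windows — and upscaling uses nearest-neighbour interpolation.

**Refine.** Two attention gates are computed *from* $F_b$ and applied *to*
$F_b$ in parallel:

- channel gate $M_c = \sigma(\mathrm{MLP}(\mathrm{avgpool}(F_b)) +
  \mathrm{MLP}(\mathrm{maxpool}(F_b)))$, a length-$C$ vector, where the two
  global-pooling branches share one two-layer MLP
  ($W_1\,\mathrm{ReLU}(W_0 x)$, hidden width $C/r$);
- spatial gate $M_s = \sigma(f^{7\times7}([\mathrm{avg}; \mathrm{max}]))$,
  an $H\times W$ grid, from a $7\times7$ convolution over the stacked
  per-pixel channel average and maximum (average plane first).

The refined map is the *sum of the two gated copies*,

$$F_{ab} = M_c \otimes F_b \;\oplus\; M_s \otimes F_b,$$

with $M_c$ broadcast over pixels and $M_s$ over channels. This parallel
additive composition differs from the sequential composition of standard
CBAM; both gates see the unmodified balanced map. With both gates at $0.5$
the refinement is exactly the identity, which anchors several tests. No
normalization follows the sum, so the output magnitude can approach twice
the input bound — implemented exactly as specified by the model.

**Strengthen.** $F_{ab}$ is rescaled back to every level's own shape (by
the same primitives, in the opposite direction) and added element-wise to
the original level. Shapes are conserved exactly, so the refinement stacks
on any producer of a uniform-channel pyramid — FPN here, but the interface
accepts any neck output.

## Design choices where the design was open

- **Interpolation kind.** Only "interpolation" is specified for upscaling;
  we default to nearest-neighbour, which makes constant maps and integer
  factors exact (and matches the Libra R-CNN lineage of the balanced
  pyramid); bilinear is available via `upsample_mode = "bilinear"`.
- **Intermediate level.** "The middle size" leaves a choice for even $N$;
  the default index is `N %/% 2 + 1` (1-based), i.e. the coarser of the two
  middle levels of a 4-level pyramid. Configurable.
- **Non-dyadic shapes.** Ceil-halving odd sizes (5 → 3 → 2) produces
  non-integer scale factors; rather than failing, rescaling falls back to
  nearest-neighbour interpolation to the exact target shape (tested on
  5×5 → 3×3).
- **ReLU placement.** The gate description mentions a ReLU without fixing
  its position; it sits between $W_0$ and $W_1$ inside the shared MLP, the
  standard squeeze-excite/CBAM design the module mirrors.
- **Reduction ratio.** Unspecified upstream; default $r = 16$, clamped so
  the hidden width is at least 1, and $r$ must divide $C$. The micro
  detector uses $r = 4$ because its neck is only 16 channels wide.
- **Biases.** Bias terms in the MLP and the 7×7 convolution are not
  specified; they are included by default and can be disabled
  (`attention_bias = FALSE`).
- **Conv padding.** The spatial gate pads by 3 with zeros so $H \times W$
  is preserved; on spatially constant input the gate is therefore constant
  only away from a 3-pixel border, and the tests assert exactly that.
- **Ablation arm.** With `attention = FALSE` the refinement is replaced by
  a single 3×3 convolution, mirroring the convolution-refinement ablation.
- **ABFP input.** The refinement operates on FPN *outputs*, not raw
  backbone features: the unweighted average requires equal channel counts,
  which only the neck outputs have. (Upstream prose also says levels are
  "weighted" before fusion; the defining equation is an unweighted mean,
  and the unweighted mean is what is implemented.)

## Evaluation

`evaluate_detections()` is a single-class COCO-style evaluator: greedy
score-ordered matching per image (each detection takes the unmatched
ground-truth box of highest IoU, provided IoU ≥ t; ties in score keep
input order), a global precision–recall curve, 101-point interpolated AP
on the precision envelope, and AP/AP50/AP75/AR aggregated over the ten IoU
thresholds 0.50:0.05:0.95. AR uses a per-image cap of 100 detections (the
COCO convention; the cap is configurable because it was not specified
upstream). All of it is checked against hand-derived cases and an
independent per-grid-point integration oracle.

## The synthetic data

The real study data (private CT series with expert boxes) are not
available, so the package ships a deterministic generator that emulates the
regime the method targets: 128×128 grayscale slices (512 supported), a
smooth random background field (coarse Gaussian noise, bilinearly
upsampled, correlation length 16 px, s.d. 0.04 around gray level 0.45),
and per image a fixed number of non-overlapping elliptical lesions with
random center, semi-axes (4.5–12.5 % of the image side), and orientation.
Lesion edges are blurred with a Gaussian (σ = 1.5 px), the lesion-minus-
background contrast is a low 0.15, and i.i.d. Gaussian pixel noise
(σ = 0.03) is added before clamping to [0, 1]. Boxes are the tight analytic
extents of each ellipse.

What this does *not* emulate: anatomical context and confounding organs,
multi-phase acquisition, inter-slice 3-D structure, annotation noise, and
the long-tailed size distribution of real lesions. Passing the end-to-end
test therefore shows that the pipeline — data, neck, heads, losses,
optimizer, evaluator — is wired correctly and can learn a low-contrast
detection task from scratch; it is not evidence about clinical
performance.

## The micro detector

A deliberately tiny single-stage detector proves the neck end-to-end on one
CPU. Backbone: five 3×3 stride-2 convolutions (widths 8, 16, 32, 64, 128)
with per-channel instance normalization and ReLU, giving features at
strides 4/8/16/32; inputs are centered to $[-1, 1]$. Instance
normalization is used because a from-scratch network trained for only a
few hundred SGD steps needs the conditioning; a full-scale counterpart
would use a pretrained, batch-normalized backbone instead. Neck: FPN to 16
channels, then ABFP. Head: one shared 3×3 conv (instance-normalized) and
3×3 classification/regression convs over 3 anchors per cell (aspect ratios
0.5/1/2, base size 4× the level stride); the classification bias starts at
the 1 % foreground prior. Losses are the single-stage defaults: focal loss
(γ = 2, α = 0.25) over non-ignored anchors plus smooth-L1 (β = 1/9) over
positives (IoU ≥ 0.5 positive, < 0.4 negative, each ground-truth box force-
matched to its best anchor), normalized by the number of positives in the
batch.

Optimization follows the reference recipe where one is stated — SGD,
initial learning rate 0.01, momentum 0.9, weight decay 1e-4, batch size 4,
horizontal flips with probability 0.5, linear warmup — at the desk-scale
schedule of 12 epochs with 10× drops at epochs 8 and 11 (the full-scale
schedule is 24 epochs with drops at 16 and 22). Training is single-threaded
and bit-reproducible for a fixed seed. The standard problem size used by
the tests and the acceptance script is 200 images with an 80/20 image-level
split, which trains in a few minutes on one CPU.

Everything is differentiated analytically — convolutions (im2col + BLAS),
pooling, resizing, normalization, attention, losses — and the backward
passes are verified against central finite differences (the refinement
path to 1e-4 relative; in practice ~1e-10).

## Numerical notes

- All oracle comparisons use an absolute tolerance of 1e-6; computations
  are in double precision.
- Max pooling and the channel-max plane break ties by first index, making
  forward and backward passes deterministic.
- Gates are sigmoid outputs and lie strictly inside (0, 1) for finite
  pre-activations; exact 0/1 cannot occur in finite arithmetic.
- Degenerate (zero-area) boxes are rejected at the evaluator boundary;
  decoded boxes are clipped to the image and discarded if their side falls
  below 1e-3 px.
- Box-delta decoding clamps log-scale offsets to ±4 to avoid overflow from
  untrained heads.

## Worked example

```{r example, eval = FALSE}
spec <- lesion_scene_spec(seed = 101)
dataset <- make_lesion_dataset(spec, 200)
splits <- split_dataset(dataset, 0.8, seed = 101)

detector <- build_detector(seed = 101)
detector <- train_detector(detector, dataset, train_config(seed = 101),
                           indices = splits$train)
predict_and_evaluate(detector, dataset, splits$test)
```

The README shows the numbers this prints on one CPU, alongside the
untrained baseline and the convolution-refinement ablation arm; the same
pipeline is what `scripts/acceptance.R` re-runs from scratch.

## Known limitations

- The generator's lesions are brighter than background by construction;
  real lesions may be hypo- or hyper-dense. A sign option would be a
  one-line extension but is not needed for the method's verification.
- The micro detector is not a clinical model: no pretraining, a toy
  backbone, one foreground class, 2-D only.
- AR is reported at the 100-detection cap only; per-size AP breakdowns are
  not implemented.
- PAFPN/BiFPN-style necks are accepted through the same pyramid interface
  but are not implemented here.
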