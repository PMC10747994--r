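# abfp

Balanced multi-scale feature fusion with parallel attention for detecting
low-contrast lesions in CT slices.

## The problem

Anchor-based detectors fuse multi-scale backbone features in a neck such as
the feature pyramid network (FPN). The top-down sequence of pairwise merges
privileges adjacent levels: semantic information from non-adjacent levels is
diluted at every step. For lesions whose size and shape vary widely and
whose gray values barely differ from the surrounding tissue — small
intestinal stromal tumors in abdominal CT are the motivating case — this
imbalance between deep and shallow features costs detection accuracy.

The **attention balanced feature pyramid (ABFP)** gives every level the same
aggregated view of all levels. With pyramid levels $\{P_2,\dots,P_5\}$
(shared channel count $C$, resolution halving per level):

1. **Integrate** — rescale every level to the intermediate level's shape
   (max pooling down, nearest-neighbour up) and average them with equal
   weights: $\bar C = \frac{1}{N}\sum_l \mathrm{resize}(P_l)$, the
   *balanced semantic map* $F_b$. No learned parameters.
2. **Refine** — gate $F_b$ with channel attention
   $M_c = \sigma(\mathrm{MLP}(\mathrm{avgpool}\,F_b) +
   \mathrm{MLP}(\mathrm{maxpool}\,F_b))$ (one shared two-layer MLP with
   reduction ratio $r$) and spatial attention
   $M_s = \sigma(f^{7\times 7}[\mathrm{avg};\mathrm{max}])$, applied in
   **parallel** and summed:
   $F_{ab} = M_c \otimes F_b \oplus M_s \otimes F_b$.
3. **Strengthen** — rescale $F_{ab}$ back to each level's own shape and add
   it to the original level. Shapes are conserved, so the block stacks on
   any neck that produces a uniform-channel pyramid.

The package implements this neck together with everything needed to verify
it end-to-end on one CPU: a baseline FPN, a single-class COCO-style
AP/AP50/AP75/AR evaluator (IoU thresholds 0.50:0.05:0.95, 101-point
interpolated AP), a deterministic generator of synthetic CT-like slices
with low-contrast elliptical lesions, and a deliberately tiny anchor-based
single-stage detector (focal loss + smooth-L1, SGD with warmup and step
drops) whose every layer carries an analytic backward pass — gradients are
verified against finite differences in the test suite.

## Worked example

```r
library(abfp)

spec    <- lesion_scene_spec(seed = 1)        # 128x128, 2 lesions, contrast 0.15
dataset <- make_lesion_dataset(spec, 200)
splits  <- split_dataset(dataset, 0.8, seed = 1)

detector <- build_detector(seed = 1)          # micro backbone + FPN + ABFP
ev_before <- predict_and_evaluate(detector, dataset, splits$test)

detector <- train_detector(detector, dataset, train_config(seed = 1),
                           indices = splits$train)
ev_after <- predict_and_evaluate(detector, dataset, splits$test)

round(detector$epoch_loss, 3)
#>  [1] 2.418 1.492 1.295 0.947 0.703 0.561 0.527 0.521 0.434 0.428 0.419 0.413
ev_before
#> <eval_result> AP 0.0000 | AP50 0.0001 | AP75 0.0000 | AR 0.0088
ev_after
#> <eval_result> AP 0.3859 | AP50 0.8439 | AP75 0.2774 | AR 0.5225
```

Training the 12-epoch schedule on 160 images takes roughly two minutes on
one CPU. The numbers say: after training, lesions are found reliably at the
loose IoU 0.5 criterion (AP50 0.84 on the 40 held-out images, versus ~0 for
the untrained detector), while strict localization (AP75) is harder — the
expected profile for low-contrast blurred-edge targets and a micro model
trained from scratch.

A thin command-line interface over the same functions is installed with the
package (`system.file("cli", "abfp.R", package = "abfp")`) with subcommands
`gen-data`, `train`, `eval`, and `selftest`.

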