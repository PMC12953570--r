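# edgewave

Building blocks, assembly and desk-scale verification for a single-stage
small-object detector aimed at crop-pest field imagery — entirely in R.

Detecting rice pests in the field is hard for generic detectors for three
compounding reasons: the insects are tiny (tens of pixels at 640×640),
morphologically similar species differ only in fine edge detail, and the
vegetation background is textured and often low-contrast against the target.
`edgewave` implements a detector family organised around four architectural
answers, each an independent toggle on a nano-scale anchor-free baseline
(stem → four CSP stages → SPPF → terminal attention → pyramid neck →
decoupled heads at strides 8/16/32):

- **MEN** (toggle A) — backbone stages whose dual-path units combine
  multi-scale adaptive pooling with an explicit edge gate,
  `E(x) = x + x ⊙ σ(H(x − P_avg(x)))`, bounded in `[x, 2x)` for
  nonnegative input.
- **BAFE** (toggle B) — a terminal block that separates frequency bands with
  the frozen orthonormal 2×2 Haar filters `½[1,1;1,1]`, `½[−1,−1;1,1]`,
  `½[−1,1;−1,1]`, `½[1,−1;−1,1]` (stride 2, no padding), then applies two
  cascaded windowed-attention stages, `softmax(QK′/√d_h + B)` over 3×3
  windows, guided by the high- and low-frequency maps in turn.
- **EM-BFPN** (toggle C) — a bidirectional neck fusing P3/P4/P5 with
  learnable nonnegative weights,
  `F = Σ max(wᵢ,0)·Fᵢ / (Σ max(wⱼ,0) + 1e−4)`, followed by multi-kernel
  depthwise enhancement with per-level kernel sets {1,3,5}/{3,5,7}/{5,7,9}.
- **SCAU** (toggle D) — an upsampler combining depthwise-separable
  convolution, grouped channel shuffle and circular multi-directional
  feature shifts (pure index permutations: value multisets are conserved
  exactly).

No deep-learning framework exists on CRAN/Bioconductor, so the package ships
a compact tape-based reverse-mode autodiff engine (gather+GEMM convolutions
over BLAS, hand-derived backward passes verified against finite differences).
On top of it sit full network assembly for all 16 ablation variants,
parameter/FLOP accounting, a synthetic pest-scene generator with YOLO-format
label I/O and deterministic largest-remainder splitting, a CPU smoke-training
loop, and COCO-style evaluation (precision, recall, mAP@50, mAP@50-95).

## Worked example

```r
library(edgewave)

# the full model (all four toggles), nano widths, 11 classes
cfg   <- ablation_config("A+B+C+D")        # or read_model_config("inst/configs/a_b_c_d.yaml")
model <- build_model(cfg, seed = 1)
budget_report(model, 640)
#> params: 4.738 M (frozen: 32)  flops: 9.46 G

# deterministic 8:1:1 split, largest-remainder rule
lengths(split_dataset(4565, c(8, 1, 1), seed = 0))
#> train   val  test
#>  3652   456   457

# a synthetic 640x640 scene with tight normalised boxes
sc <- generate_scene(scene_spec(image_size = 640, num_classes = 11, seed = 7), index = 1)
head(sc$annotations, 3)
#>   class_id        cx        cy         w         h
#> 1        4 0.8132812 0.0625000 0.0843750 0.0765625
#> 2        4 0.0953125 0.2125000 0.0796875 0.0796875
#> 3        5 0.4250000 0.2078125 0.0765625 0.0609375

# the exact Haar algebra behind the BAFE block
x <- array(0, c(1, 1, 2, 2)); x[1, 1, , ] <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
lapply(haar_decompose(x), as.numeric)
#> $approx 5   $horiz 2   $vert 1   $diag 0
```

The budget report reads: 4.74 million trainable parameters (the 32 frozen
values are the Haar filter bank and the distribution-focal bin constants)
and 9.46 GFLOPs for one 640×640 forward pass counting two operations per
multiply-accumulate. The split reproduces the published 3652/456/457
partition exactly; the single 2×2 block `[1 2; 3 4]` decomposes to
approximation 5 and directional details (2, 1, 0), conserving the input
energy 30.

Training and evaluation at desk scale:

```r
sp    <- scene_spec(96, num_classes = 3, objects_per_image = c(1, 3),
                    object_size_px = c(16, 32), contrast = "high", seed = 42)
train <- lapply(1:32, function(i) { s <- generate_scene(sp, i)
                                    list(image = s$image, annotations = s$annotations) })
tiny  <- model_config(men = TRUE, bafe = TRUE, embfpn = TRUE, scau = TRUE,
                      num_classes = 3, input_size = 96,
                      widths = c(8, 16, 16, 32, 32), neck_width = 16,
                      men_scales = list(c(2,4), c(2,4), c(2,3), c(1,2)))
model <- build_model(tiny, seed = 7)
trace <- smoke_train(model, train, train_config(epochs = 50, batch_size = 4, image_size = 96))
dets  <- predict_detections(model, lapply(train, `[[`, "image"), conf_thresh = 0.01)
evaluate_detections(dets, lapply(train, `[[`, "annotations"))
```

A command-line front end over the same functions lives at
`inst/cli/edgewave-cli.R` (`count`, `build`, `generate`, `split`,
`train-smoke`, `eval`); the 13 ablation-row configuration files ship under
`inst/configs/`.

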