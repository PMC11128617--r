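# seednet

Lightweight residual networks for maize seed variety identification from RGB
images.

Seed lot purity — whether every kernel in a lot really belongs to the variety
on the label — is assessed by classifying individual seeds. `seednet`
implements a configurable family of 50-layer bottleneck residual networks for
single-seed classification, together with everything around the model that
such a study needs: the multi-seed photograph segmentation pipeline that
produces fixed-size single-seed crops, exact parameter/MAC accounting for
every architecture variant, SGD training with stratified 5-fold
cross-validation, standard classification metrics, Grad-CAM heatmaps, and a
synthetic seed-image generator that makes the whole pipeline testable without
the original photographs.

## The model family

Starting from the classic bottleneck residual network (ResNet50), three
independent modifications are toggled by `variant_config()`:

- **ResStage** — the two early stages (bottleneck widths 64, 128) are
  reorganised into Start/Middle/End blocks so that the residual trunk carries
  a *fixed* number of activations (one per stage; four across a four-stage
  network) instead of one per block. Parameter count is preserved exactly.
- **Improved residual blocks** — each block of the two later stages (widths
  256, 512) gains *efficient channel attention* (ECA) after its first
  convolution: channel weights `ω = σ(C1D_k(GAP(x)))`, with the kernel width
  chosen adaptively, `k = |log2(C)/γ + b/γ|_odd`, γ = 2, b = 1; and its 3×3
  convolution is replaced by a *depthwise-separable* pair, cutting that
  layer's parameters from `9C²` to `9C + C²`.
- **Mixed activations** — Swish `x·σ(x)` at the stem and after the additions
  of End/improved blocks; PReLU (learnable negative slope, shared per site)
  everywhere else.

All three together cut the 6-class model from 23.52 M parameters / 4.12 GMac
to 14.12 M / 3.20 GMac — a 40% parameter reduction — while leaving every
intermediate ablation buildable and countable.

## Worked example

```r
library(seednet)

variants <- list(
  variant_config(),                                          # baseline
  variant_config(TRUE, FALSE, FALSE),                        # ResStage only
  variant_config(TRUE, TRUE, TRUE, conv2_kind = "standard3x3"),
  variant_config(TRUE, TRUE, TRUE)                           # full model
)
complexity_report(variants)
#> # A tibble: 4 × 6
#>   variant          params_raw params_M   macs_raw macs_GMac input_shape
#>   <chr>                 <dbl>    <dbl>      <dbl>     <dbl> <chr>
#> 1 ---                23520326     23.5 4120891910      4.12 3x224x224
#> 2 R--                23520326     23.5 4119687686      4.12 3x224x224
#> 3 RIA (no DS conv)   23520406     23.5 4125200390      4.13 3x224x224
#> 4 RIA                14117014     14.1 3204495878      3.2  3x224x224
```

Row 1 is the 6-class baseline: 23,520,326 trainable parameters (23.52 M at
two decimals) and 4.12 GMac for one 224×224 forward pass. The ResStage
rewrite (row 2) is parameter-neutral by construction. Adding attention and
the mixed activations without the depthwise-separable substitution (row 3)
costs ~0.01 GMac; the substitution itself (row 4) removes 9.40 M parameters
and 0.92 GMac.

Training and evaluating on synthetic crops:

```r
spec <- synthetic_spec(n_per_class = 40, image_size = 48, rng_seed = 11)
ds   <- generate_crop_dataset(spec)              # 240 labelled crops
fit  <- train_model(build_model(variant_config(TRUE, TRUE, TRUE), seed = 5),
                    ds, train_config(epochs = 5, batch_size = 16,
                                     learning_rate = 0.02,
                                     lr_schedule = "cosine", clip_norm = 5,
                                     rng_seed = 9))
evaluate_model(fit, ds)$accuracy                 # resubstitution accuracy
cam <- grad_cam(fit$model, ds$images[[1]], ds$labels[1])
autoplot(cam)
```

Segmenting a multi-seed scene:

```r
scene <- generate_scene(synthetic_spec(rng_seed = 7))
crops <- segment_scene(scene$image)   # Otsu -> morphology -> centroid crops
crop_manifest(crops)
```

A thin command-line front end over the same functions lives in
`inst/cli/seednet.R` (`count`, `build`, `synth-crops`, `synth-scenes`,
`segment`, `train`, `eval`, `gradcam`).

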