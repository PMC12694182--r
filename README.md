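# holostain

Label-free detection of rare tumor cells in liquid-cytology smears by
**virtual staining of off-axis digital holograms**, for researchers working
on quantitative phase imaging (QPI) and learned image-to-image translation
in cytology.

Circulating tumor cells occur at PBMC:tumor ratios down to 1000:1.
Holography sees every cell label-free but produces phase maps clinicians do
not read; fluorescence sees the tumor cells but requires labeling.
`holostain` implements the full computational chain that links the two:

1. **Simulation** — synthetic smears of two cell populations (small
   low-phase PBMC-like cells, large high-phase HCT116-like cells, mixed at
   10:1 / 50:1 / 1000:1 across donors) rendered as spherical-cap phase
   profiles; off-axis holograms `|O + R|^2` with a tilted plane reference,
   polynomial background aberration, sensor noise; paired fluorescence with
   PSF blur, background, and excitation bleed-through into PBMCs.
2. **Reconstruction** — Fourier demodulation of the +1 order,
   angular-spectrum propagation
   `H = exp(i 2 pi z sqrt(1/lambda^2 - fx^2 - fy^2))`, numerical autofocus
   by coarse-to-fine sharpness search, and aberration correction against a
   sample-free reference hologram.
3. **Preprocessing** — one-pixel-shift phase gradients
   `g_x = phi[i,j] - phi[i,j-1]`, `g_y = phi[i,j] - phi[i-1,j]` as extra
   input channels; Otsu + morphology fluorescence segmentation; a
   single-channel stain target (`0.5 * normalized phase` outside the cancer
   mask, `1.0` inside); stratified 3:1:1 train/val/test splits with
   quarantined unseen donors.
4. **U-net virtual staining** — four encoder blocks (3x3 conv + ReLU,
   channels C..8C, average pooling), four decoder blocks (bilinear
   upsampling, 1x1 skip projection, concatenation, channel reduction by 4),
   trained with MAE loss `1/m * sum|y_i - f(x_i)|` and Adam. Forward and
   backward passes are implemented natively (im2col + BLAS).
5. **Evaluation** — SSIM against targets, plus cell-level counting:
   predicted components matched to tumor cells by gated greedy centroid
   matching, pooled TP/FN/TN/FP, and precision = TP/(TP+FP),
   recall = TP/(FN+TP), F1 = their harmonic mean, accuracy =
   (TP+TN)/(TP+TN+FP+FN).

## Worked example

The reduced desk-scale pipeline (2 donors x 3 ratios x 20 crops of 128 px,
reduced U-net with 16 base channels, 30 epochs; about 13 minutes on one
CPU):

```r
library(holostain)
res <- run_pipeline(pipeline_config(out_dir = "run", seed = 1), verbose = TRUE)
res$report
#> <metrics_report> split 'test', 24 images
#>   SSIM mean: 0.98309
#>   counts: TP 7 FN 0 TN 121 FP 0
#>   precision 1  recall 1  F1 1  accuracy 1
glance_history(res$history)
#> # A tibble: 1 × 4
#>   epochs_run best_epoch best_val_mae final_train_mae
#>        <int>      <int>        <dbl>           <dbl>
#> 1         30         26      0.00985         0.00874
```

Reading the report: across the 24 test crops the ground truth contained 7
tumor cells and 121 PBMCs; every tumor cell was stained and matched (TP 7,
FN 0) and no PBMC was falsely stained (FP 0), giving pooled accuracy 1.0,
with mean SSIM 0.983 between predicted stains and targets. On this
synthetic benchmark the two populations are separable by size and phase, so
these numbers certify that the pipeline is internally consistent end to
end — not that clinical smears would score this well.

Individual stages are exposed as plain functions
(`sample_cell_field()`, `synthesize_hologram()`, `reconstruct_phase()`,
`gradient_channels()`, `fluo_to_mask()`, `compose_target()`,
`build_model()`, `train_unet()`, `predict_stain()`, `evaluate_run()`), and
a thin command-line wrapper lives in `inst/cli/holostain`
(`holostain simulate|train|evaluate|predict|pipeline`).

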