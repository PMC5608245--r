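# dynpet — dynamic PET reconstruction with MLEM and a stacked sparse autoencoder

Frame-by-frame maximum-likelihood reconstruction of dynamic positron
emission tomography (PET) is noise-limited: short early frames collect few
coincidence events, and unregularized MLEM amplifies that scarcity into
checkerboard noise.  `dynpet` implements a deep patch-fusion pipeline for
this problem, together with everything needed to train and evaluate it with
no external data:

* a **synthetic dynamic-phantom generator** — multi-region 2-D objects with
  configurable time-activity curves (constant, mono-exponential decay
  `A·e^(−λt)`, gamma-variate uptake `A·t^α·e^(−βt)`);
* an exact **parallel-beam projector** (Siddon-style ray/pixel intersection
  lengths) with count-budget calibration and Poisson sampling;
* classical **MLEM** per frame, `x ← (x/s) ⊙ Gᵀ(y ⊘ Gx)`, `s = Gᵀ1`, with
  monotone Poisson log-likelihood;
* a **stacked sparse autoencoder** that maps the 7×7 patches of frames
  `i−1, i, i+1` of the MLEM series (147 inputs) through hidden layers of
  200 and 100 sigmoid units to the ground-truth 49-pixel patch of frame
  `i`.  Layers are pretrained greedily — restricted-Boltzmann-machine
  (CD-1) initialization, then backpropagation on the sparse objective
  `‖o−x‖² + α₁‖W‖_F + α₂·KL(ρ̂‖ρ₀)` — and the stack is fine-tuned
  end-to-end by mean-squared error;
* a Gaussian-weighted **patch sweep** assembling the fused frame estimate,
  and per-ROI **SNR / bias / variance** metrics
  (`SNR = 20·log₁₀(255/RMSE)`).

It is aimed at researchers studying learned reconstruction/denoising for
emission tomography who want a small, fully reproducible, testable
reference implementation of the MLEM+SAE approach.

## Worked example

Simulate one brain-like phantom at a 5×10⁴-count budget and reconstruct it
with MLEM:

```r
library(dynpet)
G  <- build_system_matrix(n_angles = 64, n_radial = 64, grid_size = c(64, 64))
ph <- make_dynamic_phantom("brain_like", c(64, 64), n_frames = 9,
                           n_regions = 3, seed = 7)
ph <- calibrate_phantom(G, ph, total_counts = 5e4)   # truth in count units
sino <- sample_poisson(forward_project(G, ph), seed = 7)
rec  <- mlem_reconstruct(G, sino, n_iterations = 50)
roi_report(rec$images[5], ph$frames[5], roi_masks(ph))
#>     roi frame snr_db     bias variance n_pixels n_excluded
#> 1  ROI1     1 -0.797 -0.07386     4.09     1016          0
#> 2  ROI2     1 -2.146 -0.05129     3.23     1460          0
#> 3  ROI3     1 -3.630  0.00964     2.31      188          0
#> 4 Total     1 -1.816 -0.05560     3.52     2664          0
```

At ~5 600 counts per frame the MLEM image is heavily degraded (low SNR,
large within-region variance).  The full pipeline — 12 training phantoms,
SAE training, patch fusion of 4 held-out test sets — runs in a few minutes:

```r
res <- run_experiment(default_config(seed = 1))
res$summary
#>     method mean_snr_db mean_abs_bias mean_variance
#> 1     MLEM        3.65        0.0676         1.400
#> 2 MLEM+SAE       16.91        0.0648         0.458
```

The fused images gain ≈13 dB Total-ROI SNR over frame-by-frame MLEM at
this counting rate, with a three-fold lower variance index and comparable
absolute bias; per-set metrics are in `res$metrics`.  The gain comes from
the low-count regime: with far more counts, or with very small training
corpora, plain MLEM can be the better estimator — the package makes such
comparisons one function call.

A thin CLI wraps the same pipeline
(`inst/scripts/dynpet run --config cfg.yaml --out runs/exp1`), with stage
results cached by configuration hash so sweeps reuse simulations.

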