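# sepsnet — accelerated pure shift NMR reconstruction

Pure shift NMR collapses J-coupling multiplets into singlets — one line per
chemical shift — but interferogram-mode acquisition assembles the FID chunk
by chunk, so high resolution costs hours of spectrometer time. Non-uniform
sampling (NUS) acquires only a subset of chunks; the price is severe
undersampling artifacts that can bury weak peaks entirely. This package is
for NMR spectroscopists and methods developers who want to study and run the
reconstruction side of that trade on synthetic (and externally processed)
1D pure-shift spectra.

It provides, natively in R:

* **Simulator** — chunked pure-shift FIDs from Lorentzian singlet
  parameters, `s(t_k) = Σ_j A_j exp(i(2π f_j t_k + φ_j)) exp(−π lw_j t_k)`,
  with chunk-wise NUS (93 chunks by default; keeping {5, 7, 15, 23} chunks
  gives the standard 5.4 / 7.5 / 16.1 / 24.7 % levels), complex Gaussian
  noise, Fourier processing and unit-max normalized (input, ideal label)
  training pairs.
* **SE-PSNet** — a lightweight 1D residual convolutional network with
  squeeze-and-excitation channel attention (entry CBLD block, six SE
  residual blocks with kernels 9/21 and C = 32 channels, 1×1 output block;
  266,051 parameters ≈ 1.03 MB, ≈ 2.12 billion multiply-adds per forward
  pass at N = 8192). Forward pass, backpropagation, batch norm, SE gates and
  Adam are implemented in the package (RcppArmadillo convolutions); there is
  no deep-learning framework dependency.
* **IST-S baseline** — compressed-sensing reconstruction by iterative soft
  thresholding (500 iterations, geometric threshold decay 0.99) with exact
  chunk-wise data consistency.
* **Evaluation** — RMSD, peak picking/matching, peak-intensity and integral
  R² (squared Pearson correlation), false positive/negative counts, and
  multi-trial summaries.

## Worked example

Simulate a 16.1% NUS acquisition in the scaled-down world and compare the
raw undersampled spectrum and the IST-S baseline against the ideal label:

```r
library(sepsnet)
cfg <- sim_config("tiny")
set.seed(42)
peaks <- sample_peak_set(cfg)
fid   <- synthesize_fid(peaks, cfg$acq)
sched <- make_nus_schedule(cfg$acq$n_chunks, 15)
print(sched)
#> NUS schedule: 15 of 93 chunks (16.1%), scheme first-fixed

pair <- make_training_pair(peaks, cfg$acq, sched, sigma = 0.01)
evaluate_reconstruction(pair$label, pair$input)    # raw NUS vs ideal
#> RMSD 0.1883 (peak regions 0.1704); R2 intensity 0.9235, integral 0.9546; FP 90, FN 2

ist <- ist_s_reconstruct(apply_nus(fid, sched), sched)
evaluate_reconstruction(pair$label, ist)           # IST-S vs ideal
#> RMSD 0.1017 (peak regions 0.1155); R2 intensity 0.9818, integral 0.9908; FP 112, FN 1
```

The raw undersampled spectrum deviates from the ideal label by RMSD 0.19
with 90 spurious peaks above 1% of the maximum; IST-S halves the deviation
and raises the peak-intensity correlation to 0.98. The network is trained
the same way a practitioner would use it:

```r
ds  <- generate_dataset(350, cfg, seed = 3)        # synthetic pairs
net <- psnet_config(n_input = 512, channels = 16)  # scaled-down architecture
fit <- sepsnet(ds, net, epochs = 16, batch_size = 8, lr = 1e-2, lr_end = 1e-3)
rec <- predict(fit, pair$input$values)             # reconstructed spectrum
```

and the full-scale architecture is inspected with:

```r
print(build_model(psnet_config(), seed = 1))
#> Pure-shift NMR reconstruction network (SE attention)
#>   input length 8192, 32 channels, kernels 9/21, 6 residual blocks
#>   266,051 learnable parameters (1.01 MB at 4 bytes), 2.12 billion conv multiply-adds
#>   untrained (initial weights)
```

A shell entry point wrapping the same functions (subcommands `simulate`,
`train`, `reconstruct`, `baseline`, `evaluate`, each writing a JSON run
manifest) is installed at `inst/cli/sepsnet.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/sepsnet.R", package="sepsnet"))') \
    simulate --n 100 --seed 1 --profile tiny --out dataset.rds
```

## Acceptance script

`scripts/acceptance.R` recomputes the architecture-accounting headline
figures from scratch — it instantiates the default network, enumerates every
convolution layer for the multiply-add count, and walks every weight array
for the learnable-scalar count (model size at 4 bytes per scalar):

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope notes

The simulator draws ideal singlets; chunk sidebands, baseline distortion
and phase errors of real spectrometer data are not emulated, and pulse-
sequence simulation, ppm referencing and vendor raw formats are out of
scope. See the methods vignette
(`vignettes/pure-shift-reconstruction.Rmd`) for the model, the simulator's
stated world, numerical choices and known limitations.
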