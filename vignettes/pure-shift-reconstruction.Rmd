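---
title: "Reconstructing undersampled pure shift NMR spectra: model, simulator and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing undersampled pure shift NMR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsnet)
```

## The problem

Pure shift NMR collapses scalar-coupling multiplets into singlets, one line
per chemical shift, at the cost of an extra pseudo-dimension: in
interferogram-mode acquisition (e.g. PSYCHE) the free induction decay is
assembled chunk by chunk from successive increments, so experiment time
scales with the number of chunks. Non-uniform sampling (NUS) shortens the
experiment by acquiring only a subset of chunks, but Fourier transforming the
chunk-zeroed FID scatters every peak into undersampling artifacts that can
bury weak signals entirely.

This package implements three things around that problem:

1. a **physics-driven simulator** of chunked pure-shift FIDs and their
   undersampled spectra (`sim_config()`, `generate_dataset()`);
2. a **lightweight 1D residual convolutional network with
   squeeze-and-excitation (SE) channel attention** that learns, from
   synthetic data alone, the mapping from an undersampled real spectrum to
   its artifact-free fully sampled counterpart (`sepsnet()`);
3. a classical **compressed-sensing baseline** (iterative soft thresholding
   with chunk-wise data consistency, `ist_s_reconstruct()`) and
   **quantitative evaluation** tools (`rmsd()`, `match_and_correlate()`).

## Signal model and simulator world

The ideal pure-shift FID of a mixture of singlets is

$$ s(t_k) \;=\; \sum_j A_j \, e^{\,i(2\pi f_j t_k + \phi_j)}\,
   e^{-\pi\,\mathrm{lw}_j\, t_k}, \qquad t_k = k\,\Delta t , $$

with per-peak amplitude $A_j$, offset frequency $f_j$ (Hz), full Lorentzian
linewidth at half height $\mathrm{lw}_j$ (Hz) and zero-order phase $\phi_j$.
Because the supervised labels are ideal singlet spectra, concatenated chunks
of this model form a continuous decaying sinusoid; chunk-boundary artifacts
(sidebands from residual J-modulation) are one artifact class the simulator
does **not** emulate by default — a deliberate simplification, since the
exact chunk-concatenation arithmetic of real interferogram processing
(chunk duration versus increment, dropped points) varies between platforms.

The default world fixes the geometry at **93 chunks of 64 complex points**
(5952 points, zero-filled to an 8192-point transform). Ninety-three is not
arbitrary: it is the unique chunk count in a wide range that reconciles the
standard quoted NUS levels 5.4%, 7.5%, 16.1% and 24.7% with integer sampled
chunk counts {5, 7, 15, 23} and an acceleration factor of 6.2 = 93/15 (the
test suite performs this brute-force search). Chunk-wise NUS keeps whole
chunks or zeroes them; schedules are uniform random without replacement with
chunk 0 always sampled (`make_nus_schedule()`), because the first chunk
anchors the overall intensity scale and no standard scheduler prescription exists
to copy.

Random worlds are drawn as follows (defaults, all exposed in
`sim_config()`):

| parameter | default | why |
|---|---|---|
| peak count | uniform 3–25 | sparse to crowded spectra |
| frequencies | uniform over central 90% of the window, ≥ 2 bins apart | avoids edge wrap and degenerate overlap |
| amplitudes | log-uniform on [0.02, 1] | 50× dynamic range, the hardest case quoted for real samples |
| linewidths | uniform 1–6 Hz | typical proton pure-shift lines |
| phases | 0 | labels are phased; a small-phase option exists |
| noise | complex Gaussian, σ uniform on [0, 0.05]·max\|FID\| | noise-robust training without drowning weak peaks |

Each training pair transforms (zero-fill, FFT, centre zero frequency, real
part) a noisy chunk-masked FID into the network input and the noiseless fully
sampled FID into the label; both are independently scaled to unit maximum
absolute value, and the scale is kept as `norm_factor` for de-normalization.

The **many-to-single (M-to-S)** option (`m_to_s` in `generate_dataset()`)
pairs several inputs with different schedules and NUS levels to one shared
ideal label, which is how a single model is made robust across sampling
schemes.

## Network

`psnet_config()` defaults describe the full-scale architecture: input length
N = 8192, C = 32 channels, entry kernel 9, residual kernels 21, six SE
residual blocks, SE bottleneck C/2, dropout 0.1, leaky-ReLU slope 0.01.
Each residual block is CBLD → SE gate → CBLD with an additive skip; the SE
gate squeezes each channel to its mean, passes the C-vector through a
two-layer bottleneck (ReLU, then sigmoid) and rescales the channels by the
resulting (0, 1) gates — channel attention that costs almost nothing
(6.4k of 266k parameters) because it acts on 1×1 summaries. The output block
is a 1×1 convolution plus batch normalization with no activation or dropout,
so peak intensities are not clipped.

Accounting conventions (`count_flops()`, `count_parameters()`): the headline
multiply-add count sums $N \cdot C_{in} \cdot C_{out} \cdot K$ over
convolutions only (2.117 billion at N = 8192); SE, bias and normalization
terms are reported separately. Model size is learnable scalars × 4 bytes
(single precision convention), using MiB (1024²): 266,051 scalars → 1.015 MB.
Both figures agree with the commonly quoted 2.13 billion / 1.03 MB for this
architecture to within ~1.5%.

Because no neural-network stack exists in the target R environment, the
forward pass, backpropagation (verified against finite differences in the
test suite), batch normalization, SE gates, dropout and the Adam optimizer
are implemented natively, with the convolutions running as im2col + GEMM
through BLAS via RcppArmadillo. Training minimizes mean squared error — the
architecture description does not prescribe a loss, and MSE is the natural choice
for intensity-faithful regression. Biases of convolutions feeding directly
into batch normalization are redundant (BN subtracts the batch mean); they
are retained for architectural fidelity and their gradients are exactly
zero.

Numerical choices: batch-norm ε = 1e-5, momentum 0.1 on running statistics
(used at inference); variance-scaling fan-in weight initialization under a
user seed; model selection by lowest validation loss; training aborts with a
diagnostic on non-finite loss. Inference is deterministic and independent of
batch composition.

## IST-S baseline

The compressed-sensing reference carries a sparse spectrum estimate and
alternates (i) inverse FFT and substitution of the measured samples into the
sampled chunks (data consistency — the "S" of IST-S), (ii) FFT back, and
(iii) soft thresholding of the complex spectrum's magnitude (phase
preserved) at $\tau_k = \rho^k \max|S_0|$. Defaults are 500 iterations and
ρ = 0.99. Two numerical choices matter. First, the quoted "threshold value
of 0.99" is interpreted as this per-iteration geometric decay ratio
initialized at the maximum spectral magnitude — standard
decreasing-threshold IST practice; whether the original operates on the real
spectrum or the complex magnitude is not documented, and magnitude
thresholding was chosen because it is phase-safe. Second, the spectrum
estimate is *not* re-truncated to the acquired time support each iteration:
re-imposing the zero-fill region repeatedly re-broadens the sparse estimate
and leaves a systematic peak-amplitude deficit (~17% on a 50%-sampled
single-peak test), whereas the residual-substitution form debiases
amplitudes to within a few percent as the threshold decays.

## Evaluation

`rmsd()` is computed over all bins of the unit-max normalized spectra (with
a peak-region variant). Peak intensity fidelity is the squared Pearson
correlation between matched peak heights: reference peaks (local maxima
above 1% of the maximum, ≥ 2 bins apart) are matched to the nearest
reconstructed peak within 2 bins; unmatched reference peaks count as false
negatives and surplus reconstructed peaks as false positives. The 1%
threshold deliberately retains peaks as weak as ~2% of the strongest — the
weak-peak regime that motivates attention gating — and the tolerance/window
defaults (2 bins match, ±5 bins integrals) are exposed because no canonical
values exist. `summarize_trials()` reports mean ± sample SD over repeated
random trials (20 by convention).

## Scaled-down test world

Full-scale training (4k pairs of length 8192, C = 32) needs a GPU-class
budget; on the single CPU available to the test suite it would take hours.
The test suite therefore uses a **tiny profile fixed in advance by compute
budget, not by results**: every length is divided by 16 (93 chunks of 4
points, 250 Hz window, 512-point transform — identical chunk duration of
16 ms and identical linewidth-in-bins), C = 16 channels with the same six
SE-block topology, 350 training pairs, 16 epochs, Adam at 1e-2 decaying
linearly to 1e-3 with batch 8 (the smaller batch and larger step compensate
for the far shorter step budget; the full-scale defaults remain a constant
1e-3 with batch 64). A green reconstruction test
in this world establishes that the implementation learns the mapping it
should; it does **not** establish the full-scale figures, which require the
full compute. The acceptance checks assert the reference full-scale
reconstruction quality numbers against this scaled world at their stated
tolerances and are reported honestly either way.

## Known limitations

* The simulator draws ideal singlets; chunk sidebands, baseline distortion,
  phase errors and solvent signals present in real spectra are absent, so
  synthetic scores overestimate real-world performance.
* Frequencies are continuous (peaks need not be bin-centred), but ppm
  referencing and vendor raw formats are out of scope; externally processed
  spectra enter via delimited text or minimal JCAMP-DX.
* One model serves one sampling regime unless trained with M-to-S mixing;
  generalization across very different NUS densities still degrades.
* Multi-dimensional pure shift data would be reconstructed line by line;
  no dedicated support is provided.
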