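# Shared fixtures. Everything is generated in code; the "micro" network is
# small enough for sub-second training smoke tests, the "tiny" world is the
# 16x-scaled simulation used by the compute-heavy acceptance checks.

micro_acq <- function() acq_params(spectral_width_hz = 100, chunk_len = 4,
                                   n_chunks = 24, n_ft = 128)

micro_sim_config <- function(n_keep = 12L, ...) {
  sim_config(acq = micro_acq(), n_peaks = c(2L, 4L), min_sep_bins = 4,
             n_keep = n_keep, ...)
}

micro_net <- function(dropout = 0, ...) {
  psnet_config(n_input = 128L, channels = 4L, k_entry = 3L, k_res = 5L,
               n_res_blocks = 1L, se_reduction = 2L, dropout = dropout, ...)
}

# Direct DFT oracle, independent of stats::fft and of fid_to_spectrum:
# plain O(n^2) sum with centered bin ordering.
oracle_dft_centered <- function(x, n_ft) {
  x <- c(x, complex(n_ft - length(x)))
  k <- 0:(n_ft - 1)
  out <- vapply(k, function(j)
    sum(x * exp(-2i * pi * j * k / n_ft)), complex(1))
  half <- n_ft %/% 2
  out[c((half + 1):n_ft, 1:half)]
}
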