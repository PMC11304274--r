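#' IST-S configuration
#'
#' Iterative soft thresholding with a geometrically decreasing threshold: at
#' iteration k the spectrum is soft-thresholded at
#' `threshold_factor^k * max|initial spectrum|`.
#'
#' @param n_iterations number of iterations (default 500).
#' @param threshold_factor per-iteration geometric decay ratio in (0, 1)
#'   (default 0.99).
#' @export
ist_config <- function(n_iterations = 500L, threshold_factor = 0.99) {
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (threshold_factor <= 0 || threshold_factor >= 1)
    stop("threshold_factor must lie in (0, 1)")
  structure(list(n_iterations = n_iterations,
                 threshold_factor = threshold_factor),
            class = "ist_config")
}

#' Compressed-sensing reconstruction of a chunk-undersampled FID (IST-S)
#'
#' Classical sparsity-promoting baseline. Each iteration (1) inverse
#' transforms the current spectrum estimate to the time domain and
#' substitutes the measured samples into all sampled chunks (data
#' consistency), (2) Fourier transforms back, and (3) soft-thresholds the
#' complex spectrum's magnitude (phase preserved) at the geometrically
#' decaying level. The sparse spectrum estimate is carried across
#' iterations (the zero-fill region is not re-truncated, so peak amplitudes
#' debias as the threshold decays). The returned spectrum is the real part
#' of the transform of the final, data-consistent estimate, unit-max
#' normalized.
#'
#' @param nus_fid an `nmr_fid` that is zero outside the sampled chunks
#'   (see [apply_nus()]).
#' @param schedule the [make_nus_schedule()] used to undersample.
#' @param config an [ist_config()].
#' @param n_ft transform length (default: geometry's `n_ft`).
#' @return an `nmr_spectrum` with attributes `"tau"` (the threshold
#'   schedule) and `"fid"` (the final time-domain estimate).
#' @export
ist_s_reconstruct <- function(nus_fid, schedule, config = ist_config(),
                              n_ft = nus_fid$acq$n_ft) {
  stopifnot(inherits(nus_fid, "nmr_fid"), inherits(schedule, "nus_schedule"),
            inherits(config, "ist_config"))
  if (length(schedule$sampled) < 1) stop("schedule samples no chunks")
  if (schedule$n_chunks != nus_fid$acq$n_chunks)
    stop("schedule geometry does not match the FID")
  acq <- nus_fid$acq
  n <- acq$n_points
  sampled_pts <- unlist(lapply(schedule$sampled, function(c)
    (c * acq$chunk_len + 1L):((c + 1L) * acq$chunk_len)))
  measured <- nus_fid$samples[sampled_pts]
  pad <- function(s) c(s, complex(n_ft - length(s)))
  tau0 <- max(Mod(stats::fft(pad(nus_fid$samples))))
  tau <- tau0 * config$threshold_factor^seq_len(config$n_iterations)
  sp <- complex(n_ft)
  resid <- complex(n)
  for (k in seq_len(config$n_iterations)) {
    est <- stats::fft(sp, inverse = TRUE)[seq_len(n)] / n_ft
    resid[] <- 0
    resid[sampled_pts] <- measured - est[sampled_pts]   # data consistency
    sp <- sp + stats::fft(pad(resid))
    mag <- Mod(sp)
    sp <- sp * pmax(1 - tau[k] / pmax(mag, .Machine$double.eps), 0)
  }
  est <- stats::fft(sp, inverse = TRUE)[seq_len(n)] / n_ft
  est[sampled_pts] <- measured
  out_fid <- structure(list(samples = est, acq = acq), class = "nmr_fid")
  spec <- fid_to_spectrum(out_fid, n_ft)
  attr(spec, "tau") <- tau
  attr(spec, "fid") <- out_fid
  spec
}
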