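#' Acquisition geometry for a chunked interferogram pure-shift FID
#'
#' Interferogram-mode pure shift experiments assemble the free induction decay
#' (FID) chunk by chunk: each t1 increment contributes one short contiguous
#' block of `chunk_len` complex points, and `n_chunks` concatenated blocks
#' form the full pure-shift FID. Non-uniform sampling (NUS) omits whole
#' chunks, not individual points.
#'
#' @param spectral_width_hz total sweep width in Hz; the dwell time is its
#'   reciprocal.
#' @param chunk_len complex points per chunk.
#' @param n_chunks total number of chunks (sampled plus omitted).
#' @param n_ft Fourier transform length after zero filling; must be at least
#'   `chunk_len * n_chunks`.
#' @return an object of class `acq_params`.
#' @examples
#' acq_params()                      # default world: 93 x 64 points, FT 8192
#' acq_params(250, 4, 93, 512)      # scaled-down world for quick experiments
#' @export
acq_params <- function(spectral_width_hz = 4000, chunk_len = 64,
                       n_chunks = 93, n_ft = 8192) {
  stopifnot(spectral_width_hz > 0, chunk_len >= 1, n_chunks >= 1, n_ft >= 1)
  chunk_len <- as.integer(chunk_len)
  n_chunks <- as.integer(n_chunks)
  n_ft <- as.integer(n_ft)
  if (chunk_len * n_chunks > n_ft)
    stop("n_ft (", n_ft, ") must be >= chunk_len * n_chunks (",
         chunk_len * n_chunks, ")")
  structure(list(spectral_width_hz = spectral_width_hz,
                 chunk_len = chunk_len, n_chunks = n_chunks, n_ft = n_ft,
                 dwell_s = 1 / spectral_width_hz,
                 n_points = chunk_len * n_chunks),
            class = "acq_params")
}

#' Construct a set of Lorentzian singlet parameters
#'
#' A pure shift spectrum is modelled as a sum of Lorentzian singlets, one per
#' chemical site. Each peak is parameterised by its offset frequency within
#' the spectral window, a relative amplitude, the full linewidth at half
#' height, and a zero-order phase.
#'
#' @param freq_hz,amplitude,lw_hz,phase_rad equal-length numeric vectors.
#' @return a `peak_set` (a `data.frame` with one row per peak).
#' @export
peak_set <- function(freq_hz, amplitude, lw_hz = 1, phase_rad = 0) {
  n <- length(freq_hz)
  if (n < 1) stop("a peak_set must contain at least one peak")
  df <- data.frame(freq_hz = as.numeric(freq_hz),
                   amplitude = rep_len(as.numeric(amplitude), n),
                   lw_hz = rep_len(as.numeric(lw_hz), n),
                   phase_rad = rep_len(as.numeric(phase_rad), n))
  if (any(!is.finite(as.matrix(df)))) stop("peak parameters must be finite")
  if (any(df$amplitude <= 0)) stop("amplitudes must be > 0")
  if (any(df$lw_hz < 0)) stop("linewidths must be >= 0")
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Simulator configuration
#'
#' Bundles the acquisition geometry with the random-peak distribution and
#' noise ranges used to draw synthetic training worlds. The `"default"`
#' profile is the full-scale world (93 chunks of 64 points, FT length 8192,
#' up to 25 peaks with a 50x amplitude dynamic range); `"tiny"` is a
#' 16x-reduced world with the same chunk duration (16 ms) and the same
#' linewidth-to-bin ratios, intended for CPU-budget tests.
#'
#' @param profile `"default"` or `"tiny"`.
#' @param acq an [acq_params()] object.
#' @param n_peaks integer range (min, max) for the peak count per draw.
#' @param freq_frac peaks are placed uniformly over this central fraction of
#'   the spectral window.
#' @param min_sep_bins minimum separation between drawn peak frequencies, in
#'   spectral bins.
#' @param amp_range amplitudes are drawn log-uniformly over this range; the
#'   ratio of its endpoints caps the dynamic range (default 50x).
#' @param lw_range linewidth range in Hz.
#' @param phase_range zero-order phase range in radians.
#' @param sigma_range time-domain noise standard deviation, as a fraction of
#'   the maximum FID magnitude; drawn uniformly per pair.
#' @param n_keep admissible sampled-chunk counts; one is drawn per pair. The
#'   default `15` of 93 chunks is the 16.1% NUS level.
#' @param scheme NUS schedule scheme, see [make_nus_schedule()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(profile = c("default", "tiny"), acq = NULL,
                       n_peaks = c(3L, 25L), freq_frac = 0.9,
                       min_sep_bins = 2, amp_range = c(0.02, 1),
                       lw_range = c(1, 6), phase_range = c(0, 0),
                       sigma_range = c(0, 0.05), n_keep = 15L,
                       scheme = "first-fixed") {
  profile <- match.arg(profile)
  if (is.null(acq))
    acq <- if (profile == "tiny") acq_params(250, 4, 93, 512) else acq_params()
  if (profile == "tiny" && missing(n_peaks)) n_peaks <- c(3L, 10L)
  if (profile == "tiny" && missing(min_sep_bins)) min_sep_bins <- 4
  check_range <- function(r, name, pos = FALSE) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2])
      stop("invalid range for ", name)
    if (pos && r[1] <= 0) stop(name, " must be strictly positive")
  }
  check_range(n_peaks, "n_peaks"); check_range(amp_range, "amp_range", TRUE)
  check_range(lw_range, "lw_range"); check_range(phase_range, "phase_range")
  check_range(sigma_range, "sigma_range")
  if (n_peaks[1] < 1) stop("n_peaks must be >= 1")
  if (any(n_keep < 1) || any(n_keep > acq$n_chunks))
    stop("n_keep out of range [1, n_chunks]")
  structure(list(profile = profile, acq = acq,
                 n_peaks = as.integer(n_peaks), freq_frac = freq_frac,
                 min_sep_bins = min_sep_bins, amp_range = amp_range,
                 lw_range = lw_range, phase_range = phase_range,
                 sigma_range = sigma_range, n_keep = as.integer(n_keep),
                 scheme = scheme, dynamic_range_cap = amp_range[2] / amp_range[1]),
            class = "sim_config")
}

#' Draw a random peak set from a simulator configuration
#'
#' Peak count is uniform over `config$n_peaks`; frequencies are uniform over
#' the central `freq_frac` of the window, redrawn until all pairwise
#' separations exceed `min_sep_bins`; amplitudes are log-uniform over
#' `amp_range` (so the max/min ratio never exceeds the configured dynamic
#' range cap); linewidths and phases are uniform over their ranges. Uses the
#' R random number generator: call `set.seed()` beforehand for reproducible
#' draws.
#'
#' @param config a [sim_config()].
#' @return a [peak_set()].
#' @export
sample_peak_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  acq <- config$acq
  n <- if (config$n_peaks[1] == config$n_peaks[2]) config$n_peaks[1] else
    sample(config$n_peaks[1]:config$n_peaks[2], 1)
  half <- config$freq_frac * acq$spectral_width_hz / 2
  bin_hz <- acq$spectral_width_hz / acq$n_ft
  min_sep_hz <- config$min_sep_bins * bin_hz
  freq <- numeric(0)
  tries <- 0L
  while (length(freq) < n) {
    f <- stats::runif(1, -half, half)
    if (!length(freq) || min(abs(freq - f)) >= min_sep_hz) {
      freq <- c(freq, f)
    } else {
      tries <- tries + 1L
      if (tries > 10000L)
        stop("cannot place ", n, " peaks with min_sep_bins = ",
             config$min_sep_bins, " in this window")
    }
  }
  la <- log(config$amp_range)
  amp <- exp(stats::runif(n, la[1], la[2]))
  lw <- stats::runif(n, config$lw_range[1], config$lw_range[2])
  ph <- stats::runif(n, config$phase_range[1], config$phase_range[2])
  peak_set(freq, amp, lw, ph)
}

#' Synthesize a complex pure-shift FID from Lorentzian peak parameters
#'
#' The ideal chunked pure-shift FID of singlets is a continuous sum of
#' decaying complex exponentials sampled at the dwell time:
#' \deqn{s(t_k) = \sum_j A_j \exp(i(2\pi f_j t_k + \phi_j))
#'   \exp(-\pi\, \mathrm{lw}_j\, t_k),\qquad t_k = k\,\Delta t,}
#' where `lw` is the full Lorentzian linewidth at half height in Hz. The
#' signal is additive over peaks.
#'
#' @param peaks a [peak_set()].
#' @param acq an [acq_params()].
#' @return an object of class `nmr_fid` (complex samples plus geometry).
#' @export
synthesize_fid <- function(peaks, acq) {
  stopifnot(inherits(peaks, "peak_set"), inherits(acq, "acq_params"))
  if (any(abs(peaks$freq_hz) >= acq$spectral_width_hz / 2))
    stop("peak frequency outside the spectral window (+-sw/2)")
  t <- (seq_len(acq$n_points) - 1) * acq$dwell_s
  s <- complex(real = numeric(acq$n_points), imaginary = numeric(acq$n_points))
  for (j in seq_len(nrow(peaks))) {
    s <- s + peaks$amplitude[j] *
      exp(1i * (2 * pi * peaks$freq_hz[j] * t + peaks$phase_rad[j])) *
      exp(-pi * peaks$lw_hz[j] * t)
  }
  structure(list(samples = s, acq = acq), class = "nmr_fid")
}

#' Build a chunk-wise NUS schedule
#'
#' @param n_chunks total chunk count.
#' @param n_keep number of chunks to sample, `1 <= n_keep <= n_chunks`. The
#'   NUS level is `n_keep / n_chunks`.
#' @param scheme `"first-fixed"` always samples chunk 0 (which anchors the
#'   overall intensity) and draws the rest uniformly without replacement;
#'   `"uniform"` draws all chunks uniformly without replacement.
#' @return a `nus_schedule`: strictly increasing 0-based chunk indices.
#'   Deterministic under `set.seed()`.
#' @export
make_nus_schedule <- function(n_chunks, n_keep,
                              scheme = c("first-fixed", "uniform")) {
  scheme <- match.arg(scheme)
  n_chunks <- as.integer(n_chunks); n_keep <- as.integer(n_keep)
  if (n_keep < 1 || n_keep > n_chunks)
    stop("n_keep must lie in [1, n_chunks]")
  idx <- if (scheme == "first-fixed") {
    if (n_keep == 1) 0L else
      c(0L, sort(sample(seq_len(n_chunks - 1L), n_keep - 1L)))
  } else {
    sort(sample(seq_len(n_chunks) - 1L, n_keep))
  }
  structure(list(sampled = as.integer(idx), n_chunks = n_chunks,
                 nus_level = n_keep / n_chunks, scheme = scheme),
            class = "nus_schedule")
}

#' Zero the omitted chunks of a FID
#'
#' Chunk `c` covers the half-open sample range `[c*chunk_len, (c+1)*chunk_len)`
#' (0-based). Samples inside sampled chunks are untouched; all others are set
#' to zero, which is what Fourier transforming an undersampled interferogram
#' acquisition amounts to.
#'
#' @param fid an `nmr_fid`.
#' @param schedule a [make_nus_schedule()] result with matching `n_chunks`.
#' @return the chunk-masked `nmr_fid`.
#' @export
apply_nus <- function(fid, schedule) {
  stopifnot(inherits(fid, "nmr_fid"), inherits(schedule, "nus_schedule"))
  if (schedule$n_chunks != fid$acq$n_chunks)
    stop("schedule is for ", schedule$n_chunks, " chunks but FID has ",
         fid$acq$n_chunks)
  keep <- logical(fid$acq$n_points)
  for (c in schedule$sampled) {
    keep[(c * fid$acq$chunk_len + 1L):((c + 1L) * fid$acq$chunk_len)] <- TRUE
  }
  fid$samples[!keep] <- 0 + 0i
  fid$schedule <- schedule
  fid
}

#' Add complex Gaussian time-domain noise
#'
#' Independent Gaussian perturbations of standard deviation `sigma` are added
#' to the real and imaginary parts of every sample. Uses the R RNG.
#'
#' @param fid an `nmr_fid`.
#' @param sigma noise standard deviation (absolute units of the FID), >= 0.
#' @export
add_noise <- function(fid, sigma) {
  stopifnot(inherits(fid, "nmr_fid"))
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(fid)
  n <- length(fid$samples)
  fid$samples <- fid$samples +
    complex(real = stats::rnorm(n, 0, sigma),
            imaginary = stats::rnorm(n, 0, sigma))
  fid
}

#' Fourier transform a FID into a real normalized spectrum
#'
#' Zero-fills to `n_ft`, applies the discrete Fourier transform, rotates the
#' zero-frequency bin to the centre, takes the real part and scales it to
#' unit maximum absolute value. The applied scale is retained as
#' `norm_factor` so intensities can be de-normalized. A zero FID yields a
#' zero spectrum with `norm_factor = 0` (flagged, not an error).
#'
#' @param fid an `nmr_fid`.
#' @param n_ft transform length, at least the FID length (default: the
#'   geometry's `n_ft`).
#' @param normalize scale to unit maximum absolute value (default `TRUE`).
#' @return an `nmr_spectrum`: real `values` of length `n_ft`, the frequency
#'   `axis_hz` (centered, in Hz), and `norm_factor`.
#' @export
fid_to_spectrum <- function(fid, n_ft = fid$acq$n_ft, normalize = TRUE) {
  stopifnot(inherits(fid, "nmr_fid"))
  n_ft <- as.integer(n_ft)
  if (n_ft < length(fid$samples))
    stop("n_ft (", n_ft, ") smaller than FID length (", length(fid$samples), ")")
  padded <- c(fid$samples, complex(n_ft - length(fid$samples)))
  sp <- stats::fft(padded)
  half <- n_ft %/% 2
  sp <- sp[c((half + 1L):n_ft, 1L:half)]   # rotate zero frequency to centre
  vals <- Re(sp)
  nf <- max(abs(vals))
  if (normalize && nf > 0) vals <- vals / nf
  structure(list(values = vals,
                 axis_hz = (seq_len(n_ft) - 1L - half) *
                   fid$acq$spectral_width_hz / n_ft,
                 norm_factor = if (normalize) nf else 1,
                 n_ft = n_ft,
                 spectral_width_hz = fid$acq$spectral_width_hz),
            class = "nmr_spectrum")
}

#' Construct a spectrum object from raw values
#'
#' For externally processed real spectra (e.g. loaded from a text file).
#' @param values real vector.
#' @param spectral_width_hz sweep width used to build the axis; default 1 bin
#'   per Hz.
#' @param normalize scale to unit maximum absolute value.
#' @export
as_spectrum <- function(values, spectral_width_hz = length(values),
                        normalize = FALSE) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1) stop("a spectrum must contain at least one point")
  nf <- 1
  if (normalize) {
    nf <- max(abs(values))
    if (nf > 0) values <- values / nf
  }
  half <- n %/% 2
  structure(list(values = values,
                 axis_hz = (seq_len(n) - 1L - half) * spectral_width_hz / n,
                 norm_factor = nf, n_ft = n,
                 spectral_width_hz = spectral_width_hz),
            class = "nmr_spectrum")
}

#' Build one (undersampled input, ideal label) spectrum pair
#'
#' The input spectrum is the Fourier transform of the noisy, chunk-masked
#' FID; the label is the transform of the same peak set's noiseless, fully
#' sampled FID. Both are unit-max normalized independently — the supervised
#' target is the ideal artifact-free spectrum.
#'
#' @param peaks a [peak_set()].
#' @param acq an [acq_params()].
#' @param schedule a [make_nus_schedule()] result.
#' @param sigma absolute time-domain noise standard deviation for the input.
#' @return a `training_pair`: list with `input`, `label` (both
#'   `nmr_spectrum`) and `meta`.
#' @export
make_training_pair <- function(peaks, acq, schedule, sigma = 0) {
  fid <- synthesize_fid(peaks, acq)
  label <- fid_to_spectrum(fid)
  input <- fid_to_spectrum(apply_nus(add_noise(fid, sigma), schedule))
  structure(list(input = input, label = label,
                 meta = list(peaks = peaks, schedule = schedule,
                             sigma = sigma)),
            class = "training_pair")
}

pair_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + 7919 * as.double(i)) %% 2147483647)
}

#' Generate a reproducible synthetic training dataset
#'
#' Draws `n` random peak sets and NUS schedules from `config` and builds the
#' corresponding (input, label) spectrum pairs. The master `seed` fans out a
#' deterministic child seed per pair, so any pair can be regenerated in
#' isolation. With `m_to_s > 1` each peak set contributes `m_to_s` inputs
#' with pairwise distinct schedules (and levels drawn from `config$n_keep`)
#' sharing one ideal label — the many-to-single augmentation that lets one
#' model generalize across sampling schemes and NUS levels.
#'
#' @param n number of distinct peak sets (labels).
#' @param config a [sim_config()].
#' @param seed master seed (integer).
#' @param m_to_s inputs per label (default 1).
#' @return a `psnet_dataset`: `input` and `label` matrices of size
#'   `(n * m_to_s) x n_ft` (one spectrum per row) plus per-pair `meta`.
#' @export
generate_dataset <- function(n, config = sim_config(), seed = 1L, m_to_s = 1L) {
  stopifnot(n >= 1, m_to_s >= 1)
  n <- as.integer(n); m_to_s <- as.integer(m_to_s)
  acq <- config$acq
  ntot <- n * m_to_s
  input <- matrix(0, ntot, acq$n_ft)
  label <- matrix(0, ntot, acq$n_ft)
  meta <- vector("list", ntot)
  row <- 0L
  for (i in seq_len(n)) {
    set.seed(pair_seed(seed, i))
    peaks <- sample_peak_set(config)
    prs <- m_to_s_augment(peaks, config, m = m_to_s)
    for (p in prs) {
      row <- row + 1L
      input[row, ] <- p$input$values
      label[row, ] <- p$label$values
      meta[[row]] <- c(p$meta, list(seed = pair_seed(seed, i), label_id = i))
    }
  }
  structure(list(input = input, label = label, meta = meta,
                 config = config, seed = seed, m_to_s = m_to_s),
            class = "psnet_dataset")
}

#' Many-to-single training augmentation
#'
#' Builds `m` training pairs whose inputs use pairwise distinct NUS schedules
#' (levels drawn from `config$n_keep`) while sharing the single ideal label
#' spectrum of `peaks`.
#'
#' @param peaks a [peak_set()].
#' @param config a [sim_config()].
#' @param m number of inputs for this label.
#' @return list of `training_pair`s with identical `label`.
#' @export
m_to_s_augment <- function(peaks, config, m = 1L) {
  stopifnot(inherits(config, "sim_config"), m >= 1)
  acq <- config$acq
  n_free <- acq$n_chunks - (config$scheme == "first-fixed")
  max_sched <- sum(vapply(unique(config$n_keep), function(k)
    choose(n_free, k - (config$scheme == "first-fixed")), numeric(1)))
  if (m > max_sched)
    stop("m = ", m, " exceeds the number of distinct schedules (", max_sched, ")")
  fid <- synthesize_fid(peaks, acq)
  label <- fid_to_spectrum(fid)
  seen <- character(0)
  out <- vector("list", m)
  for (j in seq_len(m)) {
    repeat {
      keep <- if (length(config$n_keep) == 1) config$n_keep else
        sample(config$n_keep, 1)
      sched <- make_nus_schedule(acq$n_chunks, keep, config$scheme)
      key <- paste(sched$sampled, collapse = ",")
      if (!key %in% seen) { seen <- c(seen, key); break }
    }
    sigma <- stats::runif(1, config$sigma_range[1], config$sigma_range[2]) *
      max(Mod(fid$samples))
    input <- fid_to_spectrum(apply_nus(add_noise(fid, sigma), sched))
    out[[j]] <- structure(list(input = input, label = label,
                               meta = list(peaks = peaks, schedule = sched,
                                           sigma = sigma)),
                          class = "training_pair")
  }
  out
}
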