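#' Root-mean-squared deviation between two spectra
#'
#' Computed over all bins of the (unit-max normalized) spectra, the global
#' figure of reconstruction error. For the peak-region variant restrict via
#' `bins`.
#'
#' @param a,b `nmr_spectrum` objects or equal-length numeric vectors.
#' @param bins optional bin indices to restrict the deviation to (e.g. peak
#'   regions).
#' @export
rmsd <- function(a, b, bins = NULL) {
  av <- if (inherits(a, "nmr_spectrum")) a$values else as.numeric(a)
  bv <- if (inherits(b, "nmr_spectrum")) b$values else as.numeric(b)
  if (length(av) != length(bv))
    stop("spectra lengths differ (", length(av), " vs ", length(bv), ")")
  if (!is.null(bins)) { av <- av[bins]; bv <- bv[bins] }
  sqrt(mean((av - bv)^2))
}

#' Pick peaks from a normalized spectrum
#'
#' Local maxima above `min_height`, greedily thinned so that retained peaks
#' are at least `min_separation` bins apart (strongest first).
#'
#' @param spectrum an `nmr_spectrum` or numeric vector.
#' @param min_height intensity threshold, on the normalized scale
#'   (default 0.01 of the maximum — low enough to retain a peak at 2.2% of
#'   the strongest, the weakest case of interest).
#' @param min_separation minimum separation between reported peaks, bins.
#' @return data frame with columns `bin` (1-based) and `intensity`, ordered
#'   by bin.
#' @export
pick_peaks <- function(spectrum, min_height = 0.01, min_separation = 2L) {
  v <- if (inherits(spectrum, "nmr_spectrum")) spectrum$values else
    as.numeric(spectrum)
  n <- length(v)
  if (n < 3) return(data.frame(bin = integer(0), intensity = numeric(0)))
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n],
              FALSE)
  cand <- which(is_max & v > min_height)
  if (!length(cand)) return(data.frame(bin = integer(0), intensity = numeric(0)))
  cand <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (b in cand) {
    if (!length(kept) || min(abs(kept - b)) >= min_separation)
      kept <- c(kept, b)
  }
  kept <- sort(kept)
  data.frame(bin = kept, intensity = v[kept])
}

#' Match reference peaks to a reconstruction and correlate intensities
#'
#' Every reference peak is matched to the nearest reconstructed peak within
#' `tol_bins`; unmatched reference peaks are false negatives, surplus
#' reconstructed peaks above threshold are false positives. The quantitative
#' figure is the squared Pearson correlation of the matched intensity pairs;
#' the integral variant correlates sums over a `+-integral_halfwidth`-bin
#' window around each matched peak instead of the bin heights.
#'
#' @param reference,reconstruction `nmr_spectrum` objects or numeric vectors
#'   (both unit-max normalized, picked with identical settings).
#' @param tol_bins matching tolerance in bins (default 2).
#' @param min_height,min_separation passed to [pick_peaks()].
#' @param integral_halfwidth half width w of the integration window, bins
#'   (default 5).
#' @return list with `table` (one row per reference peak), `r2_intensity`,
#'   `r2_integral` (NA and flagged if fewer than 2 matches),
#'   `n_false_positive`, `n_false_negative`.
#' @export
match_and_correlate <- function(reference, reconstruction, tol_bins = 2L,
                                min_height = 0.01, min_separation = 2L,
                                integral_halfwidth = 5L) {
  rv <- if (inherits(reference, "nmr_spectrum")) reference$values else
    as.numeric(reference)
  cv <- if (inherits(reconstruction, "nmr_spectrum")) reconstruction$values
    else as.numeric(reconstruction)
  ref <- pick_peaks(rv, min_height, min_separation)
  rec <- pick_peaks(cv, min_height, min_separation)
  used <- logical(nrow(rec))
  tab <- data.frame(ref_bin = ref$bin, ref_intensity = ref$intensity,
                    rec_bin = NA_integer_, rec_intensity = NA_real_,
                    matched = FALSE)
  for (i in seq_len(nrow(ref))) {
    if (!nrow(rec)) break
    d <- abs(rec$bin - ref$bin[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol_bins) {
      used[j] <- TRUE
      tab$rec_bin[i] <- rec$bin[j]
      tab$rec_intensity[i] <- rec$intensity[j]
      tab$matched[i] <- TRUE
    }
  }
  m <- tab[tab$matched, ]
  window_sum <- function(v, bin, w) {
    lo <- max(1L, bin - w); hi <- min(length(v), bin + w)
    sum(v[lo:hi])
  }
  r2i <- r2int <- NA_real_
  flagged <- nrow(m) < 2
  if (!flagged) {
    r2i <- if (stats::sd(m$ref_intensity) == 0 || stats::sd(m$rec_intensity) == 0)
      NA_real_ else stats::cor(m$ref_intensity, m$rec_intensity)^2
    ri <- vapply(m$ref_bin, window_sum, numeric(1), v = rv,
                 w = integral_halfwidth)
    ci <- vapply(m$rec_bin, window_sum, numeric(1), v = cv,
                 w = integral_halfwidth)
    r2int <- if (stats::sd(ri) == 0 || stats::sd(ci) == 0) NA_real_ else
      stats::cor(ri, ci)^2
  }
  list(table = tab, r2_intensity = r2i, r2_integral = r2int,
       n_false_positive = sum(!used), n_false_negative = sum(!tab$matched),
       insufficient_matches = flagged)
}

#' Summarize per-trial metrics over repeated random trials
#'
#' @param trials data frame with one row per trial and one numeric column per
#'   metric.
#' @return data frame with one row per metric: mean and sample standard
#'   deviation.
#' @export
summarize_trials <- function(trials) {
  stopifnot(is.data.frame(trials), nrow(trials) >= 2)
  num <- vapply(trials, is.numeric, logical(1))
  data.frame(metric = names(trials)[num],
             mean = vapply(trials[num], mean, numeric(1)),
             sd = vapply(trials[num], stats::sd, numeric(1)),
             n = nrow(trials), row.names = NULL)
}

#' Full evaluation of a reconstruction against its reference
#'
#' Convenience wrapper producing the standard report: global RMSD,
#' peak-region RMSD, intensity and integral squared correlations, and false
#' positive/negative counts.
#'
#' @inheritParams match_and_correlate
#' @param region_halfwidth half width of the peak regions used for the
#'   peak-region RMSD variant, bins.
#' @return list of class `eval_report`.
#' @export
evaluate_reconstruction <- function(reference, reconstruction, tol_bins = 2L,
                                    min_height = 0.01, min_separation = 2L,
                                    integral_halfwidth = 5L,
                                    region_halfwidth = 5L) {
  rv <- if (inherits(reference, "nmr_spectrum")) reference$values else
    as.numeric(reference)
  cv <- if (inherits(reconstruction, "nmr_spectrum")) reconstruction$values
    else as.numeric(reconstruction)
  mc <- match_and_correlate(rv, cv, tol_bins, min_height, min_separation,
                            integral_halfwidth)
  region <- unique(unlist(lapply(mc$table$ref_bin, function(b)
    max(1L, b - region_halfwidth):min(length(rv), b + region_halfwidth))))
  structure(list(rmsd = rmsd(rv, cv),
                 rmsd_peak_region = if (length(region)) rmsd(rv, cv, region)
                   else NA_real_,
                 r2_intensity = mc$r2_intensity,
                 r2_integral = mc$r2_integral,
                 n_false_positive = mc$n_false_positive,
                 n_false_negative = mc$n_false_negative,
                 table = mc$table),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("RMSD %.4g (peak regions %.4g); R2 intensity %.4f, integral %.4f; FP %d, FN %d\n",
              x$rmsd, x$rmsd_peak_region, x$r2_intensity, x$r2_integral,
              x$n_false_positive, x$n_false_negative))
  invisible(x)
}
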