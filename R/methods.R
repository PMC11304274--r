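# S3 methods for the model object and the small data containers.

#' Predict method: reconstruct undersampled spectra
#'
#' Runs the network in inference mode. Inference is a pure function of the
#' weights and the individual input: results do not depend on how samples are
#' batched.
#'
#' @param object a `sepsnet` model.
#' @param newdata an `nmr_spectrum`, a numeric vector, a matrix with one
#'   spectrum per row, or a `psnet_dataset` (its `input` matrix is used).
#' @param normalize unit-max normalize each reconstructed spectrum
#'   (default `TRUE`, the scale the evaluation metrics expect).
#' @param batch_size internal batch size.
#' @param ... unused.
#' @return a matrix with one reconstructed spectrum per row (or an
#'   `nmr_spectrum` when `newdata` was one).
#' @export
predict.sepsnet <- function(object, newdata, normalize = TRUE,
                            batch_size = 32L, ...) {
  if (inherits(newdata, "nmr_spectrum")) return(reconstruct(object, newdata))
  x <- if (is.list(newdata) && !is.null(newdata$input)) newdata$input else
    newdata
  if (!is.matrix(x)) x <- matrix(as.numeric(x), nrow = 1)
  if (ncol(x) != object$config$n_input)
    stop("spectra have length ", ncol(x), " but the model expects ",
         object$config$n_input)
  out <- matrix(0, nrow(x), ncol(x))
  for (start in seq(1, nrow(x), by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, nrow(x))
    y <- network_forward(object$params, object$bn_stats, object$config,
                         t(x[ix, , drop = FALSE]), training = FALSE)$y
    out[ix, ] <- t(y)
  }
  if (normalize) {
    mx <- apply(abs(out), 1, max)
    mx[mx == 0] <- 1
    out <- out / mx
  }
  out
}

#' @export
print.sepsnet <- function(x, ...) {
  cfg <- x$config
  cat("Pure-shift NMR reconstruction network",
      if (cfg$use_se) "(SE attention)" else "(no attention, ablation)", "\n")
  cat(sprintf("  input length %d, %d channels, kernels %d/%d, %d residual blocks\n",
              cfg$n_input, cfg$channels, cfg$k_entry, cfg$k_res,
              cfg$n_res_blocks))
  np <- count_parameters(cfg)
  cat(sprintf("  %s learnable parameters (%.2f MB at 4 bytes), %.2f billion conv multiply-adds\n",
              format(np, big.mark = ","), np * 4 / 1024^2,
              as.numeric(count_flops(cfg)) / 1e9))
  if (isTRUE(x$trained)) {
    h <- x$history
    cat(sprintf("  trained %d epochs; best validation MSE %.3e at epoch %d\n",
                nrow(h), min(h$val_loss), x$best_epoch))
  } else cat("  untrained (initial weights)\n")
  invisible(x)
}

#' @export
summary.sepsnet <- function(object, ...) {
  print(object)
  if (isTRUE(object$trained)) {
    h <- object$history
    cat("\nLoss history (last 5 epochs):\n")
    print(utils::tail(h, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.sepsnet <- function(object, ...) object$params

#' Plot training and validation loss curves
#' @param x a fitted `sepsnet`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.sepsnet <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"), log = "y",
                    xlab = "epoch", ylab = "MSE loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(h)
}

#' Reconstruction residuals on a dataset
#'
#' @param object a fitted `sepsnet`.
#' @param data a dataset (defaults must be supplied; the model stores only
#'   validation indices, not the data).
#' @param ... unused.
#' @return matrix of per-bin errors, reconstruction minus label.
#' @export
residuals.sepsnet <- function(object, data, ...) {
  if (missing(data)) stop("supply the dataset the residuals refer to")
  predict(object, data) - data$label
}

#' Simulate new training pairs from a fitted model's stored simulator world
#'
#' @param object a `sepsnet` fitted on a [generate_dataset()] result.
#' @param nsim number of pairs.
#' @param seed master seed.
#' @param ... unused.
#' @export
simulate.sepsnet <- function(object, nsim = 1, seed = 1L, ...) {
  if (is.null(object$sim_config))
    stop("model does not carry a simulator configuration")
  generate_dataset(nsim, object$sim_config, seed = seed)
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("nmr_spectrum: %d points, %.1f Hz window, norm_factor %.4g\n",
              x$n_ft, x$spectral_width_hz, x$norm_factor))
  invisible(x)
}

#' @export
plot.nmr_spectrum <- function(x, ...) {
  graphics::plot(x$axis_hz, x$values, type = "l", xlab = "frequency (Hz)",
                 ylab = "intensity (normalized)", ...)
  invisible(x)
}

#' @export
print.nus_schedule <- function(x, ...) {
  cat(sprintf("NUS schedule: %d of %d chunks (%.1f%%), scheme %s\n",
              length(x$sampled), x$n_chunks, 100 * x$nus_level, x$scheme))
  invisible(x)
}

#' @export
print.psnet_dataset <- function(x, ...) {
  cat(sprintf("synthetic pure-shift dataset: %d pairs of length %d (seed %d)\n",
              nrow(x$input), ncol(x$input), x$seed))
  invisible(x)
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("acquisition: %d chunks x %d points, sw %.1f Hz, FT %d\n",
              x$n_chunks, x$chunk_len, x$spectral_width_hz, x$n_ft))
  invisible(x)
}
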