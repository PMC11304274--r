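#' Mean squared error between two spectra
#'
#' @param prediction,label equal-length numeric vectors or matrices.
#' @return non-negative scalar.
#' @export
mse_loss <- function(prediction, label) {
  if (length(prediction) != length(label))
    stop("prediction and label lengths differ (", length(prediction),
         " vs ", length(label), ")")
  mean((as.numeric(prediction) - as.numeric(label))^2)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Fit the squeeze-and-excitation pure-shift reconstruction network
#'
#' Trains the network end to end to map undersampled real pure-shift spectra
#' to their ideal fully sampled, noiseless counterparts, by minimizing the
#' mean squared error with Adam. The dataset is split into training and
#' validation subsets by seed; the returned model carries the weights of the
#' epoch with the lowest validation loss, plus the full per-epoch loss
#' history.
#'
#' @param data a [generate_dataset()] result, or any list with `input` and
#'   `label` matrices (one spectrum per row).
#' @param config a [psnet_config()] whose `n_input` matches the spectra.
#' @param epochs training epochs (default 100).
#' @param batch_size minibatch size (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param lr_end final learning rate; when it differs from `lr` the rate is
#'   interpolated linearly across epochs (default: constant).
#' @param val_fraction held-out validation fraction in (0, 1) (default 0.1).
#' @param seed controls the split, weight initialization, shuffling and
#'   dropout; one seed makes the whole run reproducible on one device.
#' @param verbose print a line per epoch.
#' @return an object of class `sepsnet` with components `config`, `params`
#'   (weights), `bn_stats`, `history` (data frame of epoch, train and
#'   validation loss), `best_epoch`, `val_idx` and `sim_config` (when the
#'   dataset carries one). Methods: [predict.sepsnet()], `print`, `summary`,
#'   `coef`, `plot`, `residuals`, `simulate`.
#' @examples
#' \donttest{
#' cfg <- sim_config("tiny")
#' ds <- generate_dataset(32, cfg, seed = 7)
#' net <- psnet_config(n_input = cfg$acq$n_ft, channels = 4, n_res_blocks = 1)
#' fit <- sepsnet(ds, net, epochs = 2, batch_size = 8, seed = 7)
#' print(fit)
#' }
#' @export
sepsnet <- function(data, config = psnet_config(), epochs = 100L,
                    batch_size = 64L, lr = 1e-3, lr_end = lr,
                    val_fraction = 0.1, seed = 1L, verbose = FALSE) {
  stopifnot(is.list(data), !is.null(data$input), !is.null(data$label))
  x <- data$input; y <- data$label
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(y)) y <- matrix(y, nrow = 1)
  if (ncol(x) != config$n_input)
    stop("dataset spectra have length ", ncol(x),
         " but config$n_input is ", config$n_input)
  if (any(dim(x) != dim(y))) stop("input and label matrices differ in shape")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must lie in (0, 1)")
  n <- nrow(x)
  model <- build_model(config, seed = seed)
  set.seed(seed + 1L)
  n_val <- max(1L, round(val_fraction * n))
  if (n_val >= n) stop("not enough samples for a validation split")
  val_idx <- sort(sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)
  xt <- t(x[tr_idx, , drop = FALSE])     # n_input x n_train
  yt <- t(y[tr_idx, , drop = FALSE])
  xv <- t(x[val_idx, , drop = FALSE])
  yv <- t(y[val_idx, , drop = FALSE])
  opt <- adam_init(model$params)
  params <- model$params
  stats <- model$bn_stats
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, params = params, stats = stats, epoch = 0L)
  lr_ep <- if (epochs > 1) seq(lr, lr_end, length.out = epochs) else lr
  for (ep in seq_len(epochs)) {
    ord <- sample(length(tr_idx))
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1, length(ord), by = batch_size)) {
      ix <- ord[start:min(start + batch_size - 1L, length(ord))]
      fw <- network_forward(params, stats, config, xt[, ix, drop = FALSE],
                            training = TRUE)
      stats <- fw$stats
      diff <- fw$y - yt[, ix, drop = FALSE]
      loss <- mean(diff^2)
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", ep,
             "; lower the learning rate")
      grads <- network_backward(2 * diff / length(diff), fw$caches, params,
                                config)
      st <- adam_step(params, grads, opt, lr_ep[ep])
      params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + loss
      nb <- nb + 1L
    }
    vl <- batched_loss(params, stats, config, xv, yv, batch_size)
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                         val_loss = vl))
    if (vl < best$loss) best <- list(loss = vl, params = params,
                                     stats = stats, epoch = ep)
    if (verbose)
      message(sprintf("epoch %3d  train %.3e  val %.3e", ep, ep_loss / nb, vl))
  }
  model$params <- best$params
  model$bn_stats <- best$stats
  model$history <- history
  model$best_epoch <- best$epoch
  model$trained <- TRUE
  model$val_idx <- val_idx
  model$train_meta <- list(epochs = epochs, batch_size = batch_size, lr = lr,
                           val_fraction = val_fraction, seed = seed,
                           n_pairs = n)
  if (!is.null(data$config)) model$sim_config <- data$config
  model
}

batched_loss <- function(params, stats, config, x, y, batch_size) {
  tot <- 0
  for (start in seq(1, ncol(x), by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, ncol(x))
    fw <- network_forward(params, stats, config, x[, ix, drop = FALSE],
                          training = FALSE)
    tot <- tot + sum((fw$y - y[, ix, drop = FALSE])^2)
  }
  tot / length(x)
}
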