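#' Network architecture hyperparameters
#'
#' Configuration of the squeeze-and-excitation pure-shift network: an entry
#' CBLD block (convolution, batch normalization, leaky rectifier, dropout)
#' lifting 1 channel to `channels`, six residual blocks each holding two CBLD
#' units with an SE channel-attention gate between them and an additive skip
#' connection, and an output block (1x1 convolution back to one channel plus
#' batch normalization, with no activation or dropout). All convolutions are
#' stride 1 with "same" zero padding, so the feature-map length stays
#' `n_input` throughout.
#'
#' @param n_input spectrum length N (default 8192).
#' @param channels feature channels C (default 32).
#' @param k_entry kernel size of the entry CBLD block (default 9).
#' @param k_res kernel size inside the residual blocks (default 21).
#' @param n_res_blocks number of SE residual blocks (default 6).
#' @param se_reduction SE bottleneck divisor r; must divide `channels`
#'   (default 2, i.e. bottleneck width C/2).
#' @param dropout dropout fraction in CBLD units (default 0.1).
#' @param leaky_slope negative slope of the leaky rectifier (default 0.01).
#' @param use_se `FALSE` gives the ablation network without attention gates
#'   (identical layer count minus the SE gates).
#' @return a `psnet_config` list.
#' @export
psnet_config <- function(n_input = 8192L, channels = 32L, k_entry = 9L,
                         k_res = 21L, n_res_blocks = 6L, se_reduction = 2L,
                         dropout = 0.1, leaky_slope = 0.01, use_se = TRUE) {
  n_input <- as.integer(n_input); channels <- as.integer(channels)
  k_entry <- as.integer(k_entry); k_res <- as.integer(k_res)
  n_res_blocks <- as.integer(n_res_blocks)
  se_reduction <- as.integer(se_reduction)
  if (any(c(n_input, channels, k_entry, k_res, n_res_blocks, se_reduction) < 1))
    stop("all architecture counts must be positive")
  if (k_entry %% 2 == 0 || k_res %% 2 == 0)
    stop("kernel sizes must be odd so 'same' padding is exact")
  if (channels %% se_reduction != 0)
    stop("se_reduction must divide channels")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(list(n_input = n_input, channels = channels, k_entry = k_entry,
                 k_res = k_res, n_res_blocks = n_res_blocks,
                 se_reduction = se_reduction, dropout = dropout,
                 leaky_slope = leaky_slope, use_se = isTRUE(use_se)),
            class = "psnet_config")
}

init_conv <- function(c_out, c_in, K) {
  matrix(stats::rnorm(c_out * c_in * K, 0, sqrt(2 / (c_in * K))),
         c_out, c_in * K)
}

init_params <- function(config) {
  C <- config$channels
  H <- C %/% config$se_reduction
  p <- list()
  s <- list()
  add_bn <- function(p, s, prefix, ch) {
    p[[paste0(prefix, ".bn.gamma")]] <- rep(1, ch)
    p[[paste0(prefix, ".bn.beta")]] <- rep(0, ch)
    s[[paste0(prefix, ".bn.mean")]] <- rep(0, ch)
    s[[paste0(prefix, ".bn.var")]] <- rep(1, ch)
    list(p = p, s = s)
  }
  p[["entry.conv.w"]] <- init_conv(C, 1, config$k_entry)
  p[["entry.conv.b"]] <- rep(0, C)
  r <- add_bn(p, s, "entry", C); p <- r$p; s <- r$s
  for (i in seq_len(config$n_res_blocks)) {
    for (u in c("cbld1", "cbld2")) {
      pre <- sprintf("block%d.%s", i, u)
      p[[paste0(pre, ".conv.w")]] <- init_conv(C, C, config$k_res)
      p[[paste0(pre, ".conv.b")]] <- rep(0, C)
      r <- add_bn(p, s, pre, C); p <- r$p; s <- r$s
    }
    if (config$use_se) {
      pre <- sprintf("block%d.se", i)
      p[[paste0(pre, ".w1")]] <- matrix(stats::rnorm(H * C, 0, sqrt(2 / C)), H, C)
      p[[paste0(pre, ".b1")]] <- rep(0, H)
      p[[paste0(pre, ".w2")]] <- matrix(stats::rnorm(C * H, 0, sqrt(2 / H)), C, H)
      p[[paste0(pre, ".b2")]] <- rep(0, C)
    }
  }
  p[["out.conv.w"]] <- init_conv(1, C, 1)
  p[["out.conv.b"]] <- 0
  r <- add_bn(p, s, "out", 1); p <- r$p; s <- r$s
  list(params = p, stats = s)
}

#' Instantiate an untrained network
#'
#' Builds the layer graph and draws variance-scaling (fan-in) initial
#' weights. The returned object is the same class as a fitted [sepsnet()]
#' model, with an empty training history; [predict()][predict.sepsnet] works
#' on it (useful as an untrained baseline).
#'
#' @param config a [psnet_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `sepsnet`.
#' @export
build_model <- function(config = psnet_config(), seed = 1L) {
  stopifnot(inherits(config, "psnet_config"))
  set.seed(seed)
  ps <- init_params(config)
  structure(list(config = config, params = ps$params, bn_stats = ps$stats,
                 history = NULL, seed = as.integer(seed), trained = FALSE),
            class = "sepsnet")
}

# Full network pass. x is an n_input x batch matrix; returns the output
# matrix plus (when training) the per-layer caches needed for backprop.
network_forward <- function(params, stats, config, x, training = FALSE) {
  d <- dim(x)
  h <- array(x, c(1L, d[1], d[2]))
  caches <- list()
  en <- cbld_forward(h, params, stats, "entry", config$k_entry, config, training)
  stats <- en$stats
  caches$entry <- en$cache
  h <- en$y
  for (i in seq_len(config$n_res_blocks)) {
    xin <- h
    c1 <- cbld_forward(h, params, stats, sprintf("block%d.cbld1", i),
                       config$k_res, config, training)
    stats <- c1$stats
    h <- c1$y
    se_cache <- NULL
    if (config$use_se) {
      pre <- sprintf("block%d.se", i)
      se <- se_forward(h, params[[paste0(pre, ".w1")]],
                       params[[paste0(pre, ".b1")]],
                       params[[paste0(pre, ".w2")]],
                       params[[paste0(pre, ".b2")]])
      se_cache <- se$cache
      h <- se$y
    }
    c2 <- cbld_forward(h, params, stats, sprintf("block%d.cbld2", i),
                       config$k_res, config, training)
    stats <- c2$stats
    h <- xin + c2$y                       # additive skip around the block
    caches[[sprintf("block%d", i)]] <- list(c1 = c1$cache, se = se_cache,
                                            c2 = c2$cache)
  }
  w_out <- params[["out.conv.w"]]
  y0 <- conv_forward(h, w_out, params[["out.conv.b"]], 1L)
  bn <- bn_forward(y0, params[["out.bn.gamma"]], params[["out.bn.beta"]],
                   stats[["out.bn.mean"]], stats[["out.bn.var"]], training)
  stats[["out.bn.mean"]] <- bn$rmean
  stats[["out.bn.var"]] <- bn$rvar
  caches$out <- list(x = h, bn = bn$cache)
  y <- matrix(bn$y, d[1], d[2])
  list(y = y, caches = caches, stats = stats)
}

network_backward <- function(dy, caches, params, config) {
  grads <- list()
  d3 <- array(dy, c(1L, dim(dy)))
  bn <- bn_backward(d3, caches$out$bn)
  grads[["out.bn.gamma"]] <- bn$dgamma
  grads[["out.bn.beta"]] <- bn$dbeta
  cv <- conv_backward(caches$out$x, params[["out.conv.w"]], bn$dx, 1L)
  grads[["out.conv.w"]] <- cv$dw
  grads[["out.conv.b"]] <- cv$db
  dh <- cv$dx
  for (i in rev(seq_len(config$n_res_blocks))) {
    bc <- caches[[sprintf("block%d", i)]]
    r2 <- cbld_backward(dh, bc$c2, params, grads)
    grads <- r2$grads
    dbranch <- r2$dx
    if (config$use_se) {
      pre <- sprintf("block%d.se", i)
      se <- se_backward(dbranch, bc$se, params[[paste0(pre, ".w1")]],
                        params[[paste0(pre, ".w2")]])
      grads[[paste0(pre, ".w1")]] <- se$dw1
      grads[[paste0(pre, ".b1")]] <- se$db1
      grads[[paste0(pre, ".w2")]] <- se$dw2
      grads[[paste0(pre, ".b2")]] <- se$db2
      dbranch <- se$dx
    }
    r1 <- cbld_backward(dbranch, bc$c1, params, grads)
    grads <- r1$grads
    dh <- dh + r1$dx                      # skip path carries dh through
  }
  en <- cbld_backward(dh, caches$entry, params, grads)
  en$grads
}

#' Squeeze-and-excitation channel gate
#'
#' Functional form of the attention gate: channel means are squeezed to one
#' scalar per channel, passed through a two-layer bottleneck (`w1`:
#' C -> C/r with ReLU, `w2`: C/r -> C with sigmoid), and the resulting gate
#' scalars — strictly inside (0, 1) — rescale their channels.
#'
#' @param x a `C x N` matrix (one sample's feature map).
#' @param w1,b1,w2,b2 bottleneck weights and biases.
#' @return list with `output` (`C x N`) and `gates` (length C, in (0,1)).
#' @export
se_gate <- function(x, w1, b1, w2, b2) {
  r <- se_forward(array(x, c(dim(x), 1L)), w1, b1, w2, b2)
  list(output = matrix(r$y, dim(x)[1]), gates = as.vector(r$cache$g))
}

#' Exact learnable-parameter count of the architecture
#'
#' Enumerates every learnable scalar: convolution weights and biases, batch
#' normalization affine pairs, and the SE bottleneck weights. Matches the
#' number of scalars in a built model exactly.
#'
#' @param config a [psnet_config()] (or a `sepsnet` model, whose config is
#'   used).
#' @return integer-valued count.
#' @export
count_parameters <- function(config = psnet_config()) {
  if (inherits(config, "sepsnet")) config <- config$config
  stopifnot(inherits(config, "psnet_config"))
  C <- config$channels
  nb <- config$n_res_blocks
  conv <- (1 * C * config$k_entry + C) +
    2 * nb * (C * C * config$k_res + C) +
    (C * 1 * 1 + 1)
  bn <- 2 * C * (1 + 2 * nb) + 2 * 1
  se <- if (config$use_se) {
    H <- C %/% config$se_reduction
    nb * (C * H + H + H * C + C)
  } else 0
  conv + bn + se
}

#' Count the learnable scalars of a built model by walking its weights
#'
#' Independent of the closed-form [count_parameters()]; the two must agree
#' exactly.
#' @param model a `sepsnet` object.
#' @export
n_learnable <- function(model) {
  stopifnot(inherits(model, "sepsnet"))
  sum(vapply(model$params, length, numeric(1)))
}

#' Multiply-add count of one forward pass
#'
#' The headline figure counts convolution multiply-adds only
#' (`n_input * C_in * C_out * K` per layer, summed over all convolutions),
#' the convention under which the default architecture at N = 8192 costs
#' about 2.12 billion multiply-adds. SE bottleneck, bias and normalization
#' costs are reported separately in the `"detail"` attribute and excluded
#' from the headline.
#'
#' @param config a [psnet_config()].
#' @param n_input input length; defaults to the config's.
#' @return numeric multiply-add count with a `"detail"` attribute.
#' @export
count_flops <- function(config = psnet_config(), n_input = config$n_input) {
  if (inherits(config, "sepsnet")) config <- config$config
  stopifnot(inherits(config, "psnet_config"))
  C <- config$channels
  nb <- config$n_res_blocks
  conv <- n_input * 1 * C * config$k_entry +
    2 * nb * n_input * C * C * config$k_res +
    n_input * C * 1 * 1
  H <- C %/% config$se_reduction
  detail <- list(
    se_linear = if (config$use_se) nb * 2 * C * H else 0,
    se_scale = if (config$use_se) nb * C * n_input else 0,
    bias = n_input * (C * (1 + 2 * nb) + 1),
    norm = 2 * n_input * (C * (1 + 2 * nb) + 1))
  structure(conv, detail = detail)
}

#' Reconstruct a spectrum with a (trained) network
#'
#' Runs the network in inference mode (dropout off, batch normalization on
#' running statistics) on one undersampled spectrum and returns the
#' artifact-suppressed reconstruction, unit-max normalized.
#'
#' @param model a `sepsnet` object.
#' @param spectrum an `nmr_spectrum` (length must equal the model's
#'   `n_input`) or a numeric vector.
#' @return an `nmr_spectrum`.
#' @export
reconstruct <- function(model, spectrum) {
  stopifnot(inherits(model, "sepsnet"))
  vals <- if (inherits(spectrum, "nmr_spectrum")) spectrum$values else
    as.numeric(spectrum)
  if (length(vals) != model$config$n_input)
    stop("spectrum length ", length(vals), " does not match the model's ",
         "n_input (", model$config$n_input, ")")
  y <- network_forward(model$params, model$bn_stats, model$config,
                       matrix(vals, ncol = 1), training = FALSE)$y[, 1]
  nf <- max(abs(y))
  if (nf > 0) y <- y / nf
  if (inherits(spectrum, "nmr_spectrum")) {
    out <- spectrum
    out$values <- y
    out$norm_factor <- nf
    out
  } else {
    as_spectrum(y)
  }
}
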