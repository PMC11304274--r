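# Internal layer primitives for the 1D residual network. Feature maps are
# arrays of dim (channels, length, batch); per-channel broadcasting exploits
# R's column-major recycling on a C x (L*B) matrix view.

conv_forward <- function(x, w, b, K) .conv1d_forward(x, w, b, K)

conv_backward <- function(x, w, dy, K) .conv1d_backward(x, w, dy, K)

bn_forward <- function(x, gamma, beta, rmean, rvar, training,
                       momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  m <- matrix(x, d[1])
  if (training) {
    mu <- rowMeans(m)
    v <- rowMeans(m * m) - mu^2
    v[v < 0] <- 0
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmean; v <- rvar
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (m - mu) * invstd
  y <- gamma * xhat + beta
  list(y = array(y, d),
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, dims = d),
       rmean = rmean, rvar = rvar)
}

bn_backward <- function(dy, cache) {
  d <- matrix(dy, cache$dims[1])
  xhat <- cache$xhat
  dgamma <- rowSums(d * xhat)
  dbeta <- rowSums(d)
  dxhat <- d * cache$gamma
  dx <- cache$invstd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = array(dx, cache$dims), dgamma = dgamma, dbeta = dbeta)
}

lrelu_forward <- function(x, slope) {
  neg <- !is.na(x) & x < 0      # NaN/Inf propagate; divergence is caught at the loss
  x[neg] <- slope * x[neg]
  list(y = x, cache = list(neg = neg, slope = slope))
}

lrelu_backward <- function(dy, cache) {
  dy[cache$neg] <- cache$slope * dy[cache$neg]
  dy
}

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- array((stats::runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(y = x * mask, mask = mask)
}

dropout_backward <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# squeeze over the length axis -> C x B matrix of channel means
se_squeeze <- function(x) {
  d <- dim(x)
  out <- colSums(aperm(x, c(2, 1, 3)))
  matrix(out / d[2], d[1], d[3])
}

se_forward <- function(x, w1, b1, w2, b2) {
  s <- se_squeeze(x)
  z1 <- w1 %*% s + as.vector(b1)
  a1 <- pmax(z1, 0)
  z2 <- w2 %*% a1 + as.vector(b2)
  g <- 1 / (1 + exp(-z2))
  y <- x
  for (b in seq_len(dim(x)[3])) y[, , b] <- x[, , b] * g[, b]
  list(y = y, cache = list(x = x, s = s, relu_pos = z1 > 0, a1 = a1, g = g))
}

se_backward <- function(dy, cache, w1, w2) {
  x <- cache$x; g <- cache$g
  d <- dim(x); L <- d[2]; B <- d[3]
  dg <- matrix(colSums(aperm(dy * x, c(2, 1, 3))), d[1], B)
  dx <- dy
  for (b in seq_len(B)) dx[, , b] <- dy[, , b] * g[, b]
  dz2 <- dg * g * (1 - g)
  dw2 <- dz2 %*% t(cache$a1)
  db2 <- rowSums(dz2)
  dz1 <- (t(w2) %*% dz2) * cache$relu_pos
  dw1 <- dz1 %*% t(cache$s)
  db1 <- rowSums(dz1)
  ds <- t(w1) %*% dz1 / L
  for (b in seq_len(B)) dx[, , b] <- dx[, , b] + ds[, b]
  list(dx = dx, dw1 = dw1, db1 = db1, dw2 = dw2, db2 = db2)
}

# one CBLD unit: convolution -> batch norm -> leaky ReLU -> dropout
cbld_forward <- function(x, params, stats, prefix, K, config, training) {
  w <- params[[paste0(prefix, ".conv.w")]]
  b <- params[[paste0(prefix, ".conv.b")]]
  y0 <- conv_forward(x, w, b, K)
  bn <- bn_forward(y0, params[[paste0(prefix, ".bn.gamma")]],
                   params[[paste0(prefix, ".bn.beta")]],
                   stats[[paste0(prefix, ".bn.mean")]],
                   stats[[paste0(prefix, ".bn.var")]], training)
  stats[[paste0(prefix, ".bn.mean")]] <- bn$rmean
  stats[[paste0(prefix, ".bn.var")]] <- bn$rvar
  lr <- lrelu_forward(bn$y, config$leaky_slope)
  dr <- dropout_forward(lr$y, config$dropout, training)
  list(y = dr$y, stats = stats,
       cache = list(x = x, K = K, bn = bn$cache, lr = lr$cache,
                    drop = dr$mask, prefix = prefix))
}

cbld_backward <- function(dy, cache, params, grads) {
  prefix <- cache$prefix
  dy <- dropout_backward(dy, cache$drop)
  dy <- lrelu_backward(dy, cache$lr)
  bn <- bn_backward(dy, cache$bn)
  grads[[paste0(prefix, ".bn.gamma")]] <- bn$dgamma
  grads[[paste0(prefix, ".bn.beta")]] <- bn$dbeta
  cv <- conv_backward(cache$x, params[[paste0(prefix, ".conv.w")]],
                      bn$dx, cache$K)
  grads[[paste0(prefix, ".conv.w")]] <- cv$dw
  grads[[paste0(prefix, ".conv.b")]] <- cv$db
  list(dx = cv$dx, grads = grads)
}
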