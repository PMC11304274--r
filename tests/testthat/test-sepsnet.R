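test_that("architecture accounting matches layer-by-layer enumeration", {
  cfg <- psnet_config()                      # N=8192, C=32, k 9/21, 6 blocks
  # independent oracle: enumerate the convolution layers explicitly
  layers <- rbind(
    data.frame(c_in = 1, c_out = 32, k = 9),                   # entry CBLD
    do.call(rbind, replicate(12, data.frame(c_in = 32, c_out = 32, k = 21),
                             simplify = FALSE)),               # 6 x 2 CBLD
    data.frame(c_in = 32, c_out = 1, k = 1))                   # output block
  conv_params <- sum(layers$c_in * layers$c_out * layers$k + layers$c_out)
  expect_equal(conv_params, 258785)          # 320 + 12 x 21536 + 33
  conv_macs <- sum(8192 * layers$c_in * layers$c_out * layers$k)
  expect_equal(as.numeric(count_flops(cfg)), conv_macs)

  # closed-form count equals walking every weight array of a built model
  model <- build_model(cfg, seed = 1)
  expect_identical(as.numeric(count_parameters(cfg)), n_learnable(model))

  small <- micro_net()
  expect_identical(as.numeric(count_parameters(small)),
                   n_learnable(build_model(small, seed = 2)))
})

test_that("removing SE gates drops exactly the bottleneck parameters", {
  cfg <- psnet_config()
  cfg_no <- psnet_config(use_se = FALSE)
  C <- cfg$channels; r <- cfg$se_reduction
  expect_equal(count_parameters(cfg) - count_parameters(cfg_no),
               6 * (2 * C^2 / r + C / r + C))
  expect_identical(as.numeric(count_parameters(cfg_no)),
                   n_learnable(build_model(cfg_no, seed = 3)))
})

test_that("multiply-add count is linear in input length and exact in degenerate cases", {
  cfg <- psnet_config()
  expect_equal(as.numeric(count_flops(cfg, n_input = 4096)),
               as.numeric(count_flops(cfg, n_input = 8192)) / 2)
  # one 1-channel, kernel-1 residual conv pair plus entry/output: closed form
  tiny <- psnet_config(n_input = 64, channels = 2, k_entry = 1, k_res = 1,
                       n_res_blocks = 1, se_reduction = 2)
  expect_equal(as.numeric(count_flops(tiny)),
               64 * 1 * 2 * 1 + 2 * 64 * 2 * 2 * 1 + 64 * 2 * 1 * 1)
})

test_that("config invariants are enforced", {
  expect_error(psnet_config(k_res = 20), "odd")
  expect_error(psnet_config(channels = 30, se_reduction = 4), "divide")
  expect_error(psnet_config(n_res_blocks = 0), "positive")
  expect_error(psnet_config(dropout = 1), "dropout")
})

test_that("forward pass preserves length, stays finite, and is a pure function", {
  cfg <- micro_net()
  model <- build_model(cfg, seed = 4)
  zeros <- rep(0, 128)
  y <- predict(model, zeros, normalize = FALSE)
  expect_equal(dim(y), c(1L, 128L))
  expect_true(all(is.finite(y)))

  set.seed(5)
  x <- matrix(rnorm(3 * 128), 3, 128)
  y1 <- predict(model, x, normalize = FALSE)
  y2 <- predict(model, x, normalize = FALSE)
  expect_identical(y1, y2)                  # inference determinism

  # no dependence on batch composition
  singles <- t(vapply(1:3, function(i)
    predict(model, x[i, , drop = FALSE], normalize = FALSE)[1, ],
    numeric(128)))
  expect_equal(y1, singles, tolerance = 1e-12)

  expect_error(predict(model, rep(0, 64)), "length")
})

test_that("SE gate squeezes, bottlenecks and rescales as specified", {
  C <- 6L; H <- 3L; N <- 40L
  # zero weights: sigmoid(0) = 0.5 gates; zero input stays zero
  z <- se_gate(matrix(0, C, N), matrix(0, H, C), rep(0, H),
               matrix(0, C, H), rep(0, C))
  expect_equal(z$gates, rep(0.5, C))
  expect_equal(z$output, matrix(0, C, N))

  set.seed(6)
  w1 <- matrix(rnorm(H * C), H, C); b1 <- rnorm(H)
  w2 <- matrix(rnorm(C * H), C, H); b2 <- rnorm(C)
  x <- matrix(rnorm(C * N), C, N)
  g <- se_gate(x, w1, b1, w2, b2)
  expect_true(all(g$gates > 0 & g$gates < 1))

  # independent recomputation oracle with plain R arithmetic
  s <- rowMeans(x)
  gates_oracle <- 1 / (1 + exp(-(w2 %*% pmax(w1 %*% s + b1, 0) + b2)))
  expect_equal(g$gates, as.vector(gates_oracle), tolerance = 1e-12)
  expect_equal(g$output, x * as.vector(gates_oracle), tolerance = 1e-12)

  # scaling channel 2 by t: that output channel is t * x * (recomputed gate)
  t_ <- 2.5
  x2 <- x; x2[2, ] <- t_ * x[2, ]
  g2 <- se_gate(x2, w1, b1, w2, b2)
  expect_equal(g2$output[2, ], t_ * x[2, ] * g2$gates[2], tolerance = 1e-12)
})

test_that("zeroing a residual branch makes the block the identity map", {
  cfg <- micro_net()
  model <- build_model(cfg, seed = 7)
  # kill the branch at its last CBLD: conv and BN affine to zero
  model$params[["block1.cbld2.conv.w"]][] <- 0
  model$params[["block1.cbld2.conv.b"]][] <- 0
  model$params[["block1.cbld2.bn.gamma"]][] <- 0
  model$params[["block1.cbld2.bn.beta"]][] <- 0
  set.seed(8)
  x <- rnorm(128)
  y <- predict(model, x, normalize = FALSE)[1, ]

  # oracle: entry CBLD + output block only, using the same weights
  fwd <- sepsnet:::network_forward
  h <- array(x, c(1L, 128L, 1L))
  en <- sepsnet:::cbld_forward(h, model$params, model$bn_stats, "entry",
                               cfg$k_entry, cfg, training = FALSE)
  y0 <- sepsnet:::conv_forward(en$y, model$params[["out.conv.w"]],
                               model$params[["out.conv.b"]], 1L)
  bn <- sepsnet:::bn_forward(y0, model$params[["out.bn.gamma"]],
                             model$params[["out.bn.beta"]],
                             model$bn_stats[["out.bn.mean"]],
                             model$bn_stats[["out.bn.var"]], training = FALSE)
  expect_equal(y, as.vector(bn$y), tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- psnet_config(n_input = 16, channels = 4, k_entry = 3, k_res = 5,
                      n_res_blocks = 1, se_reduction = 2, dropout = 0)
  model <- build_model(cfg, seed = 42)
  set.seed(9)
  x <- matrix(rnorm(16 * 2), 16, 2)
  y <- matrix(rnorm(16 * 2), 16, 2)
  nf <- sepsnet:::network_forward
  fw <- nf(model$params, model$bn_stats, cfg, x, training = TRUE)
  grads <- sepsnet:::network_backward(2 * (fw$y - y) / length(y), fw$caches,
                                      model$params, cfg)
  loss_at <- function(params)
    mean((nf(params, model$bn_stats, cfg, x, training = TRUE)$y - y)^2)
  eps <- 1e-6
  # conv biases feeding straight into batch norm have exactly zero gradient
  expect_lt(max(abs(grads[["entry.conv.b"]])), 1e-12)
  check <- grep("conv\\.b$", names(model$params), invert = TRUE, value = TRUE)
  for (nm in check) {
    i <- which.max(abs(grads[[nm]]))         # probe the largest gradient
    pp <- model$params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- model$params; pm[[nm]][i] <- pm[[nm]][i] - eps
    num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})
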