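# One-time training of the scaled-down models shared by the reconstruction
# and ablation tests. The tiny profile (16x-reduced world, C = 16, six SE
# blocks, 350 pairs, 16 epochs, Adam 1e-2 decaying to 1e-3, batch 8) is
# fixed by compute budget; training runs once per test session and is cached.

.model_cache <- new.env(parent = emptyenv())

tiny_net <- function(use_se = TRUE) {
  psnet_config(n_input = 512L, channels = 16L, n_res_blocks = 6L,
               se_reduction = 2L, use_se = use_se)
}

tiny_world <- function(n_keep = 15L) sim_config("tiny", n_keep = n_keep)

cached <- function(key, builder) {
  if (!exists(key, envir = .model_cache))
    assign(key, builder(), envir = .model_cache)
  get(key, envir = .model_cache)
}

tiny_train_set <- function(n_keep) {
  cached(paste0("train", n_keep), function()
    generate_dataset(350, tiny_world(n_keep), seed = 3))
}

tiny_test_set <- function(n_keep) {
  cached(paste0("test", n_keep), function()
    generate_dataset(25, tiny_world(n_keep), seed = 1000 + n_keep))
}

tiny_model <- function(which = c("se16", "nose16", "se5", "mts")) {
  which <- match.arg(which)
  cached(which, function() {
    switch(which,
      se16 = sepsnet(tiny_train_set(15L), tiny_net(TRUE), epochs = 16,
                     batch_size = 8, lr = 1e-2, lr_end = 1e-3, seed = 5),
      nose16 = sepsnet(tiny_train_set(15L), tiny_net(FALSE), epochs = 16,
                       batch_size = 8, lr = 1e-2, lr_end = 1e-3, seed = 5),
      se5 = sepsnet(tiny_train_set(5L), tiny_net(TRUE), epochs = 16,
                    batch_size = 8, lr = 1e-2, lr_end = 1e-3, seed = 5),
      mts = sepsnet(generate_dataset(60, tiny_world(c(5L, 7L, 15L, 23L)),
                                     seed = 6, m_to_s = 4),
                    tiny_net(TRUE), epochs = 8, batch_size = 8, lr = 1e-2,
                    seed = 5))
  })
}

# mean per-sample peak-intensity R^2 of reconstructions over a dataset;
# samples with too few matched peaks to define a correlation (e.g. an
# untrained network that reconstructs no peaks) score 0, not NA.
mean_peak_r2 <- function(model, ds) {
  pred <- if (is.null(model)) ds$input else predict(model, ds$input)
  r2 <- vapply(seq_len(nrow(ds$input)), function(j)
    match_and_correlate(ds$label[j, ], pred[j, ])$r2_intensity, numeric(1))
  r2[is.na(r2)] <- 0
  mean(r2)
}

per_sample_rmsd <- function(model, ds) {
  pred <- predict(model, ds$input)
  vapply(seq_len(nrow(ds$input)), function(j)
    rmsd(ds$label[j, ], pred[j, ]), numeric(1))
}
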