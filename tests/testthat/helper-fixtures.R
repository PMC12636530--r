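# Shared fixtures: small model configurations, tiny random batches, and a
# memoised cache so expensive trained models are built once per test run.

bs_test_cache <- new.env(parent = emptyenv())

tiny_model_config <- function(fusion = "bridge", d_model = 8, n_heads = 2,
                              n_bridge = 2, n_layers = 2) {
  bs_model_config(d_model = d_model, n_heads = n_heads, n_bridge = n_bridge,
                  n_layers = n_layers, ffn_ratio = 2, dropout = 0,
                  droppath = 0, grr_blocks = 1, grr_ratio = 2,
                  layerscale_init = 0.5, fusion = fusion)
}

tiny_model <- function(seed = 7, d_in_drug = 3, d_in_cell = 4, ...) {
  bridgesyn(d_in_drug, d_in_cell, tiny_model_config(...), seed = seed)
}

tiny_batch <- function(seed = 1, b = 3, nd1 = 2, nd2 = 2, nc = 3,
                       d_in_drug = 3, d_in_cell = 4) {
  set.seed(seed)
  list(Xd1 = matrix(rnorm(b * nd1 * d_in_drug), b * nd1, d_in_drug), nd1 = nd1,
       Xd2 = matrix(rnorm(b * nd2 * d_in_drug), b * nd2, d_in_drug), nd2 = nd2,
       Xc = matrix(rnorm(b * nc * d_in_cell), b * nc, d_in_cell), nc = nc,
       b = b)
}

# the small study configuration used for the learnability checks; dropout
# keeps the published default rate
small_study_model_config <- function(fusion = "bridge") {
  bs_model_config(d_model = 64, n_heads = 2, n_bridge = 4, n_layers = 2,
                  ffn_ratio = 2, grr_blocks = 1, grr_ratio = 2,
                  dropout = 0.2, droppath = 0, fusion = fusion)
}

small_study_train_config <- function(seed) {
  bs_train_config(learning_rate = 2e-3, batch_size = 128, max_epochs = 45,
                  patience = 12, schedule = "cosine", seed = seed)
}

# Train the small study model (full architecture or ablation variant "e")
# on the reference synthetic regime for one seed; memoised across tests.
trained_small_study <- function(seed, variant = "full") {
  key <- paste0("fit_", variant, "_", seed)
  if (!is.null(bs_test_cache[[key]])) return(bs_test_cache[[key]])
  gen <- gen_dataset(synth_config(seed = seed))
  ds <- gen$dataset
  run <- resolve_variant(bs_run_config(
    variant = variant,
    ccf = ccf_config(k = 8, n_clusters = 8),
    model = small_study_model_config()))
  prep <- prepare_features(ds, run$feature, run$ccf)
  sp <- make_splits(ds$triplets, split_spec("random", seed = seed))
  pool <- setdiff(seq_len(nrow(ds$triplets)), sp$holdout)
  vs <- validation_split(ds$triplets, pool, "random", seed = seed)
  model <- bridgesyn(prep$d_in_drug, prep$d_in_cell, run$model, seed = seed)
  fit <- train_bridgesyn(model, prep, ds$triplets, vs$train, vs$valid,
                         small_study_train_config(seed))
  yh <- predict(fit$model, prep, ds$triplets, idx = sp$holdout)
  m <- compute_metrics(ds$triplets$y[sp$holdout], yh)
  out <- list(fit = fit, prep = prep, ds = ds, splits = sp,
              holdout_metrics = m, truth = gen$truth)
  bs_test_cache[[key]] <- out
  out
}
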