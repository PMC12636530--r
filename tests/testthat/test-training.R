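test_that("the MSE objective matches its closed form", {
  expect_equal(mse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse_loss(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
  set.seed(50)
  y <- rnorm(20); yh <- rnorm(20)
  perm <- sample(20)
  expect_equal(mse_loss(y, yh), mse_loss(y[perm], yh[perm]))
  expect_gte(mse_loss(y, yh), 0)
  expect_error(mse_loss(1:3, 1:2), "length mismatch")
})

test_that("split protocols partition groups and isolate the hold-out", {
  set.seed(51)
  drugs <- sprintf("D%02d", 1:12)
  pairs <- t(combn(drugs, 2))
  tr <- data.frame(
    drug_a = rep(pairs[, 1], 10), drug_b = rep(pairs[, 2], 10),
    cell_line = rep(sprintf("CL%02d", 1:10), each = nrow(pairs)),
    y = rnorm(nrow(pairs) * 10), stringsAsFactors = FALSE)
  # randomise drug order within pairs so both orders occur
  flip <- runif(nrow(tr)) < 0.5
  tmp <- tr$drug_a[flip]; tr$drug_a[flip] <- tr$drug_b[flip]
  tr$drug_b[flip] <- tmp

  n <- nrow(tr)
  for (scheme in c("random", "leave_cell_out", "leave_combination_out")) {
    sp <- make_splits(tr, split_spec(scheme, n_folds = 5, seed = 3))
    expect_lte(abs(length(sp$holdout) - round(0.1 * n)), 1)
    rest <- setdiff(seq_len(n), sp$holdout)
    test_union <- integer(0)
    for (fold in sp$folds) {
      expect_length(intersect(fold$test, sp$holdout), 0)
      expect_length(intersect(fold$train, fold$test), 0)
      test_union <- c(test_union, fold$test)
      if (scheme == "leave_cell_out") {
        expect_length(intersect(tr$cell_line[fold$train],
                                tr$cell_line[fold$test]), 0)
      }
      if (scheme == "leave_combination_out") {
        ktr <- pair_key(tr$drug_a[fold$train], tr$drug_b[fold$train])
        kte <- pair_key(tr$drug_a[fold$test], tr$drug_b[fold$test])
        expect_length(intersect(ktr, kte), 0)
      }
    }
    # folds cover the non-hold-out set exactly once
    expect_setequal(test_union, rest)
    expect_equal(anyDuplicated(test_union), 0L)
  }

  # leave-cell-out with 10 cell lines and 5 folds: 2 cell lines per test fold
  sp <- make_splits(tr, split_spec("leave_cell_out", n_folds = 5, seed = 9))
  for (fold in sp$folds) {
    expect_length(unique(tr$cell_line[fold$test]), 2L)
  }

  # (A,B) and (B,A) always land in the same leave-combination-out fold
  sp <- make_splits(tr, split_spec("leave_combination_out", seed = 4))
  fold_of <- integer(n)
  for (f in seq_along(sp$folds)) fold_of[sp$folds[[f]]$test] <- f
  keys <- pair_key(tr$drug_a, tr$drug_b)
  rest <- setdiff(seq_len(n), sp$holdout)
  per_key <- tapply(fold_of[rest], keys[rest], function(v) length(unique(v)))
  expect_true(all(per_key == 1))

  # fixed seed reproduces splits exactly
  expect_identical(make_splits(tr, split_spec("random", seed = 7)),
                   make_splits(tr, split_spec("random", seed = 7)))

  expect_error(make_splits(tr[tr$cell_line %in% c("CL01", "CL02"), ],
                           split_spec("leave_cell_out", n_folds = 5)),
               "distinct groups")
})

test_that("validation subsets split at the scheme's group level", {
  set.seed(52)
  tr <- data.frame(drug_a = "A", drug_b = sprintf("B%d", 1:60),
                   cell_line = rep(sprintf("CL%d", 1:6), 10),
                   y = rnorm(60), stringsAsFactors = FALSE)
  vs <- validation_split(tr, 1:60, "leave_cell_out", fraction = 0.2, seed = 1)
  expect_length(intersect(vs$train, vs$valid), 0)
  expect_setequal(c(vs$train, vs$valid), 1:60)
  expect_length(intersect(tr$cell_line[vs$train], tr$cell_line[vs$valid]), 0)
})

test_that("metrics satisfy their identities and flag undefined cases", {
  m <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$rmse, 0); expect_equal(m$r2, 1); expect_equal(m$pcc, 1)

  # hand-computed case: constant predictions at the mean
  m2 <- compute_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m2$rmse, sqrt(2 / 3))
  expect_equal(m2$r2, 0)
  expect_true(is.na(m2$pcc))
  expect_equal(m2$n, 3L)

  set.seed(53)
  y <- rnorm(30); yh <- rnorm(30)
  m3 <- compute_metrics(y, yh)
  expect_equal(m3$rmse^2, m3$mse, tolerance = 1e-12)
  expect_equal(m3$r2, 1 - m3$mse * m3$n / sum((y - mean(y))^2),
               tolerance = 1e-12)
  # PCC is invariant under positive affine rescaling of the predictions
  expect_equal(compute_metrics(y, 3 * yh + 2)$pcc, m3$pcc, tolerance = 1e-12)

  expect_true(is.na(compute_metrics(c(2, 2, 2), yh[1:3])$r2))
})

test_that("group aggregation reports per-cell-line PCC and tissue spread", {
  tr <- data.frame(drug_a = "A", drug_b = "B",
                   cell_line = rep(c("c1", "c2", "c3"), each = 4),
                   tissue = rep(c("lung", "lung", "skin"), each = 4),
                   y = rep(1:4, 3), stringsAsFactors = FALSE)
  y <- tr$y
  res <- aggregate_by_group(tr, y, y)
  expect_equal(res$per_group$pcc, rep(1, 3))
  lung <- res$per_tissue[res$per_tissue$tissue == "lung", ]
  expect_equal(lung$sd_pcc, 0)
  # a single-member tissue has no defined spread
  skin <- res$per_tissue[res$per_tissue$tissue == "skin", ]
  expect_true(is.na(skin$sd_pcc))

  # randomised check against a plain group-by loop
  set.seed(54)
  tr2 <- data.frame(drug_a = "A", drug_b = "B",
                    cell_line = sample(c("c1", "c2", "c3"), 40, TRUE),
                    y = rnorm(40), stringsAsFactors = FALSE)
  yh2 <- rnorm(40)
  res2 <- aggregate_by_group(tr2, tr2$y, yh2)
  for (g in unique(tr2$cell_line)) {
    i <- tr2$cell_line == g
    expect_equal(res2$per_group$pcc[res2$per_group$cell_line == g],
                 cor(tr2$y[i], yh2[i]), tolerance = 1e-12)
  }
})

test_that("training stops early, reproduces exactly, and learns a noiseless target", {
  # an additive, noise-free ground truth is learnable to a small fraction
  # of the score SD by the small model
  cfg <- synth_config(n_drugs = 12, n_cells = 4, n_genes = 24,
                      n_gene_modules = 3, noise_sd = 0,
                      interaction_strength = 0, n_triplets = 260, seed = 60)
  gen <- gen_dataset(cfg)
  ds <- gen$dataset
  prep <- prepare_features(ds, feature_config(), ccf_config(k = 4, n_clusters = 4))
  vs <- validation_split(ds$triplets, seq_len(260), "random", seed = 60)
  model <- bridgesyn(prep$d_in_drug, prep$d_in_cell,
                     tiny_model_config(d_model = 32, n_heads = 2,
                                       n_bridge = 2, n_layers = 2),
                     seed = 60)
  tc <- bs_train_config(learning_rate = 3e-3, batch_size = 32,
                        max_epochs = 60, patience = 60, schedule = "cosine",
                        seed = 60)
  fit <- train_bridgesyn(model, prep, ds$triplets, vs$train, vs$valid, tc)
  expect_lt(sqrt(fit$best_valid_mse), 0.1 * sd(ds$triplets$y))

  # identical seeds reproduce the whole loss curve bitwise
  model2 <- bridgesyn(prep$d_in_drug, prep$d_in_cell,
                      tiny_model_config(d_model = 32, n_heads = 2,
                                        n_bridge = 2, n_layers = 2),
                      seed = 60)
  tc2 <- tc; tc2$max_epochs <- 4L
  f1 <- train_bridgesyn(model2, prep, ds$triplets, vs$train, vs$valid, tc2)
  f2 <- train_bridgesyn(model2, prep, ds$triplets, vs$train, vs$valid, tc2)
  expect_identical(f1$log, f2$log)

  # patience = 1 stops at the first epoch whose validation MSE fails to
  # improve on the running best
  tc3 <- tc; tc3$patience <- 1L; tc3$max_epochs <- 30L
  f3 <- train_bridgesyn(model2, prep, ds$triplets, vs$train, vs$valid, tc3)
  v <- f3$log$valid_mse
  stop_epoch <- nrow(f3$log)
  expect_lt(stop_epoch, 30L)
  expect_gte(v[stop_epoch], min(v[seq_len(stop_epoch - 1)]))
  if (stop_epoch > 2) {
    # every earlier epoch improved the running best, or it would have stopped
    expect_true(all(diff(cummin(v[seq_len(stop_epoch - 1)])) < 0))
  }

  # training and validation sets must be disjoint
  expect_error(train_bridgesyn(model2, prep, ds$triplets, 1:10, 5:12, tc2),
               "overlap")
})
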