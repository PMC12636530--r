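# Training and evaluation: feature preparation with per-cell-line cluster
# caching, the three split protocols with a 10% hold-out, AdamW training
# with early stopping on validation MSE, and the RMSE / R^2 / PCC metric
# set with group-level aggregation.

#' Feature configuration
#'
#' @param drug_mode `"precomputed"` (token embedding matrices) or
#'   `"onehot_smiles"` (ablation fallback).
#' @param cell_mode `"enriched"` (expression x protein embedding) or
#'   `"expression_only"` (degenerate `D_P = 1` ablation).
#' @param vocab SMILES vocabulary for the one-hot path.
#' @param unk,max_len,two_char,pad_to passed to [one_hot_smiles()];
#'   `pad_to = "auto"` pads every drug to the longest tokenised SMILES in
#'   the dataset so batches keep uniform shapes.
#' @export
feature_config <- function(drug_mode = c("precomputed", "onehot_smiles"),
                           cell_mode = c("enriched", "expression_only"),
                           vocab = smiles_default_vocab(), unk = TRUE,
                           max_len = 128L, two_char = FALSE, pad_to = "auto") {
  list(drug_mode = match.arg(drug_mode), cell_mode = match.arg(cell_mode),
       vocab = vocab, unk = unk, max_len = max_len, two_char = two_char,
       pad_to = pad_to)
}

#' CCF encoder configuration
#'
#' @param k density neighbour count.
#' @param n_clusters cluster count `|C|`.
#' @param method clustering method.
#' @param representative cluster representative (`"mean"` or `"center"`).
#' @export
ccf_config <- function(k = 8, n_clusters = 32,
                       method = c("dpcknn", "kmeans", "dbscan"),
                       representative = "mean") {
  list(k = k, n_clusters = n_clusters, method = match.arg(method),
       representative = representative)
}

#' Prepare model-ready features for every drug and cell line
#'
#' Builds the drug token matrices (precomputed embeddings or one-hot
#' SMILES) and runs the configured clustering once per cell line on its
#' enriched (or expression-only) gene matrix, caching the cluster-level
#' features.
#'
#' @param dataset a [bs_dataset()].
#' @param feature a [feature_config()].
#' @param ccf a [ccf_config()].
#' @return list with named lists `drug` (token matrices) and `cell`
#'   (`G_c` matrices), the per-cell `clusters`, and the realised input
#'   widths `d_in_drug` / `d_in_cell`.
#' @export
prepare_features <- function(dataset, feature = feature_config(),
                             ccf = ccf_config()) {
  drugs <- dataset$drugs
  pad_to <- feature$pad_to %||% NULL
  if (identical(pad_to, "auto") && feature$drug_mode == "onehot_smiles") {
    lens <- vapply(drugs, function(d) {
      nrow(one_hot_smiles(d$smiles, feature$vocab, unk = feature$unk,
                          max_len = feature$max_len,
                          two_char = feature$two_char))
    }, integer(1))
    pad_to <- max(lens)
  } else if (identical(pad_to, "auto")) {
    pad_to <- NULL
  }
  drug_feats <- lapply(drugs, function(d) {
    if (feature$drug_mode == "precomputed") {
      if (is.null(d$tokens)) stop("drug ", d$id, " has no token matrix")
      d$tokens
    } else {
      if (is.null(d$smiles)) stop("drug ", d$id, " has no SMILES")
      one_hot_smiles(d$smiles, feature$vocab, unk = feature$unk,
                     max_len = feature$max_len, two_char = feature$two_char,
                     pad_to = pad_to)
    }
  })
  cells <- dataset$cells
  clusters <- lapply(cells, function(cc) {
    G <- if (feature$cell_mode == "enriched") {
      if (is.null(cc$G)) stop("cell line ", cc$id, " has no enriched matrix")
      cc$G
    } else {
      expression_only_features(cc$expression)
    }
    switch(ccf$method,
           dpcknn = dpc_knn(G, k = ccf$k, n_clusters = ccf$n_clusters,
                            representative = ccf$representative),
           kmeans = comparator_clustering(G, "kmeans",
                                          n_clusters = ccf$n_clusters),
           dbscan = comparator_clustering(G, "dbscan"))
  })
  cell_feats <- lapply(clusters, `[[`, "G_c")
  out <- list(drug = drug_feats, cell = cell_feats, clusters = clusters,
              d_in_drug = ncol(drug_feats[[1]]),
              d_in_cell = ncol(cell_feats[[1]]))
  # stacked copies + row maps let batch assembly use one indexing operation
  out$drug_stack <- do.call(rbind, drug_feats)
  nd <- vapply(drug_feats, nrow, integer(1))
  out$drug_rows <- split(seq_len(sum(nd)), rep(seq_along(nd), nd))
  names(out$drug_rows) <- names(drug_feats)
  out$cell_stack <- do.call(rbind, cell_feats)
  nc <- vapply(cell_feats, nrow, integer(1))
  out$cell_rows <- split(seq_len(sum(nc)), rep(seq_along(nc), nc))
  names(out$cell_rows) <- names(cell_feats)
  out
}

#' Mean squared error
#'
#' @param y,y_hat numeric vectors of equal length.
#' @return scalar `(1/N) * sum((y - y_hat)^2)`.
#' @export
mse_loss <- function(y, y_hat) {
  if (length(y) != length(y_hat)) {
    stop("length mismatch: ", length(y), " vs ", length(y_hat))
  }
  if (length(y) < 1L) stop("empty vectors")
  mean((y - y_hat)^2)
}

#' Split specification
#'
#' @param scheme `"random"` (triplet level), `"leave_cell_out"` (whole cell
#'   lines per fold) or `"leave_combination_out"` (whole unordered drug
#'   pairs per fold).
#' @param n_folds fold count.
#' @param holdout_fraction fraction reserved (triplet level) before folding.
#' @param seed RNG seed.
#' @export
split_spec <- function(scheme = c("random", "leave_cell_out",
                                  "leave_combination_out"),
                       n_folds = 5, holdout_fraction = 0.10, seed = 1L) {
  list(scheme = match.arg(scheme), n_folds = n_folds,
       holdout_fraction = holdout_fraction, seed = seed)
}

.split_groups <- function(triplets, scheme) {
  switch(scheme,
         random = as.character(seq_len(nrow(triplets))),
         leave_cell_out = triplets$cell_line,
         leave_combination_out = pair_key(triplets$drug_a, triplets$drug_b))
}

#' Create the hold-out set and cross-validation folds
#'
#' The hold-out is drawn first at triplet level; the remaining triplets are
#' folded at the scheme's group level (triplets, cell lines, or unordered
#' drug pairs), so every fold's test groups are disjoint from its training
#' groups and `(A, B)` / `(B, A)` triplets always share a fold.
#'
#' @param triplets triplet data frame.
#' @param spec a [split_spec()].
#' @return list with `holdout` (row indices), `folds` (list of
#'   `list(train, test)` index pairs) and the spec.
#' @export
make_splits <- function(triplets, spec = split_spec()) {
  set.seed(spec$seed)
  n <- nrow(triplets)
  n_hold <- round(spec$holdout_fraction * n)
  holdout <- sort(sample.int(n, n_hold))
  rest <- setdiff(seq_len(n), holdout)
  groups <- .split_groups(triplets, spec$scheme)[rest]
  ug <- unique(groups)
  if (length(ug) < spec$n_folds) {
    stop("only ", length(ug), " distinct groups for ", spec$n_folds, " folds")
  }
  perm <- sample(ug)
  gf <- rep(seq_len(spec$n_folds), length.out = length(ug))
  fold_of <- gf[match(groups, perm)]
  folds <- lapply(seq_len(spec$n_folds), function(f) {
    list(train = rest[fold_of != f], test = rest[fold_of == f])
  })
  list(holdout = holdout, folds = folds, spec = spec)
}

#' Carve a validation subset out of a training set
#'
#' Splits at the same group level as the scheme so, e.g., validation cell
#' lines are unseen during leave-cell-out training.
#'
#' @param triplets triplet data frame.
#' @param train_idx training row indices.
#' @param scheme split scheme (see [split_spec()]).
#' @param fraction validation fraction of the training groups.
#' @param seed RNG seed.
#' @return list(train, valid) of row indices.
#' @export
validation_split <- function(triplets, train_idx, scheme = "random",
                             fraction = 0.10, seed = 1L) {
  set.seed(seed)
  groups <- .split_groups(triplets, scheme)[train_idx]
  ug <- unique(groups)
  nv <- max(1L, round(fraction * length(ug)))
  vg <- sample(ug, nv)
  list(train = train_idx[!(groups %in% vg)],
       valid = train_idx[groups %in% vg])
}

#' Training configuration
#'
#' Published defaults: learning rate 1e-4, batch size 256, early-stopping
#' patience 25. AdamW is the implemented optimizer.
#'
#' @param learning_rate AdamW step size.
#' @param batch_size minibatch size.
#' @param max_epochs epoch budget.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param weight_decay decoupled weight decay on weight matrices.
#' @param warmup_epochs linear learning-rate warm-up span.
#' @param schedule learning-rate schedule after warm-up: `"constant"` or
#'   `"cosine"` (decay to 10% of the peak rate by `max_epochs`).
#' @param seed RNG seed for shuffling, dropout and DropPath.
#' @param verbose print per-epoch losses.
#' @export
bs_train_config <- function(learning_rate = 1e-4, batch_size = 256L,
                            max_epochs = 100L, patience = 25L,
                            weight_decay = 0.01, warmup_epochs = 3L,
                            schedule = c("constant", "cosine"),
                            seed = 1L, verbose = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1, patience >= 1)
  list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
       max_epochs = as.integer(max_epochs), patience = as.integer(patience),
       weight_decay = weight_decay, warmup_epochs = warmup_epochs,
       schedule = match.arg(schedule), seed = seed, verbose = verbose)
}

.lr_at <- function(config, epoch) {
  base <- config$learning_rate
  if (epoch <= config$warmup_epochs) {
    return(base * epoch / max(1, config$warmup_epochs))
  }
  if (identical(config$schedule, "cosine")) {
    span <- max(1, config$max_epochs - config$warmup_epochs)
    frac <- (epoch - config$warmup_epochs) / span
    return(base * (0.1 + 0.9 * 0.5 * (1 + cos(pi * min(1, frac)))))
  }
  base
}

# one recursive AdamW step over the parameter/gradient/moment trees; weight
# decay applies to weight matrices only (not biases, layer-norm affines or
# LayerScale vectors)
.adamw_step <- function(p, g, m, v, lr, wd, b1c, b2c) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      r <- .adamw_step(p[[i]], g[[i]], m[[i]], v[[i]], lr, wd, b1c, b2c)
      p[[i]] <- r[[1]]; m[[i]] <- r[[2]]; v[[i]] <- r[[3]]
    }
    return(list(p, m, v))
  }
  m <- 0.9 * m + 0.1 * g
  v <- 0.999 * v + 0.001 * g * g
  upd <- (m / b1c) / (sqrt(v / b2c) + 1e-8)
  if (wd > 0 && is.matrix(p)) upd <- upd + wd * p
  list(p - lr * upd, m, v)
}

.batched_mse <- function(model, prep, triplets, idx, batch_size = 512L) {
  yh <- predict(model, prep, triplets, idx = idx, batch_size = batch_size)
  mse_loss(triplets$y[idx], yh)
}

#' Train a model end-to-end with the MSE objective
#'
#' Minimises the mean squared error with AdamW, standardising the targets
#' internally by the training-set mean and SD (predictions are always
#' returned on the native score scale). Stops early when the validation MSE
#' has not improved for `patience` epochs and restores the best-validation
#' parameters.
#'
#' @param model an untrained [bridgesyn()] model.
#' @param prep prepared features from [prepare_features()].
#' @param triplets triplet data frame.
#' @param train_idx,valid_idx disjoint row-index sets.
#' @param config a [bs_train_config()].
#' @return list of class `bs_fit`: the fitted `model`, the per-epoch `log`
#'   (train/validation MSE, native units), `best_epoch` and
#'   `best_valid_mse`.
#' @export
train_bridgesyn <- function(model, prep, triplets, train_idx, valid_idx,
                            config = bs_train_config()) {
  if (length(intersect(train_idx, valid_idx)) > 0) {
    stop("train and validation sets overlap")
  }
  set.seed(config$seed)
  ytr <- triplets$y[train_idx]
  model$y_center <- mean(ytr)
  model$y_scale <- stats::sd(ytr)
  if (!is.finite(model$y_scale) || model$y_scale == 0) model$y_scale <- 1

  opt_m <- .zero_like(model$params)
  opt_v <- opt_m
  step <- 0L
  scale2 <- model$y_scale^2

  log_df <- data.frame(epoch = integer(0), train_mse = numeric(0),
                       valid_mse = numeric(0))
  best <- list(valid = Inf, params = model$params, epoch = 0L)
  wait <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    lr <- .lr_at(config, epoch)
    ord <- sample(train_idx)
    chunks <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_n <- 0L
    for (chunk in chunks) {
      # shape sub-groups share one optimizer step: gradients of the chunk's
      # mean squared error accumulate across sub-batches
      grads <- NULL
      for (sub in .shape_groups(prep, triplets, chunk)) {
        batch <- model_batch(prep, triplets$drug_a[sub], triplets$drug_b[sub],
                             triplets$cell_line[sub])
        fw <- model_forward(model, batch, train = TRUE)
        resid <- fw$yhat - triplets$y[sub]
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", epoch,
               " (batch of ", length(sub), "); consider a lower learning rate")
        }
        ep_loss <- ep_loss + loss * length(sub)
        ep_n <- ep_n + length(sub)
        dy <- 2 * resid / (length(chunk) * scale2)
        bw <- model_backward(model, fw$cache, dy)
        grads <- if (is.null(grads)) bw$grads else .tree_add(grads, bw$grads)
      }
      step <- step + 1L
      r <- .adamw_step(model$params, grads, opt_m, opt_v, lr,
                       config$weight_decay, 1 - 0.9^step, 1 - 0.999^step)
      model$params <- r[[1]]; opt_m <- r[[2]]; opt_v <- r[[3]]
    }
    valid_mse <- .batched_mse(model, prep, triplets, valid_idx)
    log_df <- rbind(log_df, data.frame(epoch = epoch,
                                       train_mse = ep_loss / ep_n,
                                       valid_mse = valid_mse))
    if (config$verbose) {
      message(sprintf("epoch %3d  train %.4f  valid %.4f", epoch,
                      ep_loss / ep_n, valid_mse))
    }
    if (valid_mse < best$valid) {
      best <- list(valid = valid_mse, params = model$params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model$params <- best$params
  structure(list(model = model, log = log_df, best_epoch = best$epoch,
                 best_valid_mse = best$valid, config = config),
            class = "bs_fit")
}

#' Regression metrics: RMSE, R^2 and Pearson correlation
#'
#' `R^2 = 1 - SS_res / SS_tot` is `NA` when the observed scores are
#' constant; the PCC is `NA` when either vector is constant. Missing values
#' are reported explicitly, never as zero.
#'
#' @param y observed scores.
#' @param y_hat predicted scores.
#' @return list of class `bs_metrics` with `rmse`, `mse`, `r2`, `pcc`, `n`.
#' @export
compute_metrics <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  if (length(y) < 2L) stop("need at least 2 observations")
  mse <- mean((y - y_hat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum((y - y_hat)^2) / ss_tot else NA_real_
  pcc <- if (stats::sd(y) > 0 && stats::sd(y_hat) > 0) {
    stats::cor(y, y_hat)
  } else NA_real_
  structure(list(rmse = sqrt(mse), mse = mse, r2 = r2, pcc = pcc,
                 n = length(y)), class = "bs_metrics")
}

#' @export
print.bs_metrics <- function(x, ...) {
  cat(sprintf("n = %d  RMSE = %.4f  R2 = %s  PCC = %s\n", x$n, x$rmse,
              ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2)),
              ifelse(is.na(x$pcc), "NA", sprintf("%.4f", x$pcc))))
  invisible(x)
}

#' Metrics aggregated by group, with intra-tissue spread
#'
#' Computes per-group (default: per cell line) metrics and, when a `tissue`
#' column is present, the mean and standard deviation of the member
#' cell-line PCCs within each tissue. Groups with fewer than two
#' observations, and single-member tissues, are reported with `NA`.
#'
#' @param triplets triplet data frame aligned with `y` / `y_hat`.
#' @param y,y_hat observed and predicted scores.
#' @param group grouping column, default `"cell_line"`.
#' @return list with data frames `per_group` and (when tissues are known)
#'   `per_tissue`.
#' @export
aggregate_by_group <- function(triplets, y, y_hat, group = "cell_line") {
  stopifnot(group %in% names(triplets), nrow(triplets) == length(y),
            length(y) == length(y_hat))
  gvals <- triplets[[group]]
  ug <- unique(gvals)
  per_group <- do.call(rbind, lapply(ug, function(g) {
    i <- which(gvals == g)
    if (length(i) < 2L) {
      return(data.frame(group = g, n = length(i), rmse = NA_real_,
                        r2 = NA_real_, pcc = NA_real_))
    }
    m <- compute_metrics(y[i], y_hat[i])
    data.frame(group = g, n = m$n, rmse = m$rmse, r2 = m$r2, pcc = m$pcc)
  }))
  names(per_group)[1] <- group
  out <- list(per_group = per_group)
  if (group == "cell_line" && "tissue" %in% names(triplets)) {
    tissue_of <- tapply(triplets$tissue, triplets$cell_line, `[`, 1L)
    per_group$tissue <- tissue_of[per_group$cell_line]
    out$per_tissue <- do.call(rbind, lapply(split(per_group, per_group$tissue),
                                            function(d) {
      pc <- d$pcc[!is.na(d$pcc)]
      data.frame(tissue = d$tissue[1], n_cell_lines = nrow(d),
                 mean_pcc = if (length(pc)) mean(pc) else NA_real_,
                 sd_pcc = if (length(pc) >= 2) stats::sd(pc) else NA_real_)
    }))
    rownames(out$per_tissue) <- NULL
    out$per_group <- per_group
  }
  out
}
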