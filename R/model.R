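# Full model assembly: projectors -> bridge fusion (or plain transformer
# fusion) -> dual-path GRR head, with a hand-derived backward pass for
# end-to-end training and input attributions.

#' Model architecture configuration
#'
#' Defaults follow the published configuration: width 1024, three fusion
#' layers, dropout 0.2. The small presets used in the package's synthetic
#' studies override these.
#'
#' @param d_model fusion width `D` (hidden units).
#' @param n_heads attention heads (must divide `d_model`).
#' @param n_bridge number of bridge tokens `N_b`.
#' @param n_layers number of fusion layers `L_f`.
#' @param ffn_ratio BAU feed-forward inner width multiple.
#' @param dropout dropout rate on attention weights and BAU feed-forward
#'   activations (training only).
#' @param droppath GRR DropPath rate (training only).
#' @param layerscale_init initial LayerScale value in GRR blocks.
#' @param grr_blocks GRR blocks per head path.
#' @param grr_ratio SwiGLU inner width multiple in GRR blocks.
#' @param fusion `"bridge"` (default) or `"plain"` (ablation variant that
#'   self-attends over the concatenated sequences).
#' @param bridge_mode `"pooled"` (tokens derived from global pooled
#'   features) or `"learned"` (constant learnable tokens).
#' @param ln_eps layer-norm epsilon.
#' @return a list of class `bs_model_config`.
#' @export
bs_model_config <- function(d_model = 1024, n_heads = 8, n_bridge = 8,
                            n_layers = 3, ffn_ratio = 4, dropout = 0.2,
                            droppath = 0.1, layerscale_init = 1e-4,
                            grr_blocks = 2, grr_ratio = 4,
                            fusion = c("bridge", "plain"),
                            bridge_mode = c("pooled", "learned"),
                            ln_eps = 1e-5) {
  fusion <- match.arg(fusion)
  bridge_mode <- match.arg(bridge_mode)
  stopifnot(d_model %% n_heads == 0, n_layers >= 1, n_bridge >= 1)
  structure(list(d_model = d_model, n_heads = n_heads, n_bridge = n_bridge,
                 n_layers = n_layers, ffn_ratio = ffn_ratio, dropout = dropout,
                 droppath = droppath, layerscale_init = layerscale_init,
                 grr_blocks = grr_blocks, grr_ratio = grr_ratio,
                 fusion = fusion, bridge_mode = bridge_mode, ln_eps = ln_eps),
            class = "bs_model_config")
}

#' Construct an untrained model
#'
#' @param d_in_drug drug token embedding width `D_in`.
#' @param d_in_cell enriched cell feature width `D_P`.
#' @param config a [bs_model_config()].
#' @param seed integer seed for parameter initialisation.
#' @return object of class `bridgesyn` holding parameters and configuration.
#' @export
bridgesyn <- function(d_in_drug, d_in_cell, config = bs_model_config(),
                      seed = 1L) {
  set.seed(seed)
  cf <- config
  d <- cf$d_model
  params <- list(drug_proj = proj_init(d_in_drug, d),
                 cell_proj = proj_init(d_in_cell, d))
  if (cf$fusion == "bridge") {
    params$bridge <- bridge_init(d, cf$n_bridge, cf$bridge_mode)
    params$layers <- lapply(seq_len(cf$n_layers), function(i)
      fusion_layer_init(d, cf$ffn_ratio))
  } else {
    params$layers <- lapply(seq_len(cf$n_layers), function(i)
      bau_init(d, cf$ffn_ratio))
  }
  params$head <- head_init(d, cf$grr_blocks, cf$grr_ratio, cf$layerscale_init)
  structure(list(params = params, config = cf,
                 d_in_drug = d_in_drug, d_in_cell = d_in_cell,
                 y_center = 0, y_scale = 1),
            class = "bridgesyn")
}

.tree_add <- function(a, b) {
  if (is.list(a)) return(mapply(.tree_add, a, b, SIMPLIFY = FALSE))
  a + b
}

# batch: list(Xd1, nd1, Xd2, nd2, Xc, nc, b) in the sample-major block layout
model_forward <- function(model, batch, train = FALSE) {
  cf <- model$config
  p <- model$params
  b <- batch$b
  cfg_a <- list(h = cf$n_heads, eps = cf$ln_eps, train = train,
                dropout = cf$dropout)
  cfg_h <- list(train = train, droppath = cf$droppath, eps = cf$ln_eps)
  pd1 <- proj_fwd(batch$Xd1, p$drug_proj, eps = cf$ln_eps)
  pd2 <- proj_fwd(batch$Xd2, p$drug_proj, eps = cf$ln_eps)
  pc <- proj_fwd(batch$Xc, p$cell_proj, eps = cf$ln_eps)
  n_scores <- 0
  if (cf$fusion == "bridge") {
    bg <- bridge_fwd(pd1$out, batch$nd1, pd2$out, batch$nd2, pc$out, batch$nc,
                     b, p$bridge, cf$n_bridge, cf$bridge_mode)
    state <- list(H = list(d1 = pd1$out, d2 = pd2$out, c = pc$out, b = bg$out),
                  n = c(d1 = batch$nd1, d2 = batch$nd2, c = batch$nc,
                        b = cf$n_bridge),
                  b = b, layer_index = 0L)
    lcaches <- vector("list", cf$n_layers)
    for (i in seq_len(cf$n_layers)) {
      r <- fusion_layer_fwd(state, p$layers[[i]], cfg_a)
      state <- r$state
      n_scores <- n_scores + r$n_scores
      lcaches[[i]] <- r$cache
    }
    hd <- head_fwd(state, p$head, cfg_h)
    cache <- list(kind = "bridge", pd1 = pd1$cache, pd2 = pd2$cache,
                  pc = pc$cache, bg = bg$cache, layers = lcaches,
                  head = hd$cache, batch = batch, cfg_a = cfg_a, cfg_h = cfg_h)
  } else {
    ntot <- batch$nd1 + batch$nd2 + batch$nc
    x12 <- seq_cat2(pd1$out, batch$nd1, pd2$out, batch$nd2, b)
    x <- seq_cat2(x12, batch$nd1 + batch$nd2, pc$out, batch$nc, b)
    lcaches <- vector("list", cf$n_layers)
    for (i in seq_len(cf$n_layers)) {
      r <- plain_layer_fwd(x, ntot, b, p$layers[[i]], cfg_a)
      x <- r$out
      n_scores <- n_scores + r$n_scores
      lcaches[[i]] <- r$cache
    }
    sp <- seq_uncat2(x, batch$nd1 + batch$nd2, batch$nc, b)
    sp12 <- seq_uncat2(sp$x1, batch$nd1, batch$nd2, b)
    state <- list(H = list(d1 = sp12$x1, d2 = sp12$x2, c = sp$x2,
                           b = matrix(numeric(0), 0L, cf$d_model)),
                  n = c(d1 = batch$nd1, d2 = batch$nd2, c = batch$nc, b = 0L),
                  b = b, layer_index = cf$n_layers)
    hd <- head_fwd(state, p$head, cfg_h)
    cache <- list(kind = "plain", pd1 = pd1$cache, pd2 = pd2$cache,
                  pc = pc$cache, layers = lcaches, head = hd$cache,
                  batch = batch, cfg_a = cfg_a, cfg_h = cfg_h)
  }
  list(yhat = model$y_center + model$y_scale * hd$out,
       raw = hd$out, cache = cache, n_scores = n_scores)
}

# dy: gradient of the loss wrt the native-scale predictions (length b)
model_backward <- function(model, cache, dy, input_grads = FALSE) {
  cf <- model$config
  p <- model$params
  batch <- cache$batch
  b <- batch$b
  dyr <- dy * model$y_scale
  hb <- head_bwd(dyr, p$head, cache$head, cache$cfg_h)
  grads <- list()
  if (cache$kind == "bridge") {
    dH <- hb$dH
    lg <- vector("list", cf$n_layers)
    for (i in rev(seq_len(cf$n_layers))) {
      r <- fusion_layer_bwd(dH, p$layers[[i]], cache$layers[[i]], cache$cfg_a)
      dH <- r$dH
      lg[[i]] <- r$grads
    }
    bgb <- bridge_bwd(dH$b, p$bridge, cache$bg)
    dHd1 <- dH$d1; dHd2 <- dH$d2; dHc <- dH$c
    if (!is.null(bgb$dHd1)) {
      dHd1 <- dHd1 + bgb$dHd1
      dHd2 <- dHd2 + bgb$dHd2
      dHc <- dHc + bgb$dHc
    }
    g1 <- proj_bwd(dHd1, p$drug_proj, cache$pd1)
    g2 <- proj_bwd(dHd2, p$drug_proj, cache$pd2)
    gc_ <- proj_bwd(dHc, p$cell_proj, cache$pc)
    grads <- list(drug_proj = .tree_add(g1$grads, g2$grads),
                  cell_proj = gc_$grads,
                  bridge = bgb$grads,
                  layers = lg,
                  head = hb$grads)
  } else {
    dx12 <- seq_cat2(hb$dH$d1, batch$nd1, hb$dH$d2, batch$nd2, b)
    dx <- seq_cat2(dx12, batch$nd1 + batch$nd2, hb$dH$c, batch$nc, b)
    lg <- vector("list", cf$n_layers)
    for (i in rev(seq_len(cf$n_layers))) {
      r <- plain_layer_bwd(dx, p$layers[[i]], cache$layers[[i]], cache$cfg_a)
      dx <- r$dx
      lg[[i]] <- r$grads
    }
    sp <- seq_uncat2(dx, batch$nd1 + batch$nd2, batch$nc, b)
    sp12 <- seq_uncat2(sp$x1, batch$nd1, batch$nd2, b)
    g1 <- proj_bwd(sp12$x1, p$drug_proj, cache$pd1)
    g2 <- proj_bwd(sp12$x2, p$drug_proj, cache$pd2)
    gc_ <- proj_bwd(sp$x2, p$cell_proj, cache$pc)
    grads <- list(drug_proj = .tree_add(g1$grads, g2$grads),
                  cell_proj = gc_$grads,
                  layers = lg,
                  head = hb$grads)
  }
  out <- list(grads = grads)
  if (input_grads) {
    out$dXd1 <- g1$dx
    out$dXd2 <- g2$dx
    out$dXc <- gc_$dx
  }
  out
}

# assemble a uniform-shape batch from prepared features
# prep: list(drug = named list of token matrices, cell = named list of G_c),
# plus optional stacked copies (drug_stack/drug_rows, cell_stack/cell_rows)
# used as a fast gather path when every id is covered
model_batch <- function(prep, drug_a, drug_b, cell) {
  fast <- !is.null(prep$drug_stack) &&
    all(c(drug_a, drug_b) %in% names(prep$drug_rows)) &&
    all(cell %in% names(prep$cell_rows))
  if (fast) {
    ra <- unlist(prep$drug_rows[drug_a], use.names = FALSE)
    rb <- unlist(prep$drug_rows[drug_b], use.names = FALSE)
    rc <- unlist(prep$cell_rows[cell], use.names = FALSE)
    return(list(Xd1 = prep$drug_stack[ra, , drop = FALSE],
                nd1 = length(prep$drug_rows[[drug_a[1]]]),
                Xd2 = prep$drug_stack[rb, , drop = FALSE],
                nd2 = length(prep$drug_rows[[drug_b[1]]]),
                Xc = prep$cell_stack[rc, , drop = FALSE],
                nc = length(prep$cell_rows[[cell[1]]]),
                b = length(drug_a)))
  }
  ta <- prep$drug[drug_a]
  tb <- prep$drug[drug_b]
  tc <- prep$cell[cell]
  list(Xd1 = do.call(rbind, ta), nd1 = nrow(ta[[1]]),
       Xd2 = do.call(rbind, tb), nd2 = nrow(tb[[1]]),
       Xc = do.call(rbind, tc), nc = nrow(tc[[1]]),
       b = length(drug_a))
}

# group triplet indices by sequence-shape signature so each forward pass
# sees uniform shapes
.shape_groups <- function(prep, triplets, idx) {
  nd <- vapply(prep$drug, nrow, integer(1))
  nc <- vapply(prep$cell, nrow, integer(1))
  sig <- paste(nd[triplets$drug_a[idx]], nd[triplets$drug_b[idx]],
               nc[triplets$cell_line[idx]])
  split(idx, sig)
}

#' Predict synergy scores for triplets
#'
#' Evaluation-mode forward pass (no dropout, no DropPath): identical inputs
#' give identical predictions.
#'
#' @param object a trained `bridgesyn` model.
#' @param prep prepared features from [prepare_features()].
#' @param triplets triplet data frame (columns `drug_a`, `drug_b`,
#'   `cell_line`).
#' @param idx optional row indices to predict (default: all rows).
#' @param batch_size forward-pass batch size.
#' @param swap_drugs if `TRUE`, feed each pair in (drug_b, drug_a) order.
#' @param ... unused.
#' @return numeric vector of predictions aligned with `idx`.
#' @export
predict.bridgesyn <- function(object, prep, triplets, idx = NULL,
                              batch_size = 256L, swap_drugs = FALSE, ...) {
  if (is.null(idx)) idx <- seq_len(nrow(triplets))
  out <- numeric(length(idx))
  groups <- .shape_groups(prep, triplets, idx)
  for (g in groups) {
    chunks <- split(g, ceiling(seq_along(g) / batch_size))
    for (ch in chunks) {
      da <- triplets$drug_a[ch]; db <- triplets$drug_b[ch]
      if (swap_drugs) { tmp <- da; da <- db; db <- tmp }
      batch <- model_batch(prep, da, db, triplets$cell_line[ch])
      out[match(ch, idx)] <- model_forward(object, batch, train = FALSE)$yhat
    }
  }
  out
}
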