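# Bridge fusion module: bridge-token generation from pooled global features
# and iterative parallel Bridge Attention Unit (BAU) layers.
#
# A BAU updates a query sequence H_m from a context sequence H_n:
#   H' = MHCA(LN(H_m), LN([H_n; H_m])) + H_m
#   out = FFN(LN(H')) + H'
# where the keys/values of the multi-head cross attention are the per-sample
# concatenation of the context and the query sequence, in that order. One
# fusion layer applies four BAUs in parallel (layer-i inputs only): the two
# drug sequences and the cell sequence each attend to the bridge tokens, and
# the bridge tokens attend to [H_c; H_d2; H_d1].

bau_init <- function(d, ffn_ratio = 4) {
  d_ffn <- round(ffn_ratio * d)
  # Wkv holds the key and value projections side by side (one wide GEMM)
  list(ln1 = nn_ln_init(d),
       Wq = nn_linear_init(d, d), Wkv = nn_linear_init(d, 2 * d),
       Wo = nn_linear_init(d, d),
       ln2 = nn_ln_init(d),
       W1 = nn_linear_init(d, d_ffn), W2 = nn_linear_init(d_ffn, d))
}

# cfg: list(h = n_heads, eps, train = logical, dropout = rate)
bau_fwd <- function(Hm, nm, Hn, nn_, b, p, cfg) {
  d <- ncol(Hm)
  h <- cfg$h
  lnm <- nn_ln_fwd(Hm, p$ln1, eps = cfg$eps)
  lnn <- nn_ln_fwd(Hn, p$ln1, eps = cfg$eps)
  nk <- nn_ + nm
  kv_in <- seq_cat2(lnn$out, nn_, lnm$out, nm, b)
  q <- nn_linear_fwd(lnm$out, p$Wq)
  kv <- nn_linear_fwd(kv_in, p$Wkv)
  mask <- NULL
  if (isTRUE(cfg$train) && cfg$dropout > 0) {
    mask <- nn_dropmask(b * h * nm, nk, cfg$dropout)
  }
  at <- cpp_attn_forward(q$out, kv$out, nm, nk, b, h, 1 / sqrt(d / h), mask)
  o <- nn_linear_fwd(at$O, p$Wo)
  H1 <- Hm + o$out
  ln2 <- nn_ln_fwd(H1, p$ln2, eps = cfg$eps)
  f1 <- nn_linear_fwd(ln2$out, p$W1)
  g1 <- nn_gelu_fwd(f1$out)
  fmask <- NULL
  hdrop <- g1$out
  if (isTRUE(cfg$train) && cfg$dropout > 0) {
    fmask <- nn_dropmask(nrow(hdrop), ncol(hdrop), cfg$dropout)
    hdrop <- hdrop * fmask
  }
  f2 <- nn_linear_fwd(hdrop, p$W2)
  list(out = H1 + f2$out,
       A = at$A,
       n_scores = nm * nk,
       cache = list(lnm = lnm$cache, lnn = lnn$cache, q = q$cache,
                    kv = kv$cache, mask = mask, fmask = fmask,
                    qout = q$out, kvout = kv$out, A = at$A,
                    o = o$cache, ln2 = ln2$cache, f1 = f1$cache, g1 = g1$cache,
                    f2 = f2$cache, nm = nm, nn_ = nn_, b = b, h = h, d = d))
}

bau_bwd <- function(dout, p, cache, cfg) {
  nm <- cache$nm; nn_ <- cache$nn_; b <- cache$b; h <- cache$h; d <- cache$d
  nk <- nn_ + nm
  # FFN sublayer
  dH1 <- dout
  f2b <- nn_linear_bwd(dout, p$W2, cache$f2)
  dhdrop <- f2b$dx
  if (!is.null(cache$fmask)) dhdrop <- dhdrop * cache$fmask
  df1 <- nn_gelu_bwd(dhdrop, cache$g1)
  f1b <- nn_linear_bwd(df1, p$W1, cache$f1)
  ln2b <- nn_ln_bwd(f1b$dx, p$ln2, cache$ln2)
  dH1 <- dH1 + ln2b$dx
  # attention sublayer
  dHm <- dH1
  ob <- nn_linear_bwd(dH1, p$Wo, cache$o)
  atb <- cpp_attn_backward(ob$dx, cache$qout, cache$kvout, cache$A,
                           nm, nk, b, h, 1 / sqrt(d / h), cache$mask)
  qb <- nn_linear_bwd(atb$dQ, p$Wq, cache$q)
  kvb <- nn_linear_bwd(atb$dKV, p$Wkv, cache$kv)
  dkv <- seq_uncat2(kvb$dx, nn_, nm, b)
  dlnm <- qb$dx + dkv$x2
  dlnn <- dkv$x1
  lnmb <- nn_ln_bwd(dlnm, p$ln1, cache$lnm)
  lnnb <- nn_ln_bwd(dlnn, p$ln1, cache$lnn)
  dHm <- dHm + lnmb$dx
  grads <- list(ln1 = list(g = lnmb$grads$g + lnnb$grads$g,
                           b = lnmb$grads$b + lnnb$grads$b),
                Wq = qb$grads, Wkv = kvb$grads, Wo = ob$grads,
                ln2 = ln2b$grads, W1 = f1b$grads, W2 = f2b$grads)
  list(dHm = dHm, dHn = lnnb$dx, grads = grads)
}

# ---- bridge token generation ------------------------------------------------

bridge_init <- function(d, n_bridge, mode = "pooled") {
  if (mode == "learned") {
    return(list(B0 = matrix(stats::rnorm(n_bridge * d, sd = 0.02), n_bridge, d)))
  }
  list(w_d = list(w = stats::rnorm(d, sd = 1 / sqrt(d)), a = 0),
       w_c = list(w = stats::rnorm(d, sd = 1 / sqrt(d)), a = 0),
       map = nn_linear_init(9 * d, n_bridge * d))
}

bridge_fwd <- function(Hd1, nd1, Hd2, nd2, Hc, nc, b, p, n_bridge, mode = "pooled") {
  d <- ncol(Hd1)
  if (mode == "learned") {
    out <- p$B0[rep(seq_len(n_bridge), times = b), , drop = FALSE]
    return(list(out = out, cache = list(mode = mode, b = b, n_bridge = n_bridge)))
  }
  pool3 <- function(x, n, wp) {
    list(mx = seq_max_pool_fwd(x, n, b),
         mn = seq_mean_pool_fwd(x, n, b),
         at = seq_attn_pool_fwd(x, n, b, wp))
  }
  p1 <- pool3(Hd1, nd1, p$w_d)
  p2 <- pool3(Hd2, nd2, p$w_d)
  pc <- pool3(Hc, nc, p$w_c)
  z <- cbind(p1$mx$out, p1$mn$out, p1$at$out,
             p2$mx$out, p2$mn$out, p2$at$out,
             pc$mx$out, pc$mn$out, pc$at$out)
  zo <- nn_linear_fwd(z, p$map)
  out <- matrix(t(zo$out), ncol = d, byrow = TRUE)
  list(out = out,
       cache = list(mode = mode, p1 = p1, p2 = p2, pc = pc, z = zo$cache,
                    b = b, d = d, n_bridge = n_bridge))
}

bridge_bwd <- function(dout, p, cache) {
  if (cache$mode == "learned") {
    grp <- rep(seq_len(cache$n_bridge), times = cache$b)
    return(list(dHd1 = NULL, dHd2 = NULL, dHc = NULL,
                grads = list(B0 = rowsum(dout, grp, reorder = FALSE))))
  }
  b <- cache$b; d <- cache$d
  dzo <- matrix(t(dout), nrow = b, byrow = TRUE)
  zb <- nn_linear_bwd(dzo, p$map, cache$z)
  dz <- zb$dx
  blk <- function(i) dz[, ((i - 1) * d + 1):(i * d), drop = FALSE]
  unpool <- function(pp, wp, i0) {
    dmx <- seq_max_pool_bwd(blk(i0), pp$mx$cache)
    dmn <- seq_mean_pool_bwd(blk(i0 + 1), pp$mn$cache)
    atb <- seq_attn_pool_bwd(blk(i0 + 2), wp, pp$at$cache)
    list(dx = dmx + dmn + atb$dx, gw = atb$grads)
  }
  u1 <- unpool(cache$p1, p$w_d, 1)
  u2 <- unpool(cache$p2, p$w_d, 4)
  uc <- unpool(cache$pc, p$w_c, 7)
  list(dHd1 = u1$dx, dHd2 = u2$dx, dHc = uc$dx,
       grads = list(w_d = list(w = u1$gw$w + u2$gw$w, a = u1$gw$a + u2$gw$a),
                    w_c = uc$gw,
                    map = zb$grads))
}

# ---- fusion layers ----------------------------------------------------------

fusion_layer_init <- function(d, ffn_ratio = 4) {
  list(d1 = bau_init(d, ffn_ratio), d2 = bau_init(d, ffn_ratio),
       c = bau_init(d, ffn_ratio), b = bau_init(d, ffn_ratio))
}

# state: list(H = list(d1, d2, c, b), n = named counts, b = batch size)
fusion_layer_fwd <- function(state, p, cfg) {
  H <- state$H; n <- state$n; b <- state$b
  u1 <- bau_fwd(H$d1, n[["d1"]], H$b, n[["b"]], b, p$d1, cfg)
  u2 <- bau_fwd(H$d2, n[["d2"]], H$b, n[["b"]], b, p$d2, cfg)
  uc <- bau_fwd(H$c, n[["c"]], H$b, n[["b"]], b, p$c, cfg)
  cat_cd2 <- seq_cat2(H$c, n[["c"]], H$d2, n[["d2"]], b)
  ctx <- seq_cat2(cat_cd2, n[["c"]] + n[["d2"]], H$d1, n[["d1"]], b)
  ub <- bau_fwd(H$b, n[["b"]], ctx, n[["c"]] + n[["d2"]] + n[["d1"]], b, p$b, cfg)
  out <- state
  out$H <- list(d1 = u1$out, d2 = u2$out, c = uc$out, b = ub$out)
  out$layer_index <- (state$layer_index %||% 0L) + 1L
  list(state = out,
       A = list(d1 = u1$A, d2 = u2$A, c = uc$A, b = ub$A),
       n_scores = u1$n_scores + u2$n_scores + uc$n_scores + ub$n_scores,
       cache = list(u1 = u1$cache, u2 = u2$cache, uc = uc$cache, ub = ub$cache,
                    n = n, b = b))
}

fusion_layer_bwd <- function(dstate, p, cache, cfg) {
  n <- cache$n; b <- cache$b
  b1 <- bau_bwd(dstate$d1, p$d1, cache$u1, cfg)
  b2 <- bau_bwd(dstate$d2, p$d2, cache$u2, cfg)
  bc <- bau_bwd(dstate$c, p$c, cache$uc, cfg)
  bb <- bau_bwd(dstate$b, p$b, cache$ub, cfg)
  # split the bridge BAU's context gradient back into [c; d2; d1]
  sp1 <- seq_uncat2(bb$dHn, n[["c"]] + n[["d2"]], n[["d1"]], b)
  sp2 <- seq_uncat2(sp1$x1, n[["c"]], n[["d2"]], b)
  list(dH = list(d1 = b1$dHm + sp1$x2,
                 d2 = b2$dHm + sp2$x2,
                 c = bc$dHm + sp2$x1,
                 b = bb$dHm + b1$dHn + b2$dHn + bc$dHn),
       grads = list(d1 = b1$grads, d2 = b2$grads, c = bc$grads, b = bb$grads))
}

# ---- plain transformer fusion (ablation variant a) --------------------------

plain_layer_fwd <- function(x, n, b, p, cfg) {
  d <- ncol(x); h <- cfg$h
  lx <- nn_ln_fwd(x, p$ln1, eps = cfg$eps)
  q <- nn_linear_fwd(lx$out, p$Wq)
  kv <- nn_linear_fwd(lx$out, p$Wkv)
  mask <- NULL
  if (isTRUE(cfg$train) && cfg$dropout > 0) mask <- nn_dropmask(b * h * n, n, cfg$dropout)
  at <- cpp_attn_forward(q$out, kv$out, n, n, b, h, 1 / sqrt(d / h), mask)
  o <- nn_linear_fwd(at$O, p$Wo)
  H1 <- x + o$out
  ln2 <- nn_ln_fwd(H1, p$ln2, eps = cfg$eps)
  f1 <- nn_linear_fwd(ln2$out, p$W1)
  g1 <- nn_gelu_fwd(f1$out)
  hdrop <- g1$out
  fmask <- NULL
  if (isTRUE(cfg$train) && cfg$dropout > 0) {
    fmask <- nn_dropmask(nrow(hdrop), ncol(hdrop), cfg$dropout)
    hdrop <- hdrop * fmask
  }
  f2 <- nn_linear_fwd(hdrop, p$W2)
  list(out = H1 + f2$out, A = at$A, n_scores = n * n,
       cache = list(lx = lx$cache, q = q$cache, kv = kv$cache,
                    qout = q$out, kvout = kv$out, A = at$A,
                    mask = mask, fmask = fmask, o = o$cache, ln2 = ln2$cache,
                    f1 = f1$cache, g1 = g1$cache, f2 = f2$cache,
                    n = n, b = b, h = h, d = d))
}

plain_layer_bwd <- function(dout, p, cache, cfg) {
  n <- cache$n; b <- cache$b; h <- cache$h; d <- cache$d
  dH1 <- dout
  f2b <- nn_linear_bwd(dout, p$W2, cache$f2)
  dhdrop <- f2b$dx
  if (!is.null(cache$fmask)) dhdrop <- dhdrop * cache$fmask
  df1 <- nn_gelu_bwd(dhdrop, cache$g1)
  f1b <- nn_linear_bwd(df1, p$W1, cache$f1)
  ln2b <- nn_ln_bwd(f1b$dx, p$ln2, cache$ln2)
  dH1 <- dH1 + ln2b$dx
  dx <- dH1
  ob <- nn_linear_bwd(dH1, p$Wo, cache$o)
  atb <- cpp_attn_backward(ob$dx, cache$qout, cache$kvout, cache$A,
                           n, n, b, h, 1 / sqrt(d / h), cache$mask)
  qb <- nn_linear_bwd(atb$dQ, p$Wq, cache$q)
  kvb <- nn_linear_bwd(atb$dKV, p$Wkv, cache$kv)
  lxb <- nn_ln_bwd(qb$dx + kvb$dx, p$ln1, cache$lx)
  dx <- dx + lxb$dx
  list(dx = dx,
       grads = list(ln1 = lxb$grads, Wq = qb$grads, Wkv = kvb$grads,
                    Wo = ob$grads, ln2 = ln2b$grads,
                    W1 = f1b$grads, W2 = f2b$grads))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- exported single-sample surfaces ----------------------------------------

#' Construct a fusion state
#'
#' Bundles the four evolving sequences of the bridge fusion module: the two
#' projected drug token matrices, the projected cell-line cluster features,
#' and the bridge tokens.
#'
#' @param H_d1,H_d2 projected drug token matrices (`N_d x D`).
#' @param H_c projected cell-line cluster matrix (`|C| x D`).
#' @param B bridge token matrix (`N_b x D`).
#' @param layer_index fusion layer counter, 0 before any layer is applied.
#' @return an object of class `bs_fusion_state`.
#' @export
fusion_state <- function(H_d1, H_d2, H_c, B, layer_index = 0L) {
  d <- ncol(H_d1)
  stopifnot(ncol(H_d2) == d, ncol(H_c) == d, ncol(B) == d)
  structure(list(H_d1 = H_d1, H_d2 = H_d2, H_c = H_c, B = B,
                 layer_index = as.integer(layer_index)),
            class = "bs_fusion_state")
}

.state_to_batch <- function(state) {
  list(H = list(d1 = state$H_d1, d2 = state$H_d2, c = state$H_c, b = state$B),
       n = c(d1 = nrow(state$H_d1), d2 = nrow(state$H_d2),
             c = nrow(state$H_c), b = nrow(state$B)),
       b = 1L, layer_index = state$layer_index)
}

.batch_to_state <- function(bs) {
  fusion_state(bs$H$d1, bs$H$d2, bs$H$c, bs$H$b,
               layer_index = bs$layer_index %||% 0L)
}

#' Generate bridge tokens from global pooled features
#'
#' Each of the three projected sequences is summarised by a global max-pool,
#' mean-pool, and attention-pool vector (a learned scalar score per token,
#' softmax-normalised over the sequence). The nine pooled vectors are
#' concatenated and a learned linear map emits `N_b` bridge tokens of width
#' `D`. The two drug sequences share one attention-pool scorer. With
#' `mode = "learned"` a constant learnable token matrix is returned instead.
#'
#' @param H_d1,H_d2,H_c projected sequences (`rows x D`).
#' @param params bridge parameters from [init_bridge_params()].
#' @param mode `"pooled"` (data-dependent tokens, the default) or `"learned"`.
#' @return `N_b x D` bridge token matrix.
#' @export
generate_bridge_tokens <- function(H_d1, H_d2, H_c, params, mode = "pooled") {
  stopifnot(nrow(H_d1) >= 1L, nrow(H_d2) >= 1L, nrow(H_c) >= 1L)
  n_bridge <- if (mode == "learned") nrow(params$B0) else
    ncol(params$map$W) / ncol(H_d1)
  bridge_fwd(H_d1, nrow(H_d1), H_d2, nrow(H_d2), H_c, nrow(H_c), 1L,
             params, n_bridge, mode = mode)$out
}

#' Initialise bridge-token generation parameters
#'
#' @param d fusion width `D`.
#' @param n_bridge number of bridge tokens `N_b`.
#' @param mode `"pooled"` or `"learned"`.
#' @export
init_bridge_params <- function(d, n_bridge, mode = "pooled") {
  bridge_init(d, n_bridge, mode)
}

#' Apply one Bridge Attention Unit
#'
#' Computes `H' = MHCA(LN(H_m), LN([H_n; H_m])) + H_m` followed by
#' `out = FFN(LN(H')) + H'`. Keys and values are the concatenation of the
#' context sequence `H_n` and the query sequence `H_m`, in that order.
#'
#' @param H_m query sequence (`N_m x D`); the output has this shape.
#' @param H_n context sequence (`N_n x D`).
#' @param params BAU parameters from [init_bau_params()].
#' @param n_heads number of attention heads (must divide `D`).
#' @param eps layer-norm epsilon.
#' @param return_attention if `TRUE`, attach the softmax attention weights
#'   (one `N_m x (N_n + N_m)` block per head) as attribute `"attention"`.
#' @return updated query sequence, same shape as `H_m`.
#' @export
bau <- function(H_m, H_n, params, n_heads = 8, eps = 1e-5,
                return_attention = FALSE) {
  if (ncol(H_m) != ncol(H_n)) stop("H_m and H_n widths differ")
  if (ncol(H_m) %% n_heads != 0) stop("n_heads must divide the width D")
  cfg <- list(h = n_heads, eps = eps, train = FALSE, dropout = 0)
  r <- bau_fwd(H_m, nrow(H_m), H_n, nrow(H_n), 1L, params, cfg)
  out <- r$out
  if (return_attention) attr(out, "attention") <- r$A
  out
}

#' Initialise BAU parameters
#'
#' @param d fusion width `D`.
#' @param ffn_ratio feed-forward inner width as a multiple of `D`.
#' @export
init_bau_params <- function(d, ffn_ratio = 4) bau_init(d, ffn_ratio)

#' Initialise one fusion layer (four BAUs)
#' @inheritParams init_bau_params
#' @export
init_fusion_layer_params <- function(d, ffn_ratio = 4) {
  fusion_layer_init(d, ffn_ratio)
}

#' Apply one bridge fusion layer
#'
#' All four updates use layer-`i` inputs only (parallel semantics): the drug
#' and cell sequences each attend to the old bridge tokens, while the bridge
#' tokens attend to the concatenation `[H_c; H_d2; H_d1]` of the old
#' sequences.
#'
#' @param state a [fusion_state()].
#' @param params layer parameters from [init_fusion_layer_params()].
#' @param n_heads attention heads.
#' @param eps layer-norm epsilon.
#' @return the updated `bs_fusion_state`; attributes `"attention"` (per-BAU
#'   softmax weights) and `"n_scores"` (attention score-matrix entry count)
#'   are attached.
#' @export
fusion_layer <- function(state, params, n_heads = 8, eps = 1e-5) {
  stopifnot(inherits(state, "bs_fusion_state"))
  cfg <- list(h = n_heads, eps = eps, train = FALSE, dropout = 0)
  r <- fusion_layer_fwd(.state_to_batch(state), params, cfg)
  out <- .batch_to_state(r$state)
  attr(out, "attention") <- r$A
  attr(out, "n_scores") <- r$n_scores
  out
}

#' Run the full stack of fusion layers
#'
#' @param state initial [fusion_state()].
#' @param layer_params list of per-layer parameter sets (distinct weights per
#'   layer).
#' @inheritParams fusion_layer
#' @return final state; attribute `"n_scores"` holds the total attention
#'   score entries across layers.
#' @export
run_fusion <- function(state, layer_params, n_heads = 8, eps = 1e-5) {
  stopifnot(length(layer_params) >= 1L)
  total <- 0
  for (p in layer_params) {
    state <- fusion_layer(state, p, n_heads = n_heads, eps = eps)
    total <- total + attr(state, "n_scores")
  }
  attr(state, "n_scores") <- total
  state
}

#' Plain transformer fusion (ablation baseline)
#'
#' Runs a standard pre-norm self-attention encoder over the concatenated
#' sequence `[H_d1; H_d2; H_c]` and re-splits the output by the original
#' segment lengths. No bridge tokens are used; the returned state's `B`
#' slot is an empty matrix.
#'
#' @param H_d1,H_d2,H_c projected sequences (`rows x D`).
#' @param params list of per-layer parameter sets from [init_bau_params()]
#'   (the same parameter shape is reused; keys/values come from the sequence
#'   itself).
#' @inheritParams fusion_layer
#' @return a `bs_fusion_state` with fused `H_d1`, `H_d2`, `H_c` and empty `B`.
#' @export
plain_transformer_fusion <- function(H_d1, H_d2, H_c, params, n_heads = 8,
                                     eps = 1e-5) {
  d <- ncol(H_d1)
  n1 <- nrow(H_d1); n2 <- nrow(H_d2); nc <- nrow(H_c)
  x <- rbind(H_d1, H_d2, H_c)
  cfg <- list(h = n_heads, eps = eps, train = FALSE, dropout = 0)
  total <- 0
  atts <- list()
  for (i in seq_along(params)) {
    r <- plain_layer_fwd(x, n1 + n2 + nc, 1L, params[[i]], cfg)
    x <- r$out
    total <- total + r$n_scores
    atts[[i]] <- r$A
  }
  out <- fusion_state(x[seq_len(n1), , drop = FALSE],
                      x[n1 + seq_len(n2), , drop = FALSE],
                      x[n1 + n2 + seq_len(nc), , drop = FALSE],
                      matrix(numeric(0), 0L, d),
                      layer_index = length(params))
  attr(out, "attention") <- atts
  attr(out, "n_scores") <- total
  out
}
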