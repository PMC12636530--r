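# Dual-path synergy prediction head.
#
# The fused sequences are mean-pooled into a 3D-wide entity vector
# (drug1 | drug2 | cell) and a D-wide bridge vector. Each path is refined by
# a stack of Global Representation Refiner (GRR) blocks:
#   x1  = x + Mix(LN(x))                         (channel mixing, residual)
#   out = x1 + DropPath(gamma * W2 SwiGLU(LN(x1)))  (LayerScale + DropPath)
# The entity path starts with a 3D -> D projection so the two refined paths
# can be summed before the final linear prediction map.

.silu <- function(x) x / (1 + exp(-x))
.silu_grad <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

grr_init <- function(d, ratio = 4, layerscale_init = 1e-4) {
  d_in <- round(ratio * d)
  list(lna = nn_ln_init(d),
       mix = nn_linear_init(d, d),
       lnb = nn_ln_init(d),
       Wg = nn_linear_init(d, d_in), Wv = nn_linear_init(d, d_in),
       W2 = nn_linear_init(d_in, d),
       gamma = rep(layerscale_init, d))
}

# cfg: list(train, droppath, eps)
grr_fwd <- function(x, p, cfg) {
  u1 <- nn_ln_fwd(x, p$lna, eps = cfg$eps)
  m <- nn_linear_fwd(u1$out, p$mix)
  x1 <- x + m$out
  u2 <- nn_ln_fwd(x1, p$lnb, eps = cfg$eps)
  a <- nn_linear_fwd(u2$out, p$Wg)
  v <- nn_linear_fwd(u2$out, p$Wv)
  sa <- .silu(a$out)
  hsw <- sa * v$out
  f <- nn_linear_fwd(hsw, p$W2)
  scaled <- .mulrow(f$out, p$gamma)
  keep <- NULL
  if (isTRUE(cfg$train) && cfg$droppath > 0) {
    keep <- (stats::runif(nrow(x)) >= cfg$droppath) / (1 - cfg$droppath)
    scaled <- scaled * keep
  }
  list(out = x1 + scaled,
       cache = list(u1 = u1$cache, m = m$cache, u2 = u2$cache, a = a$cache,
                    v = v$cache, aout = a$out, vout = v$out, sa = sa,
                    f = f$cache, fout = f$out, keep = keep))
}

grr_bwd <- function(dout, p, cache, cfg) {
  dscaled <- dout
  if (!is.null(cache$keep)) dscaled <- dscaled * cache$keep
  df <- .mulrow(dscaled, p$gamma)
  dgamma <- colSums(dscaled * cache$fout)
  fb <- nn_linear_bwd(df, p$W2, cache$f)
  dhsw <- fb$dx
  dsa <- dhsw * cache$vout
  dv <- dhsw * cache$sa
  da <- dsa * .silu_grad(cache$aout)
  ab <- nn_linear_bwd(da, p$Wg, cache$a)
  vb <- nn_linear_bwd(dv, p$Wv, cache$v)
  lnbb <- nn_ln_bwd(ab$dx + vb$dx, p$lnb, cache$u2)
  dx1 <- dout + lnbb$dx
  mb <- nn_linear_bwd(dx1, p$mix, cache$m)
  lnab <- nn_ln_bwd(mb$dx, p$lna, cache$u1)
  list(dx = dx1 + lnab$dx,
       grads = list(lna = lnab$grads, mix = mb$grads, lnb = lnbb$grads,
                    Wg = ab$grads, Wv = vb$grads, W2 = fb$grads,
                    gamma = dgamma))
}

head_init <- function(d, n_blocks = 2, grr_ratio = 4, layerscale_init = 1e-4) {
  list(ent_in = nn_linear_init(3 * d, d),
       ent_blocks = lapply(seq_len(n_blocks), function(i)
         grr_init(d, grr_ratio, layerscale_init)),
       br_blocks = lapply(seq_len(n_blocks), function(i)
         grr_init(d, grr_ratio, layerscale_init)),
       out = nn_linear_init(d, 1))
}

grr_stack_fwd <- function(x, blocks, cfg) {
  caches <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    r <- grr_fwd(x, blocks[[i]], cfg)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, cache = caches)
}

grr_stack_bwd <- function(dy, blocks, caches, cfg) {
  grads <- vector("list", length(blocks))
  for (i in rev(seq_along(blocks))) {
    r <- grr_bwd(dy, blocks[[i]], caches[[i]], cfg)
    dy <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dy, grads = grads)
}

# state: batched fusion state (list(H, n, b)); returns per-sample predictions
head_fwd <- function(state, p, cfg) {
  H <- state$H; n <- state$n; b <- state$b
  m1 <- seq_mean_pool_fwd(H$d1, n[["d1"]], b)
  m2 <- seq_mean_pool_fwd(H$d2, n[["d2"]], b)
  mc <- seq_mean_pool_fwd(H$c, n[["c"]], b)
  ge <- cbind(m1$out, m2$out, mc$out)
  ei <- nn_linear_fwd(ge, p$ent_in)
  es <- grr_stack_fwd(ei$out, p$ent_blocks, cfg)
  has_bridge <- n[["b"]] > 0L
  if (has_bridge) {
    mb <- seq_mean_pool_fwd(H$b, n[["b"]], b)
    bs <- grr_stack_fwd(mb$out, p$br_blocks, cfg)
    s <- es$out + bs$out
  } else {
    mb <- NULL; bs <- NULL
    s <- es$out
  }
  yh <- nn_linear_fwd(s, p$out)
  list(out = as.vector(yh$out),
       cache = list(m1 = m1$cache, m2 = m2$cache, mc = mc$cache,
                    mb = if (has_bridge) mb$cache, ei = ei$cache,
                    es = es$cache, bs = if (has_bridge) bs$cache,
                    yh = yh$cache, has_bridge = has_bridge, d = ncol(ei$out)))
}

head_bwd <- function(dy, p, cache, cfg) {
  dym <- matrix(dy, ncol = 1)
  yb <- nn_linear_bwd(dym, p$out, cache$yh)
  ds <- yb$dx
  eb <- grr_stack_bwd(ds, p$ent_blocks, cache$es, cfg)
  eib <- nn_linear_bwd(eb$dx, p$ent_in, cache$ei)
  d <- cache$d
  dH <- list(d1 = seq_mean_pool_bwd(eib$dx[, 1:d, drop = FALSE], cache$m1),
             d2 = seq_mean_pool_bwd(eib$dx[, d + 1:d, drop = FALSE], cache$m2),
             c = seq_mean_pool_bwd(eib$dx[, 2 * d + 1:d, drop = FALSE], cache$mc))
  if (cache$has_bridge) {
    bb <- grr_stack_bwd(ds, p$br_blocks, cache$bs, cfg)
    dH$b <- seq_mean_pool_bwd(bb$dx, cache$mb)
    br_grads <- bb$grads
  } else {
    br_grads <- .zero_like(p$br_blocks)
  }
  # grads must mirror the parameter order of head_init exactly
  grads <- list(ent_in = eib$grads, ent_blocks = eb$grads,
                br_blocks = br_grads, out = yb$grads)
  list(dH = dH, grads = grads)
}

.zero_like <- function(x) {
  if (is.list(x)) return(lapply(x, .zero_like))
  x * 0
}

# ---- exported surfaces ------------------------------------------------------

#' Pool a fused state into head-level summary vectors
#'
#' Mean-pools each fused sequence over its tokens. The three entity vectors
#' are concatenated in (drug1, drug2, cell) order into `g_entity` (length
#' `3D`); the bridge tokens pool into `g_bridge` (length `D`, `NULL` when
#' the state carries no bridge tokens).
#'
#' @param state a [fusion_state()].
#' @return list with elements `g_entity` and `g_bridge`.
#' @export
pool_entities <- function(state) {
  stopifnot(inherits(state, "bs_fusion_state"))
  g_entity <- c(colMeans(state$H_d1), colMeans(state$H_d2), colMeans(state$H_c))
  g_bridge <- if (nrow(state$B) > 0L) colMeans(state$B) else NULL
  structure(list(g_entity = g_entity, g_bridge = g_bridge),
            class = "bs_head_state")
}

#' Apply one Global Representation Refiner block
#'
#' Channel mixing with a residual connection, followed by a SwiGLU
#' feed-forward sublayer with LayerScale; DropPath acts only during
#' training, so this evaluation-mode surface is deterministic.
#'
#' @param x numeric vector (or 1-row matrix) of the block width.
#' @param params block parameters from [init_grr_params()].
#' @param eps layer-norm epsilon.
#' @return numeric vector, same length as `x`.
#' @export
grr_block <- function(x, params, eps = 1e-5) {
  xm <- matrix(x, nrow = 1)
  cfg <- list(train = FALSE, droppath = 0, eps = eps)
  as.vector(grr_fwd(xm, params, cfg)$out)
}

#' Initialise GRR block parameters
#'
#' @param d block width.
#' @param ratio SwiGLU inner width as a multiple of `d`.
#' @param layerscale_init initial LayerScale value.
#' @export
init_grr_params <- function(d, ratio = 4, layerscale_init = 1e-4) {
  grr_init(d, ratio, layerscale_init)
}

#' Initialise prediction head parameters
#'
#' @param d fusion width `D`.
#' @param n_blocks GRR blocks per path.
#' @param grr_ratio SwiGLU inner width multiple.
#' @param layerscale_init initial LayerScale value.
#' @export
init_head_params <- function(d, n_blocks = 2, grr_ratio = 4,
                             layerscale_init = 1e-4) {
  head_init(d, n_blocks, grr_ratio, layerscale_init)
}

#' Predict the synergy score from pooled head vectors
#'
#' The entity vector is projected `3D -> D`, each path is refined by its GRR
#' stack, the refined vectors are summed, and a linear map emits the scalar
#' prediction. Deterministic in evaluation mode.
#'
#' @param head a `bs_head_state` from [pool_entities()].
#' @param params head parameters from [init_head_params()].
#' @param eps layer-norm epsilon.
#' @return scalar predicted synergy score.
#' @export
predict_head <- function(head, params, eps = 1e-5) {
  stopifnot(inherits(head, "bs_head_state"))
  if (length(head$g_entity) != nrow(params$ent_in$W)) {
    stop("entity vector length ", length(head$g_entity),
         " does not match head input width ", nrow(params$ent_in$W))
  }
  cfg <- list(train = FALSE, droppath = 0, eps = eps)
  e <- nn_linear_fwd(matrix(head$g_entity, nrow = 1), params$ent_in)$out
  e <- grr_stack_fwd(e, params$ent_blocks, cfg)$out
  s <- e
  if (!is.null(head$g_bridge)) {
    b <- grr_stack_fwd(matrix(head$g_bridge, nrow = 1), params$br_blocks, cfg)$out
    s <- s + b
  }
  as.vector(nn_linear_fwd(s, params$out)$out)
}
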