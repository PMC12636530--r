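# Low-level differentiable building blocks.
#
# Every forward function returns list(out, cache); the matching backward
# takes the upstream gradient plus the cache and returns gradients for its
# inputs and parameters. Sequence batches use the sample-major block layout
# described in src/ops.cpp: a (b * n) x D matrix holds b sequences of n
# tokens each. These are internal; the exported module surfaces wrap them.

# broadcast a length-m vector across the rows of an n x m matrix
.addrow <- function(x, v) cpp_addrow(x, v)
.mulrow <- function(x, v) cpp_mulrow(x, v)

nn_linear_init <- function(nin, nout, scale = 1) {
  list(W = matrix(stats::rnorm(nin * nout, sd = scale * sqrt(2 / (nin + nout))),
                  nin, nout),
       b = numeric(nout))
}

nn_ln_init <- function(d) list(g = rep(1, d), b = numeric(d))

nn_linear_fwd <- function(x, p) {
  list(out = .addrow(x %*% p$W, p$b), cache = x)
}

nn_linear_bwd <- function(dy, p, cache) {
  list(dx = tcrossprod(dy, p$W),
       grads = list(W = crossprod(cache, dy), b = colSums(dy)))
}

# row-wise layer normalisation with learned affine (g, b)
nn_ln_fwd <- function(x, p, eps = 1e-5) {
  r <- cpp_ln_forward(x, p$g, p$b, eps)
  list(out = r$out, cache = list(xh = r$xh, inv = r$inv))
}

nn_ln_bwd <- function(dy, p, cache) {
  r <- cpp_ln_backward(dy, p$g, cache$xh, cache$inv)
  list(dx = r$dx, grads = list(g = as.vector(r$dg), b = as.vector(r$db)))
}

nn_gelu_fwd <- function(x) list(out = cpp_gelu(x), cache = x)
nn_gelu_bwd <- function(dy, cache) cpp_gelu_bwd(dy, cache)

# inverted dropout; mask entries are 0 or 1/(1-p)
nn_dropmask <- function(n, m, p) {
  matrix((stats::runif(n * m) >= p) / (1 - p), n, m)
}

# softmax over the rows of a matrix (used by attention pooling)
nn_softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

# ---- sequence pooling over token blocks -------------------------------------

# mean over the n tokens of each sample: (b*n) x D -> b x D
seq_mean_pool_fwd <- function(x, n, b) {
  grp <- rep(seq_len(b), each = n)
  list(out = rowsum(x, grp, reorder = FALSE) / n, cache = list(n = n, b = b))
}

seq_mean_pool_bwd <- function(dy, cache) {
  dy[rep(seq_len(cache$b), each = cache$n), , drop = FALSE] / cache$n
}

# elementwise max over tokens; cache records the attaining token (first hit)
seq_max_pool_fwd <- function(x, n, b) {
  d <- ncol(x)
  out <- x[seq(1L, by = n, length.out = b), , drop = FALSE]
  arg <- matrix(1L, b, d)
  if (n > 1L) {
    for (i in 2L:n) {
      xi <- x[seq(i, by = n, length.out = b), , drop = FALSE]
      upd <- xi > out
      out[upd] <- xi[upd]
      arg[upd] <- i
    }
  }
  list(out = out, cache = list(arg = arg, n = n, b = b, d = d))
}

seq_max_pool_bwd <- function(dy, cache) {
  dx <- matrix(0, cache$b * cache$n, cache$d)
  rows <- rep(seq(0L, by = cache$n, length.out = cache$b), cache$d) + as.vector(cache$arg)
  cols <- rep(seq_len(cache$d), each = cache$b)
  dx[cbind(rows, cols)] <- as.vector(dy)
  dx
}

# attention pooling: softmax over a learned scalar score per token
# p = list(w = D-vector, a = scalar bias)
seq_attn_pool_fwd <- function(x, n, b, p) {
  s <- matrix(as.vector(x %*% p$w) + p$a, b, n, byrow = TRUE)
  a <- nn_softmax_rows(s)                      # b x n
  av <- as.vector(t(a))                        # token-major, matches row blocks
  grp <- rep(seq_len(b), each = n)
  out <- rowsum(x * av, grp, reorder = FALSE)
  list(out = out, cache = list(x = x, a = a, av = av, n = n, b = b))
}

seq_attn_pool_bwd <- function(dy, p, cache) {
  n <- cache$n; b <- cache$b
  dyx <- dy[rep(seq_len(b), each = n), , drop = FALSE]  # broadcast to tokens
  dx <- dyx * cache$av
  da_tok <- rowSums(dyx * cache$x)             # d out / d a per token
  da <- matrix(da_tok, b, n, byrow = TRUE)
  ds <- cache$a * (da - rowSums(da * cache$a)) # softmax backward per sample
  ds_tok <- as.vector(t(ds))
  dx <- dx + ds_tok * matrix(p$w, b * n, length(p$w), byrow = TRUE)
  dw <- as.vector(crossprod(cache$x, ds_tok))
  list(dx = dx, grads = list(w = dw, a = sum(ds_tok)))
}

# per-sample concatenation of two sequence batches: rows [x1-block; x2-block]
seq_cat_idx <- function(n1, n2, b) {
  # row indices into rbind(x1, x2) producing the interleaved layout
  unlist(lapply(seq_len(b) - 1L, function(s) {
    c(s * n1 + seq_len(n1), b * n1 + s * n2 + seq_len(n2))
  }), use.names = FALSE)
}

seq_cat2 <- function(x1, n1, x2, n2, b) {
  rbind(x1, x2)[seq_cat_idx(n1, n2, b), , drop = FALSE]
}

seq_uncat2 <- function(x, n1, n2, b) {
  idx <- seq_cat_idx(n1, n2, b)
  inv <- integer(length(idx)); inv[idx] <- seq_along(idx)
  both <- x[inv, , drop = FALSE]
  list(x1 = both[seq_len(b * n1), , drop = FALSE],
       x2 = both[b * n1 + seq_len(b * n2), , drop = FALSE])
}
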