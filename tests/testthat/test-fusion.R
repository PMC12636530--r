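zeroed_bau <- function(d, ffn_ratio = 2) {
  # output projection and second FFN layer zeroed: both residual branches
  # vanish and the BAU is the identity
  p <- init_bau_params(d, ffn_ratio)
  p$Wo$W[] <- 0; p$Wo$b[] <- 0
  p$W2$W[] <- 0; p$W2$b[] <- 0
  p
}

test_that("bridge token generation condenses the nine pooled vectors", {
  set.seed(30)
  d <- 4
  p <- init_bridge_params(d, n_bridge = 2)

  # all-equal token rows: max, mean and attention pooling all return that row
  row <- rnorm(d)
  H <- matrix(row, 3, d, byrow = TRUE)
  B <- generate_bridge_tokens(H, H, H, p)
  z <- matrix(rep(row, 9), 1)
  expected <- matrix(t(z %*% p$map$W + rep(p$map$b, each = 1)), ncol = d,
                     byrow = TRUE)
  expect_equal(B, expected, tolerance = 1e-12)

  # hand-staged oracle with distinct pooled vectors
  H1 <- matrix(rnorm(8), 2, d); H2 <- matrix(rnorm(12), 3, d)
  Hc <- matrix(rnorm(16), 4, d)
  pool3 <- function(H, w, a) {
    s <- as.vector(H %*% w) + a
    aw <- exp(s - max(s)); aw <- aw / sum(aw)
    c(apply(H, 2, max), colMeans(H), as.vector(t(H) %*% aw))
  }
  z <- c(pool3(H1, p$w_d$w, p$w_d$a), pool3(H2, p$w_d$w, p$w_d$a),
         pool3(Hc, p$w_c$w, p$w_c$a))
  expected <- matrix(as.vector(z %*% p$map$W) + p$map$b, ncol = d,
                     byrow = TRUE)
  expect_equal(generate_bridge_tokens(H1, H2, Hc, p), expected,
               tolerance = 1e-10)

  # attention-pool weights are a softmax: they sum to one for any input
  ap <- bridgesyn:::seq_attn_pool_fwd(Hc, 4, 1, p$w_c)
  expect_equal(rowSums(ap$cache$a), 1)

  # learned-constant mode returns the token matrix itself
  pl <- init_bridge_params(d, 3, mode = "learned")
  expect_equal(generate_bridge_tokens(H1, H2, Hc, pl, mode = "learned"),
               pl$B0)
})

test_that("the BAU reduces to the identity when its projections are zeroed", {
  set.seed(31)
  p <- zeroed_bau(6)
  Hm <- matrix(rnorm(18), 3, 6)
  Hn <- matrix(rnorm(12), 2, 6)
  expect_equal(bau(Hm, Hn, p, n_heads = 2), Hm, tolerance = 1e-14)
})

test_that("BAU attention rows are softmax-normalised per head", {
  set.seed(32)
  p <- init_bau_params(6, 2)
  Hm <- matrix(rnorm(18), 3, 6)
  Hn <- matrix(rnorm(12), 2, 6)
  out <- bau(Hm, Hn, p, n_heads = 3, return_attention = TRUE)
  A <- attr(out, "attention")
  expect_equal(dim(A), c(3 * 3, 2 + 3))  # heads x queries rows, N_n + N_m keys
  expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
})

test_that("single-head BAU matches a scalar hand computation", {
  # D = 2, one query token, one context token, hand-chosen parameters
  d <- 2
  p <- init_bau_params(d, ffn_ratio = 2)
  p$ln1$g <- c(1, 1); p$ln1$b <- c(0, 0)
  p$Wq$W <- diag(2); p$Wq$b <- c(0, 0)
  p$Wkv$W <- cbind(diag(2), diag(2)); p$Wkv$b <- rep(0, 4)
  p$Wo$W <- diag(2); p$Wo$b <- c(0, 0)
  p$W2$W[] <- 0; p$W2$b[] <- 0  # silence the FFN branch
  Hm <- matrix(c(1, 3), 1, 2)
  Hn <- matrix(c(2, -1), 1, 2)
  # layer-norm of a 1x2 row is (sign of difference) * x / sqrt(x^2 + eps)
  ln <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5)
  q <- ln(c(1, 3))
  keys <- rbind(ln(c(2, -1)), ln(c(1, 3)))
  s <- as.vector(keys %*% q) / sqrt(2)
  a <- exp(s - max(s)); a <- a / sum(a)
  expected <- Hm + matrix(as.vector(t(keys) %*% a), 1)  # V = K here
  expect_equal(bau(Hm, Hn, p, n_heads = 1), expected, tolerance = 1e-10)
})

test_that("fusion layers update all four sequences in parallel", {
  set.seed(33)
  d <- 6
  lp <- init_fusion_layer_params(d, ffn_ratio = 2)
  st <- fusion_state(matrix(rnorm(12), 2, d), matrix(rnorm(12), 2, d),
                     matrix(rnorm(18), 3, d), matrix(rnorm(12), 2, d))
  out <- fusion_layer(st, lp, n_heads = 2)
  expect_s3_class(out, "bs_fusion_state")
  expect_equal(dim(out$H_d1), dim(st$H_d1))
  expect_equal(dim(out$B), dim(st$B))
  expect_equal(out$layer_index, 1L)

  # parallel semantics: every update uses layer-i inputs only, so the new
  # bridge tokens equal a direct BAU call on the *old* sequences
  ctx <- rbind(st$H_c, st$H_d2, st$H_d1)
  expect_equal(out$B, unclass(bau(st$B, ctx, lp$b, n_heads = 2)),
               tolerance = 1e-12)
  expect_equal(out$H_d1, unclass(bau(st$H_d1, st$B, lp$d1, n_heads = 2)),
               tolerance = 1e-12)

  # mutating H_d1 leaves the bridge update unchanged (recomputation check)
  st2 <- st
  st2$H_d1 <- st$H_d1 + 10
  out2 <- fusion_layer(st2, lp, n_heads = 2)
  ctx2 <- rbind(st$H_c, st$H_d2, st2$H_d1)
  expect_equal(out2$B, unclass(bau(st$B, ctx2, lp$b, n_heads = 2)),
               tolerance = 1e-12)

  # identity-parameterised layer leaves the state unchanged
  ip <- list(d1 = zeroed_bau(d), d2 = zeroed_bau(d), c = zeroed_bau(d),
             b = zeroed_bau(d))
  idout <- fusion_layer(st, ip, n_heads = 2)
  expect_equal(idout$H_d1, st$H_d1, tolerance = 1e-14)
  expect_equal(idout$H_d2, st$H_d2, tolerance = 1e-14)
  expect_equal(idout$H_c, st$H_c, tolerance = 1e-14)
  expect_equal(idout$B, st$B, tolerance = 1e-14)
})

test_that("attention score counts follow the published complexity term", {
  d <- 8
  count_for <- function(nd, nc, nb) {
    lp <- init_fusion_layer_params(d, 2)
    st <- fusion_state(matrix(0.1, nd, d), matrix(0.1, nd, d),
                       matrix(0.1, nc, d), matrix(0.1, nb, d))
    attr(fusion_layer(st, lp, n_heads = 2), "n_scores")
  }
  formula <- function(nd, nc, nb) {
    nd * (nb + nd) * 2 + nc * (nb + nc) + nb * (nc + 2 * nd + nb)
  }
  for (dims in list(c(2, 3, 2), c(4, 3, 2), c(2, 5, 3))) {
    expect_equal(count_for(dims[1], dims[2], dims[3]),
                 formula(dims[1], dims[2], dims[3]))
  }
  # after removing each sequence's quadratic self terms, the remaining
  # bridge-mediated cost is the dominant complexity term: linear in N_b at
  # fixed sequence lengths and linear in N_d + N_c at fixed N_b
  cross_part <- function(nd, nc, nb) {
    count_for(nd, nc, nb) - (2 * nd * nd + nc * nc + nb * nb)
  }
  cross_nb <- vapply(1:4, function(nb) cross_part(3, 4, nb), numeric(1))
  expect_equal(diff(cross_nb, differences = 2), rep(0, 2))
  cross_seq <- vapply(1:3, function(s) cross_part(2 * s, 2 * s, 2),
                      numeric(1))
  expect_equal(diff(cross_seq, differences = 2), 0)
})

test_that("stacked fusion equals composing single layers", {
  set.seed(34)
  d <- 6
  lps <- lapply(1:3, function(i) init_fusion_layer_params(d, 2))
  st <- fusion_state(matrix(rnorm(12), 2, d), matrix(rnorm(12), 2, d),
                     matrix(rnorm(18), 3, d), matrix(rnorm(12), 2, d))
  run <- run_fusion(st, lps, n_heads = 2)
  manual <- st
  for (lp in lps) manual <- fusion_layer(manual, lp, n_heads = 2)
  expect_equal(run$H_d1, manual$H_d1, tolerance = 1e-12)
  expect_equal(run$B, manual$B, tolerance = 1e-12)
  expect_equal(run$layer_index, 3L)

  one <- run_fusion(st, lps[1], n_heads = 2)
  expect_equal(one$H_c, fusion_layer(st, lps[[1]], n_heads = 2)$H_c,
               tolerance = 1e-14)
})

test_that("plain transformer fusion self-attends over the concatenation", {
  set.seed(35)
  d <- 6
  H1 <- matrix(rnorm(12), 2, d); H2 <- matrix(rnorm(12), 2, d)
  Hc <- matrix(rnorm(18), 3, d)

  # identity configuration
  ip <- lapply(1:2, function(i) zeroed_bau(d))
  out <- plain_transformer_fusion(H1, H2, Hc, ip, n_heads = 2)
  expect_equal(out$H_d1, H1, tolerance = 1e-14)
  expect_equal(out$H_c, Hc, tolerance = 1e-14)
  expect_equal(nrow(out$B), 0L)

  # attention rows sum to 1
  p1 <- list(init_bau_params(d, 2))
  out2 <- plain_transformer_fusion(H1, H2, Hc, p1, n_heads = 2)
  A <- attr(out2, "attention")[[1]]
  expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)

  # one-layer single-head equivalence with the base-R oracle
  p <- init_bau_params(d, 2)
  x <- rbind(H1, H2, Hc)
  lnx <- t(apply(x, 1, oracle_ln, g = p$ln1$g, b = p$ln1$b))
  Q <- sweep(lnx %*% p$Wq$W, 2, p$Wq$b, "+")
  KV <- sweep(lnx %*% p$Wkv$W, 2, p$Wkv$b, "+")
  K <- KV[, 1:d]; V <- KV[, d + 1:d]
  H1p <- x + sweep(oracle_mhca(Q, K, V, 1) %*% p$Wo$W, 2, p$Wo$b, "+")
  u <- t(apply(H1p, 1, oracle_ln, g = p$ln2$g, b = p$ln2$b))
  f <- oracle_gelu(sweep(u %*% p$W1$W, 2, p$W1$b, "+"))
  expected <- H1p + sweep(f %*% p$W2$W, 2, p$W2$b, "+")
  got <- plain_transformer_fusion(H1, H2, Hc, list(p), n_heads = 1)
  expect_equal(rbind(got$H_d1, got$H_d2, got$H_c), expected,
               tolerance = 1e-8)
})

test_that("gradients of a scalar loss through the fusion stack stay finite", {
  set.seed(36)
  ns <- asNamespace("bridgesyn")
  model <- tiny_model(seed = 36)
  batch <- tiny_batch(seed = 36)
  fw <- ns$model_forward(model, batch, train = FALSE)
  bw <- ns$model_backward(model, fw$cache, rep(1, batch$b))
  leaves <- unlist(bw$grads, use.names = FALSE)
  expect_true(all(is.finite(leaves)))
  expect_gt(sd(leaves), 0)
})
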