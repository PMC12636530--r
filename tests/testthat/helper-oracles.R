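# Independent reference implementations used as oracles. These are written
# in plain base R, straight from the mathematical definitions, and share no
# code with the package internals they check.

oracle_gelu <- function(x) x * pnorm(x)

oracle_ln <- function(v, g, b, eps = 1e-5) {
  mu <- mean(v)
  s2 <- mean((v - mu)^2)
  (v - mu) / sqrt(s2 + eps) * g + b
}

# one [linear -> layer-norm -> GELU] stage applied to each row of x
oracle_mlp_stage <- function(x, W, bias, g, b, eps = 1e-5) {
  t(apply(x, 1, function(row) {
    z <- as.vector(row %*% W) + bias
    oracle_gelu(oracle_ln(z, g, b, eps))
  }))
}

oracle_softmax <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

# single-sample multi-head attention, looping over heads and queries
oracle_mhca <- function(Q, K, V, n_heads) {
  d <- ncol(Q)
  dh <- d / n_heads
  out <- matrix(0, nrow(Q), d)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1) * dh + seq_len(dh)
    for (i in seq_len(nrow(Q))) {
      s <- as.vector(K[, cols, drop = FALSE] %*% Q[i, cols]) / sqrt(dh)
      a <- oracle_softmax(s)
      out[i, cols] <- as.vector(t(V[, cols, drop = FALSE]) %*% a)
    }
  }
  out
}

# naive O(L^2) DPC-KNN reference
oracle_dpcknn <- function(G, k, n_clusters) {
  L <- nrow(G)
  d2 <- matrix(0, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) d2[i, j] <- sum((G[i, ] - G[j, ])^2)
  }
  rho <- numeric(L)
  for (i in seq_len(L)) {
    rho[i] <- exp(-mean(sort(d2[i, -i])[seq_len(k)]))
  }
  delta <- numeric(L)
  for (i in seq_len(L)) {
    denser <- which(rho > rho[i])
    delta[i] <- if (length(denser) > 0) {
      sqrt(min(d2[i, denser]))
    } else {
      sqrt(max(d2[i, ]))
    }
  }
  score <- rho * delta
  centers <- order(-score, seq_len(L))[seq_len(n_clusters)]
  assignment <- integer(L)
  for (i in seq_len(L)) {
    assignment[i] <- which.min(d2[i, centers])
  }
  assignment[centers] <- seq_along(centers)
  list(rho = rho, delta = delta, centers = centers, assignment = assignment)
}

# agreement between two 2-cluster labelings, up to label swap
label_agreement <- function(a, b) {
  max(mean(a == b), mean(a == (3 - b)))
}
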