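# a transparent surrogate: y = sum(w_a * colMeans(tokens_a)) +
#                               sum(w_b * colMeans(tokens_b))
toy_linear_model <- function(w_a, w_b) {
  structure(list(w_a = w_a, w_b = w_b), class = "bs_toy_linear")
}

predict.bs_toy_linear <- function(object, prep, triplets, idx = NULL,
                                  swap_drugs = FALSE, ...) {
  if (is.null(idx)) idx <- seq_len(nrow(triplets))
  da <- triplets$drug_a[idx]; db <- triplets$drug_b[idx]
  if (swap_drugs) { tmp <- da; da <- db; db <- tmp }
  va <- vapply(prep$drug[da], function(m) sum(object$w_a * colMeans(m)),
               numeric(1))
  vb <- vapply(prep$drug[db], function(m) sum(object$w_b * colMeans(m)),
               numeric(1))
  unname(va + vb)
}
registerS3method("predict", "bs_toy_linear", predict.bs_toy_linear)

toy_prep <- function(seed = 70, n_drugs = 6, nd = 3, d = 4) {
  set.seed(seed)
  drugs <- lapply(seq_len(n_drugs), function(i) matrix(rnorm(nd * d), nd, d))
  names(drugs) <- sprintf("D%d", seq_len(n_drugs))
  cells <- list(CL1 = matrix(rnorm(8), 2, 4))
  list(drug = drugs, cell = cells)
}

toy_triplets <- function(prep, n = 8, seed = 71) {
  set.seed(seed)
  ids <- names(prep$drug)
  pair <- t(replicate(n, sample(ids, 2)))
  data.frame(drug_a = pair[, 1], drug_b = pair[, 2], cell_line = "CL1",
             stringsAsFactors = FALSE)
}

test_that("perturbation contributions have the linear closed form", {
  prep <- toy_prep()
  tr <- toy_triplets(prep)
  w_a <- rnorm(4); w_b <- rnorm(4)
  model <- toy_linear_model(w_a, w_b)
  res <- perturbation_contribution(model, prep, tr, baseline = "zero")
  # for the additive surrogate with a zero baseline,
  # delta_a = w_a . pool(d_a) exactly
  expect_equal(res$delta_a,
               vapply(prep$drug[tr$drug_a],
                      function(m) sum(w_a * colMeans(m)), numeric(1)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(res$delta_b,
               vapply(prep$drug[tr$drug_b],
                      function(m) sum(w_b * colMeans(m)), numeric(1)),
               ignore_attr = TRUE, tolerance = 1e-12)

  # a drug already equal to the baseline contributes exactly zero
  prep0 <- prep
  prep0$drug$D1[] <- 0
  tr0 <- data.frame(drug_a = "D1", drug_b = "D2", cell_line = "CL1",
                    stringsAsFactors = FALSE)
  res0 <- perturbation_contribution(model, prep0, tr0, baseline = "zero")
  expect_equal(res0$delta_a, 0)

  expect_error(perturbation_contribution(model, prep, tr, baseline = "odd"))
})

test_that("perturbation on the full model equals the two-forward-pass oracle", {
  set.seed(72)
  model <- tiny_model(seed = 72)
  gen <- gen_dataset(synth_config(n_drugs = 8, n_cells = 3, n_genes = 20,
                                  n_gene_modules = 2, n_triplets = 40,
                                  d_in = 3, d_p = 4, seed = 72))
  prep <- prepare_features(gen$dataset, feature_config(),
                           ccf_config(k = 3, n_clusters = 3))
  tr <- gen$dataset$triplets
  # oracle: two explicit forward passes per triplet; calling the attribution
  # one triplet at a time keeps the batch shapes identical, so agreement is
  # bitwise
  means <- rowMeans(vapply(prep$drug, colMeans, numeric(3)))
  nd <- nrow(prep$drug[[1]])
  base <- matrix(means, nd, 3, byrow = TRUE)
  for (i in sample(nrow(tr), 5)) {
    res <- perturbation_contribution(model, prep, tr, idx = i,
                                     baseline = "mean")
    xa <- prep$drug[[tr$drug_a[i]]]
    xb <- prep$drug[[tr$drug_b[i]]]
    xc <- prep$cell[[tr$cell_line[i]]]
    s_full <- bridgesyn:::.predict_one(model, xa, xb, xc)
    expect_identical(res$delta_a,
                     s_full - bridgesyn:::.predict_one(model, base, xb, xc))
    expect_identical(res$delta_b,
                     s_full - bridgesyn:::.predict_one(model, xa, base, xc))
  }
})

test_that("integrated gradients are exact for linear maps and complete in the limit", {
  set.seed(73)
  w <- rnorm(6)
  grad_fn <- function(x) matrix(w, 2, 3)
  x <- matrix(rnorm(6), 2, 3)
  b <- matrix(0, 2, 3)
  for (steps in c(1, 7)) {
    ig <- integrated_gradients_path(grad_fn, x, b, steps = steps)
    expect_equal(ig, matrix(w, 2, 3) * x, tolerance = 1e-12)
  }

  # S(x) = x^3 from baseline 0: attribution converges to x^3 as steps grow
  g3 <- function(x) 3 * x^2
  x1 <- matrix(2, 1, 1)
  err <- vapply(c(4, 8, 16), function(s) {
    abs(integrated_gradients_path(g3, x1, matrix(0, 1, 1), s)[1] - 8)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  # midpoint rule: quartic error decay or better
  expect_lt(err[3], err[1] / 4)
})

test_that("model-level integrated gradients satisfy completeness", {
  set.seed(74)
  model <- tiny_model(seed = 3, d_in_drug = 8, d_in_cell = 8, d_model = 16)
  gen <- gen_dataset(synth_config(n_drugs = 6, n_cells = 3, n_genes = 20,
                                  n_gene_modules = 2, n_triplets = 20,
                                  d_in = 8, d_p = 8, seed = 103))
  prep <- prepare_features(gen$dataset, feature_config(),
                           ccf_config(k = 3, n_clusters = 3))
  tr <- gen$dataset$triplets[1, , drop = FALSE]
  # the mean baseline keeps the interpolation path away from the origin,
  # where layer normalisation's scale invariance concentrates the whole
  # path integral into an unresolvable boundary layer
  ig32 <- integrated_gradients(model, prep, tr, baseline = "mean",
                               steps = 32)
  ig64 <- integrated_gradients(model, prep, tr, baseline = "mean",
                               steps = 64)
  # the summed attributions approach S(x) - S(baseline)
  expect_lt(abs(ig64$completeness_residual),
            abs(ig32$completeness_residual))
  expect_equal(ig64$ig_a + ig64$ig_b,
               ig64$prediction - ig64$baseline_prediction,
               tolerance = 1e-2)
  expect_equal(ig64$ig_a, sum(ig64$tokens_a), tolerance = 1e-12)
})

test_that("order sensitivity detects symmetry and flags degenerate inputs", {
  prep <- toy_prep()
  tr <- toy_triplets(prep, n = 10)
  w <- rnorm(4)
  sym <- toy_linear_model(w, w)  # identical branch weights => symmetric
  rep_sym <- order_sensitivity(sym, prep, tr)
  expect_identical(rep_sym$predictions$y_ab, rep_sym$predictions$y_ba)
  expect_equal(rep_sym$pcc_between_orders, 1)

  const <- toy_linear_model(rep(0, 4), rep(0, 4))
  expect_true(is.na(order_sensitivity(const, prep, tr)$pcc_between_orders))

  asym <- toy_linear_model(rnorm(4), rnorm(4))
  rep_a <- order_sensitivity(asym, prep, tr)
  expect_equal(rep_a$pcc_between_orders,
               cor(rep_a$predictions$y_ab, rep_a$predictions$y_ba))
})

test_that("contribution scatter tables export and round-trip", {
  res <- data.frame(delta_a = c(1.5, -0.25), delta_b = c(1.5, 0.75))
  f <- withr::local_tempfile(fileext = ".csv")
  contribution_scatter_export(res, f)
  back <- utils::read.csv(f)
  expect_equal(back$abs_diff, c(0, 1))
  expect_equal(back$delta_a, res$delta_a, tolerance = 0)

  contribution_scatter_export(res[0, ], f)
  empty <- utils::read.csv(f)
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("delta_a", "delta_b", "abs_diff"))
})
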