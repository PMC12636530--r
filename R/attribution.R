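# Interpretability procedures: null-baseline perturbation contributions,
# integrated-gradients token attributions aggregated per drug, and the
# drug-pair order-sensitivity analysis.

.baseline_tokens <- function(prep, shape_like, kind) {
  n <- nrow(shape_like); d <- ncol(shape_like)
  if (kind == "zero") return(matrix(0, n, d))
  if (kind == "mean") {
    means <- vapply(prep$drug, colMeans, numeric(d))
    return(matrix(rowMeans(means), n, d, byrow = TRUE))
  }
  stop("unknown baseline kind: ", kind)
}

#' Per-drug perturbation contributions
#'
#' For each triplet, the contribution of drug A is the change in the
#' predicted synergy when drug A is replaced by a null baseline embedding:
#' `delta_a = S(d_a, d_b, c) - S(baseline, d_b, c)`, and symmetrically for
#' drug B. The baseline is either the zero token matrix or the dataset-mean
#' token vector broadcast to the drug's token count.
#'
#' @param model a trained model (anything with a
#'   `predict(model, prep, triplets, idx)` method).
#' @param prep prepared features from [prepare_features()].
#' @param triplets triplet data frame.
#' @param idx row indices to attribute (default all).
#' @param baseline `"zero"` or `"mean"`.
#' @return data frame with the triplet key columns, `delta_a`, `delta_b`
#'   and `baseline_kind`.
#' @export
perturbation_contribution <- function(model, prep, triplets, idx = NULL,
                                      baseline = c("zero", "mean")) {
  baseline <- match.arg(baseline)
  if (is.null(idx)) idx <- seq_len(nrow(triplets))
  # register one baseline pseudo-drug per distinct token count
  shapes <- unique(vapply(prep$drug[unique(c(triplets$drug_a[idx],
                                             triplets$drug_b[idx]))],
                          nrow, integer(1)))
  prep2 <- prep
  base_id <- function(n) paste0("..baseline", n)
  for (n in shapes) {
    tmpl <- prep$drug[[which(vapply(prep$drug, nrow, integer(1)) == n)[1]]]
    prep2$drug[[base_id(n)]] <- .baseline_tokens(prep, tmpl, baseline)
  }
  nd <- vapply(prep$drug, nrow, integer(1))
  s_full <- predict(model, prep2, triplets, idx = idx)
  ta <- triplets[idx, , drop = FALSE]
  ta$drug_a <- base_id(nd[ta$drug_a])
  s_no_a <- predict(model, prep2, ta, idx = seq_len(nrow(ta)))
  tb <- triplets[idx, , drop = FALSE]
  tb$drug_b <- base_id(nd[tb$drug_b])
  s_no_b <- predict(model, prep2, tb, idx = seq_len(nrow(tb)))
  data.frame(drug_a = triplets$drug_a[idx], drug_b = triplets$drug_b[idx],
             cell_line = triplets$cell_line[idx],
             delta_a = s_full - s_no_a, delta_b = s_full - s_no_b,
             baseline_kind = baseline, stringsAsFactors = FALSE)
}

#' Integrated gradients along a straight path (generic)
#'
#' Midpoint Riemann approximation of the path integral of gradients from a
#' baseline to the input. For a linear function this is exact at any number
#' of steps; for smooth functions the completeness residual shrinks as the
#' step count grows.
#'
#' @param grad_fn function taking an input (list of numeric matrices, or a
#'   single matrix) and returning the gradient in the same shape.
#' @param x input.
#' @param baseline baseline input, same shape as `x`.
#' @param steps number of Riemann steps.
#' @return attributions in the shape of `x`: `(x - baseline) * mean of
#'   gradients along the path`.
#' @export
integrated_gradients_path <- function(grad_fn, x, baseline, steps = 64L) {
  stopifnot(steps >= 1L)
  single <- !is.list(x)
  if (single) { x <- list(x); baseline <- list(baseline) }
  acc <- lapply(x, function(m) m * 0)
  for (t in seq_len(steps)) {
    alpha <- (t - 0.5) / steps
    xt <- mapply(function(a, b) b + alpha * (a - b), x, baseline,
                 SIMPLIFY = FALSE)
    g <- grad_fn(if (single) xt[[1]] else xt)
    if (single) g <- list(g)
    acc <- mapply(`+`, acc, g, SIMPLIFY = FALSE)
  }
  out <- mapply(function(a, b, s) (a - b) * s / steps, x, baseline, acc,
                SIMPLIFY = FALSE)
  if (single) out[[1]] else out
}

#' Integrated-gradients attribution for one triplet
#'
#' Interpolates both drug token matrices jointly from the baseline to the
#' observed input (the cell line is held fixed), evaluating all path points
#' in one batched forward/backward pass. Token-level attributions are
#' summed over tokens and channels to give per-drug aggregates; the
#' completeness residual `sum(attributions) - (S(x) - S(baseline))` is
#' reported.
#'
#' @param model a trained [bridgesyn()] model.
#' @param prep prepared features.
#' @param triplet one-row triplet data frame.
#' @param baseline `"zero"` or `"mean"`.
#' @param steps midpoint Riemann steps.
#' @return list with token attribution matrices `tokens_a` / `tokens_b`,
#'   per-drug aggregates `ig_a` / `ig_b`, `prediction`,
#'   `baseline_prediction`, `completeness_residual` and `steps`.
#' @export
integrated_gradients <- function(model, prep, triplet,
                                 baseline = c("zero", "mean"), steps = 64L) {
  baseline <- match.arg(baseline)
  stopifnot(nrow(triplet) == 1L, steps >= 1L)
  xa <- prep$drug[[triplet$drug_a]]
  xb <- prep$drug[[triplet$drug_b]]
  xc <- prep$cell[[triplet$cell_line]]
  ba <- .baseline_tokens(prep, xa, baseline)
  bb <- .baseline_tokens(prep, xb, baseline)
  alphas <- (seq_len(steps) - 0.5) / steps
  stack_path <- function(x, b) {
    do.call(rbind, lapply(alphas, function(a) b + a * (x - b)))
  }
  batch <- list(Xd1 = stack_path(xa, ba), nd1 = nrow(xa),
                Xd2 = stack_path(xb, bb), nd2 = nrow(xb),
                Xc = xc[rep(seq_len(nrow(xc)), steps), , drop = FALSE],
                nc = nrow(xc), b = as.integer(steps))
  fw <- model_forward(model, batch, train = FALSE)
  bw <- model_backward(model, fw$cache, rep(1, steps), input_grads = TRUE)
  mean_grad <- function(dx, n) {
    rowsum(dx, rep(seq_len(n), times = steps), reorder = FALSE) / steps
  }
  attr_a <- (xa - ba) * mean_grad(bw$dXd1, nrow(xa))
  attr_b <- (xb - bb) * mean_grad(bw$dXd2, nrow(xb))
  pred <- .predict_one(model, xa, xb, xc)
  pred0 <- .predict_one(model, ba, bb, xc)
  list(tokens_a = attr_a, tokens_b = attr_b,
       ig_a = sum(attr_a), ig_b = sum(attr_b),
       prediction = pred, baseline_prediction = pred0,
       completeness_residual = sum(attr_a) + sum(attr_b) - (pred - pred0),
       steps = steps, baseline_kind = baseline)
}

.predict_one <- function(model, xa, xb, xc) {
  batch <- list(Xd1 = xa, nd1 = nrow(xa), Xd2 = xb, nd2 = nrow(xb),
                Xc = xc, nc = nrow(xc), b = 1L)
  model_forward(model, batch, train = FALSE)$yhat
}

#' Order sensitivity of drug-pair predictions
#'
#' Predicts every triplet twice — once as (drug A, drug B) and once with
#' the drugs swapped — and reports the Pearson correlation between the two
#' prediction sets. The PCC is `NA` when fewer than two triplets are given
#' or either prediction vector is constant.
#'
#' @param model a trained model.
#' @param prep prepared features.
#' @param triplets triplet data frame.
#' @param idx row indices (default all).
#' @return list of class `bs_order_report` with the paired `predictions`
#'   data frame and `pcc_between_orders`.
#' @export
order_sensitivity <- function(model, prep, triplets, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(triplets))
  y_ab <- predict(model, prep, triplets, idx = idx)
  y_ba <- predict(model, prep, triplets, idx = idx, swap_drugs = TRUE)
  pcc <- if (length(idx) >= 2 && stats::sd(y_ab) > 0 && stats::sd(y_ba) > 0) {
    stats::cor(y_ab, y_ba)
  } else NA_real_
  structure(list(predictions = data.frame(drug_a = triplets$drug_a[idx],
                                          drug_b = triplets$drug_b[idx],
                                          cell_line = triplets$cell_line[idx],
                                          y_ab = y_ab, y_ba = y_ba,
                                          stringsAsFactors = FALSE),
                 pcc_between_orders = pcc),
            class = "bs_order_report")
}

#' Export contribution pairs for scatter plotting
#'
#' Writes `delta_a`, `delta_b` and `|delta_a - delta_b|` (the distance from
#' the balanced-contribution diagonal) as a delimited table.
#'
#' @param results data frame from [perturbation_contribution()] (or any
#'   frame with `delta_a` / `delta_b`).
#' @param path output file.
#' @param sep field separator.
#' @export
contribution_scatter_export <- function(results, path, sep = ",") {
  out <- data.frame(delta_a = sprintf("%.17g", results$delta_a),
                    delta_b = sprintf("%.17g", results$delta_b),
                    abs_diff = sprintf("%.17g",
                                       abs(results$delta_a - results$delta_b)))
  if (nrow(results) == 0L) out <- out[0, , drop = FALSE]
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
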