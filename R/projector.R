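# Drug and cell-line projectors: three stacked [linear -> layer-norm -> GELU]
# stages applied row-wise (per token / per cluster feature). The same
# parameter object is used for both drugs of a pair, so the two drug
# branches share weights by construction.

proj_init <- function(d_in, d_out) {
  widths <- c(d_in, d_out, d_out, d_out)
  lapply(1:3, function(i) {
    list(lin = nn_linear_init(widths[i], widths[i + 1]),
         ln = nn_ln_init(widths[i + 1]))
  })
}

proj_fwd <- function(x, p, eps = 1e-5) {
  caches <- vector("list", 3L)
  h <- x
  for (i in 1:3) {
    lin <- nn_linear_fwd(h, p[[i]]$lin)
    ln <- nn_ln_fwd(lin$out, p[[i]]$ln, eps = eps)
    act <- nn_gelu_fwd(ln$out)
    caches[[i]] <- list(lin = lin$cache, ln = ln$cache, act = act$cache)
    h <- act$out
  }
  list(out = h, cache = caches)
}

proj_bwd <- function(dy, p, cache) {
  grads <- vector("list", 3L)
  d <- dy
  for (i in 3:1) {
    d <- nn_gelu_bwd(d, cache[[i]]$act)
    lnb <- nn_ln_bwd(d, p[[i]]$ln, cache[[i]]$ln)
    linb <- nn_linear_bwd(lnb$dx, p[[i]]$lin, cache[[i]]$lin)
    grads[[i]] <- list(lin = linb$grads, ln = lnb$grads)
    d <- linb$dx
  }
  list(dx = d, grads = grads)
}

#' Project drug token embeddings into the shared fusion space
#'
#' Applies the weight-shared drug projector: three stacked
#' \[linear -> layer normalisation -> GELU\] stages, token by token. Both
#' drugs of a pair are projected through the identical parameter object, so
#' `project_drug(tokens_a, params)` and `project_drug(tokens_b, params)`
#' differ only through their inputs.
#'
#' @param tokens numeric matrix, `N_d` tokens x `D_in` input channels.
#' @param params projector parameters as created by [init_projector_params()].
#' @param eps layer-norm variance epsilon.
#' @return numeric matrix `N_d` x `D` of projected tokens.
#' @export
project_drug <- function(tokens, params, eps = 1e-5) {
  stopifnot(is.matrix(tokens), nrow(tokens) >= 1L)
  if (ncol(tokens) != nrow(params[[1]]$lin$W)) {
    stop("token width ", ncol(tokens), " does not match projector input width ",
         nrow(params[[1]]$lin$W))
  }
  proj_fwd(tokens, params, eps = eps)$out
}

#' Project clustered cell-line features into the shared fusion space
#'
#' The cluster-level matrix `G_c` (one row per gene cluster) is passed
#' through three stacked \[linear -> layer normalisation -> GELU\] stages,
#' row-wise, yielding the cell-line token sequence used by the fusion
#' module.
#'
#' @param G_c numeric matrix, `|C|` clusters x `D_P` enriched channels.
#' @param params projector parameters as created by [init_projector_params()].
#' @param eps layer-norm variance epsilon.
#' @return numeric matrix `|C|` x `D`.
#' @export
cell_line_projector <- function(G_c, params, eps = 1e-5) {
  stopifnot(is.matrix(G_c), nrow(G_c) >= 1L)
  if (ncol(G_c) != nrow(params[[1]]$lin$W)) {
    stop("feature width ", ncol(G_c), " does not match projector input width ",
         nrow(params[[1]]$lin$W))
  }
  proj_fwd(G_c, params, eps = eps)$out
}

#' Initialise projector parameters
#'
#' @param d_in input channel count (token embedding width, or `D_P` for the
#'   cell branch).
#' @param d_out output width `D`; the two intermediate layers use the same
#'   width.
#' @return nested parameter list with one `lin`/`ln` pair per stage.
#' @export
init_projector_params <- function(d_in, d_out) proj_init(d_in, d_out)
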