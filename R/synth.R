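# Synthetic study generator: drugs with latent effect vectors carried by
# token embeddings, cell lines with planted gene-module structure, and a
# known ground-truth synergy function
#
#   y = f(u_a) + f(u_b) + interaction_strength * <u_a * u_b, v_c> + noise
#
# with f(u) = sum(tanh(u)) a fixed smooth per-drug effect, u_d the drug's
# latent vector, and v_c the cell line's module-activity vector. The
# ground truth is order-symmetric in the two drugs by construction.

.subseed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) * 48271 + k * 9973
  as.integer(s %% 2147483647)
}

#' Synthetic study configuration
#'
#' The defaults define the package's reference synthetic regime: 30 drugs
#' x 12 cell lines, 64 genes in 6 planted modules, 4 tokens per drug, and
#' a signal-to-noise ratio (signal SD over noise SD) of 4.
#'
#' @param n_drugs,n_cells entity counts.
#' @param n_genes number of genes `L`.
#' @param n_gene_modules planted gene modules; also the latent dimension of
#'   the drug effect vectors.
#' @param tokens_per_drug tokens per drug `N_d`.
#' @param d_in drug token embedding width.
#' @param d_p protein embedding width `D_P`.
#' @param n_tissues tissue labels cycled over cell lines.
#' @param module_separation distance between module centroids relative to
#'   the RMS within-module pair distance (values >= 3 give well-separated
#'   modules).
#' @param protein_sd within-module protein-embedding noise SD.
#' @param expression_sd per-gene expression noise SD around the module
#'   activity.
#' @param token_sd per-token noise SD around the drug's latent embedding.
#' @param activity_mean,activity_sd distribution of per-module activities
#'   per cell line.
#' @param interaction_strength weight of the drug x drug x cell bilinear
#'   term relative to the additive drug effects.
#' @param snr target signal-to-noise ratio (signal SD / noise SD); ignored
#'   when `noise_sd` is given directly.
#' @param noise_sd observation noise SD; `NULL` derives it from `snr`.
#' @param n_triplets number of distinct (unordered pair, cell) measurements.
#' @param seed master seed; all generator randomness derives from it.
#' @return list of class `bs_synth_config`.
#' @export
synth_config <- function(n_drugs = 30, n_cells = 12, n_genes = 64,
                         n_gene_modules = 6, tokens_per_drug = 4,
                         d_in = 16, d_p = 8, n_tissues = 4,
                         module_separation = 4, protein_sd = 0.15,
                         expression_sd = 0.15, token_sd = 0.1,
                         activity_mean = 1, activity_sd = 0.5,
                         interaction_strength = 0.6, snr = 4,
                         noise_sd = NULL, n_triplets = 2000, seed = 1L) {
  stopifnot(n_gene_modules <= n_genes, tokens_per_drug >= 1,
            is.null(noise_sd) || noise_sd >= 0)
  structure(as.list(environment()), class = "bs_synth_config")
}

#' Generate synthetic drugs
#'
#' Each drug receives a latent effect vector `u_d` (length
#' `n_gene_modules`), a token matrix whose rows scatter around the fixed
#' linear embedding of `u_d` (so the token row-mean encodes `u_d`), and a
#' random SMILES-like identifier string for the one-hot ablation path.
#'
#' @param config a [synth_config()].
#' @return named list of drug records `list(id, smiles, tokens, u)`;
#'   attribute `"embed_map"` holds the latent-to-token map.
#' @export
gen_drugs <- function(config) {
  m <- config$n_gene_modules
  set.seed(.subseed(config$seed, 1L))
  A <- matrix(stats::rnorm(m * config$d_in, sd = 1 / sqrt(m)), m, config$d_in)
  ids <- sprintf("D%02d", seq_len(config$n_drugs))
  alphabet <- c("C", "N", "O", "S", "F", "P", "(", ")", "=", "1", "2")
  drugs <- lapply(seq_len(config$n_drugs), function(i) {
    u <- stats::rnorm(m)
    base <- as.vector(u %*% A)
    tokens <- matrix(rep(base, each = config$tokens_per_drug),
                     config$tokens_per_drug, config$d_in)
    if (config$token_sd > 0) {
      tokens <- tokens + matrix(stats::rnorm(length(tokens), sd = config$token_sd),
                                nrow(tokens))
    }
    smiles <- paste(sample(alphabet, 6 + sample.int(6, 1), replace = TRUE),
                    collapse = "")
    list(id = ids[i], smiles = smiles, tokens = tokens, u = u)
  })
  names(drugs) <- ids
  attr(drugs, "embed_map") <- A
  drugs
}

#' Generate synthetic cell lines with planted gene modules
#'
#' Genes are partitioned into `n_gene_modules` balanced modules. Per-gene
#' protein embeddings scatter around module centroids whose minimum pairwise
#' distance is `module_separation` times the RMS within-module pair
#' distance. Each cell line draws one activity per module; a gene's
#' expression is its module's activity plus noise, and the enriched matrix
#' is `G = E_i * P_i` row-wise via [enrich_expression()].
#'
#' @param config a [synth_config()].
#' @return named list of cell records `list(id, tissue, expression, G,
#'   activity)`; attributes `"modules"` (planted labels), `"P"` (protein
#'   embeddings) and `"centroids"`.
#' @export
gen_cell_lines <- function(config) {
  L <- config$n_genes; m <- config$n_gene_modules; dp <- config$d_p
  set.seed(.subseed(config$seed, 2L))
  modules <- rep(seq_len(m), length.out = L)
  centroids <- matrix(stats::rnorm(m * dp), m, dp)
  if (m > 1) {
    dmin <- min(stats::dist(centroids))
    rms_within <- config$protein_sd * sqrt(2 * dp)
    centroids <- centroids * (config$module_separation * rms_within / dmin)
  }
  P <- centroids[modules, , drop = FALSE]
  if (config$protein_sd > 0) {
    P <- P + matrix(stats::rnorm(L * dp, sd = config$protein_sd), L, dp)
  }
  rownames(P) <- sprintf("G%03d", seq_len(L))
  ids <- sprintf("CL%02d", seq_len(config$n_cells))
  tissues <- sprintf("T%d", rep(seq_len(config$n_tissues),
                                length.out = config$n_cells))
  cells <- lapply(seq_len(config$n_cells), function(i) {
    activity <- stats::rnorm(m, mean = config$activity_mean,
                             sd = config$activity_sd)
    expression <- activity[modules]
    if (config$expression_sd > 0) {
      expression <- expression + stats::rnorm(L, sd = config$expression_sd)
    }
    names(expression) <- rownames(P)
    list(id = ids[i], tissue = tissues[i], expression = expression,
         G = enrich_expression(expression, P), activity = activity)
  })
  names(cells) <- ids
  attr(cells, "modules") <- modules
  attr(cells, "P") <- P
  attr(cells, "centroids") <- centroids
  cells
}

#' Generate synergy triplets from the ground-truth function
#'
#' Samples `n_triplets` distinct unordered (drug pair, cell line) keys and
#' evaluates `y = f(u_a) + f(u_b) + b * <u_a * u_b, v_c> + eps` with
#' `f(u) = sum(tanh(u))`, `b = interaction_strength` and Gaussian noise.
#' When `noise_sd` is not set it equals `sd(signal) / snr` over the sampled
#' triplets.
#'
#' @param drugs,cells outputs of [gen_drugs()] and [gen_cell_lines()].
#' @param config a [synth_config()].
#' @return triplet data frame (columns `drug_a`, `drug_b`, `cell_line`,
#'   `y`, `tissue`); attribute `"truth"` records the signal components,
#'   noise SD and realised signal-to-noise ratio.
#' @export
gen_synergy <- function(drugs, cells, config) {
  set.seed(.subseed(config$seed, 3L))
  ids <- names(drugs)
  pairs <- t(utils::combn(ids, 2))
  combos <- expand.grid(pair = seq_len(nrow(pairs)), cell = names(cells),
                        stringsAsFactors = FALSE)
  if (config$n_triplets > nrow(combos)) {
    stop("n_triplets exceeds the ", nrow(combos), " available combinations")
  }
  pick <- sample.int(nrow(combos), config$n_triplets)
  combos <- combos[pick, , drop = FALSE]
  da <- pairs[combos$pair, 1]
  db <- pairs[combos$pair, 2]
  # real screens list the two drugs of a pair in arbitrary order; emit each
  # sampled pair in a random orientation so models see both orders
  flip <- stats::runif(length(da)) < 0.5
  tmp <- da[flip]; da[flip] <- db[flip]; db[flip] <- tmp
  cl <- combos$cell
  f_add <- vapply(drugs, function(d) sum(tanh(d$u)), numeric(1))
  U <- t(vapply(drugs, function(d) d$u, numeric(config$n_gene_modules)))
  V <- t(vapply(cells, function(cc) cc$activity, numeric(config$n_gene_modules)))
  additive <- f_add[da] + f_add[db]
  inter <- rowSums(U[da, , drop = FALSE] * U[db, , drop = FALSE] *
                     V[cl, , drop = FALSE])
  signal <- additive + config$interaction_strength * inter
  noise_sd <- config$noise_sd %||% (stats::sd(signal) / config$snr)
  y <- signal + stats::rnorm(length(signal), sd = noise_sd)
  tissue <- vapply(cells[cl], function(cc) cc$tissue, character(1))
  out <- data.frame(drug_a = da, drug_b = db, cell_line = cl, y = y,
                    tissue = tissue, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "truth") <- list(signal = signal, additive = additive,
                             interaction = inter, noise_sd = noise_sd,
                             snr_realised = stats::sd(signal) / noise_sd,
                             U = U, V = V)
  out
}

#' Generate a complete synthetic dataset
#'
#' Composes [gen_drugs()], [gen_cell_lines()] and [gen_synergy()] into a
#' validated [bs_dataset()], optionally writing the full standard-format
#' file set (synergy table, expression matrix, SMILES table, drug-token and
#' protein embedding stores) so the file-reading path can be exercised
#' end-to-end.
#'
#' @param config a [synth_config()].
#' @param dir optional output directory for the file set.
#' @return list with elements `dataset` (a `bs_dataset`), `truth` (ground
#'   truth record), `drugs`, `cells`, and `paths` (when `dir` was given).
#' @export
gen_dataset <- function(config = synth_config(), dir = NULL) {
  drugs <- gen_drugs(config)
  cells <- gen_cell_lines(config)
  triplets <- gen_synergy(drugs, cells, config)
  truth <- attr(triplets, "truth")
  truth$modules <- attr(cells, "modules")
  truth$config <- config
  ds <- bs_dataset(triplets, drugs, cells)
  out <- list(dataset = ds, truth = truth, drugs = drugs, cells = cells)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      synergy = file.path(dir, "synergy.csv"),
      expression = file.path(dir, "expression.tsv"),
      smiles = file.path(dir, "smiles.csv"),
      drug_tokens = file.path(dir, "drug_tokens"),
      protein = file.path(dir, "protein_embeddings")
    )
    write_synergy_table(triplets, paths$synergy)
    expr <- vapply(cells, function(cc) cc$expression,
                   numeric(config$n_genes))
    write_expression_matrix(expr, paths$expression)
    utils::write.table(data.frame(id = names(drugs),
                                  smiles = vapply(drugs, `[[`, "", "smiles")),
                       paths$smiles, sep = ",", row.names = FALSE, quote = FALSE)
    write_embedding_store(lapply(drugs, `[[`, "tokens"), paths$drug_tokens)
    write_embedding_store(list(P = attr(cells, "P")), paths$protein)
    out$paths <- paths
  }
  out
}
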