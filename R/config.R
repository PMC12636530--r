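# Run configuration: nested blocks with YAML serialisation and the ablation
# variant matrix.

#' Full run configuration
#'
#' Bundles the per-module configuration blocks plus the ablation `variant`
#' switch. Variants mirror the ablation study: (a) plain transformer
#' fusion; (b) expression-only cell features; (c) one-hot SMILES drugs;
#' (d) both ablated feature sets with bridge fusion kept; (e) both ablated
#' feature sets with plain transformer fusion.
#'
#' @param variant one of `"full"`, `"a"`, `"b"`, `"c"`, `"d"`, `"e"`.
#' @param feature a [feature_config()].
#' @param ccf a [ccf_config()].
#' @param model a [bs_model_config()].
#' @param train a [bs_train_config()].
#' @param split a [split_spec()].
#' @param synth a [synth_config()].
#' @param data optional named list of input file paths (`synergy`,
#'   `expression`, `drug_tokens`, `protein`, `smiles`).
#' @return list of class `bs_run_config` (not yet variant-resolved).
#' @export
bs_run_config <- function(variant = "full", feature = feature_config(),
                          ccf = ccf_config(), model = bs_model_config(),
                          train = bs_train_config(), split = split_spec(),
                          synth = synth_config(), data = list()) {
  if (!variant %in% c("full", "a", "b", "c", "d", "e")) {
    stop("unknown variant: ", variant)
  }
  structure(list(variant = variant, feature = feature, ccf = ccf,
                 model = model, train = train, split = split, synth = synth,
                 data = data),
            class = "bs_run_config")
}

#' Resolve an ablation variant into concrete configuration switches
#'
#' Forces the feature and fusion switches implied by the variant and
#' errors when the configuration explicitly contradicts them (e.g. variant
#' `"e"` with `fusion = "bridge"`).
#'
#' @param config a [bs_run_config()].
#' @return the resolved `bs_run_config`.
#' @export
resolve_variant <- function(config) {
  v <- config$variant
  forced <- switch(v,
    full = list(),
    a = list(fusion = "plain"),
    b = list(cell_mode = "expression_only"),
    c = list(drug_mode = "onehot_smiles"),
    d = list(drug_mode = "onehot_smiles", cell_mode = "expression_only",
             fusion = "bridge"),
    e = list(drug_mode = "onehot_smiles", cell_mode = "expression_only",
             fusion = "plain"),
    stop("unknown variant: ", v))
  defaults <- list(drug_mode = "precomputed", cell_mode = "enriched",
                   fusion = "bridge")
  current <- list(drug_mode = config$feature$drug_mode,
                  cell_mode = config$feature$cell_mode,
                  fusion = config$model$fusion)
  for (key in names(forced)) {
    if (!identical(current[[key]], defaults[[key]]) &&
        !identical(current[[key]], forced[[key]])) {
      stop("variant '", v, "' forces ", key, " = '", forced[[key]],
           "' but the config sets '", current[[key]], "'")
    }
  }
  if (!is.null(forced$drug_mode)) config$feature$drug_mode <- forced$drug_mode
  if (!is.null(forced$cell_mode)) config$feature$cell_mode <- forced$cell_mode
  if (!is.null(forced$fusion)) config$model$fusion <- forced$fusion
  config
}

.deep_merge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .deep_merge(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a run configuration from YAML
#'
#' Missing fields fall back to the package defaults; the result is
#' variant-resolved.
#'
#' @param path YAML file.
#' @return a resolved `bs_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- bs_run_config()
  cfg <- .deep_merge(unclass(base), raw)
  # rebuild typed blocks so validation and class tags apply
  out <- bs_run_config(
    variant = cfg$variant,
    feature = do.call(feature_config, cfg$feature[names(cfg$feature) %in%
      names(formals(feature_config))]),
    ccf = do.call(ccf_config, cfg$ccf[names(cfg$ccf) %in%
      names(formals(ccf_config))]),
    model = do.call(bs_model_config, cfg$model[names(cfg$model) %in%
      names(formals(bs_model_config))]),
    train = do.call(bs_train_config, cfg$train[names(cfg$train) %in%
      names(formals(bs_train_config))]),
    split = do.call(split_spec, cfg$split[names(cfg$split) %in%
      names(formals(split_spec))]),
    synth = do.call(synth_config, cfg$synth[names(cfg$synth) %in%
      names(formals(synth_config))]),
    data = cfg$data %||% list())
  resolve_variant(out)
}

#' Write a resolved run configuration as YAML
#'
#' Every run writes its fully-resolved configuration beside its outputs for
#' provenance.
#'
#' @param config a `bs_run_config`.
#' @param path output YAML file.
#' @export
write_run_config <- function(config, path) {
  plain <- rapply(unclass(config), identity, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Load a dataset from the standard file set
#'
#' @param synergy synergy table path ([read_synergy_table()]).
#' @param expression expression matrix path ([read_expression_matrix()]).
#' @param drug_tokens optional drug token embedding store.
#' @param protein optional protein embedding store (matrix under key
#'   `"P"`, rows aligned with the expression gene order).
#' @param smiles optional id,smiles table for the one-hot path.
#' @param allow_duplicates passed to [bs_dataset()].
#' @return a validated [bs_dataset()].
#' @export
load_dataset <- function(synergy, expression, drug_tokens = NULL,
                         protein = NULL, smiles = NULL,
                         allow_duplicates = FALSE) {
  triplets <- read_synergy_table(synergy)
  expr <- read_expression_matrix(expression)
  drug_ids <- unique(c(triplets$drug_a, triplets$drug_b))
  tokens <- if (!is.null(drug_tokens)) {
    read_embedding_store(drug_tokens, drug_ids)
  }
  smi <- if (!is.null(smiles)) {
    tab <- utils::read.table(smiles, header = TRUE, sep = ",",
                             stringsAsFactors = FALSE)
    stats::setNames(tab$smiles, tab$id)
  }
  drugs <- lapply(drug_ids, function(id) {
    list(id = id, smiles = smi[[id]] %||% NULL,
         tokens = if (!is.null(tokens)) tokens[[id]])
  })
  names(drugs) <- drug_ids
  P <- if (!is.null(protein)) read_embedding_store(protein, "P")$P
  if (!is.null(P) && nrow(P) != nrow(expr)) {
    stop("protein embedding rows (", nrow(P), ") do not match gene count (",
         nrow(expr), ")")
  }
  cells <- lapply(colnames(expr), function(id) {
    e <- expr[, id]
    list(id = id, expression = e,
         G = if (!is.null(P)) enrich_expression(e, P))
  })
  names(cells) <- colnames(expr)
  bs_dataset(triplets, drugs, cells, allow_duplicates = allow_duplicates)
}
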