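# Reading and writing the external tables and embedding stores, and
# assembling a validated in-memory dataset.
#
# Triplets are kept as a data frame (one row per measurement), drugs and
# cell lines as named lists of records. Numeric columns are written with
# full precision ("%.17g") so write -> read round-trips exactly to printed
# precision.

.default_cols <- list(drug_a = "drug_a", drug_b = "drug_b",
                      cell_line = "cell_line", score = "score",
                      tissue = "tissue")

#' Read a synergy triplet table
#'
#' One triplet per row; rows whose synergy score is missing or non-numeric
#' are rejected (their count is reported via a message and the
#' `"n_rejected"` attribute), while structural violations (a drug paired
#' with itself) are errors. Column names are configurable.
#'
#' @param path delimited text file.
#' @param sep field separator (default comma).
#' @param cols named list mapping the roles `drug_a`, `drug_b`, `cell_line`,
#'   `score`, `tissue` to column names in the file; `tissue` is optional.
#' @return data frame with columns `drug_a`, `drug_b`, `cell_line`, `y` and,
#'   when present, `tissue`. Attribute `"n_rejected"` counts dropped rows.
#' @export
read_synergy_table <- function(path, sep = ",", cols = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- utils::modifyList(.default_cols, cols)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  required <- c("drug_a", "drug_b", "cell_line", "score")
  missing_cols <- setdiff(unlist(cols[required]), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  y <- suppressWarnings(as.numeric(raw[[cols$score]]))
  bad <- !is.finite(y)
  if (any(bad)) {
    message(sum(bad), " row(s) with missing or non-finite scores rejected ",
            "(lines ", paste(utils::head(which(bad) + 1L, 10L), collapse = ", "), ")")
  }
  out <- data.frame(drug_a = as.character(raw[[cols$drug_a]]),
                    drug_b = as.character(raw[[cols$drug_b]]),
                    cell_line = as.character(raw[[cols$cell_line]]),
                    y = y, stringsAsFactors = FALSE)
  if (cols$tissue %in% names(raw)) out$tissue <- as.character(raw[[cols$tissue]])
  out <- out[!bad, , drop = FALSE]
  self_pair <- out$drug_a == out$drug_b
  if (any(self_pair)) {
    stop("drug_a equals drug_b in row(s): ",
         paste(utils::head(which(self_pair), 10L), collapse = ", "))
  }
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write a synergy triplet table
#'
#' @param triplets data frame as returned by [read_synergy_table()].
#' @param path output file.
#' @param sep field separator.
#' @export
write_synergy_table <- function(triplets, path, sep = ",") {
  out <- triplets
  names(out)[names(out) == "y"] <- "score"
  out$score <- sprintf("%.17g", out$score)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene expression matrix
#'
#' Expects a header of cell-line ids, a first column of gene ids, and one
#' row per gene. Gene ordering is shared by construction across cell lines.
#'
#' @param path delimited text file.
#' @param sep field separator (default tab).
#' @return numeric matrix, genes x cell lines, with dimnames.
#' @export
read_expression_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(raw[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) {
    stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "))
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- genes
  m
}

#' Write a gene expression matrix
#'
#' @param m numeric matrix, genes x cell lines, with dimnames.
#' @param path output file.
#' @param sep field separator.
#' @export
write_expression_matrix <- function(m, path, sep = "\t") {
  df <- data.frame(gene = rownames(m),
                   apply(m, 2, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a keyed embedding store
#'
#' Stores a named list of 2-D numeric arrays, one per drug or gene id. Two
#' on-disk layouts are supported: a single `.rds` file (compact, default for
#' model runs) or a directory of full-precision TSV matrices with an
#' `index.tsv` manifest (plain-text interchange).
#'
#' @param x named list of numeric matrices.
#' @param path target `.rds` file or directory.
#' @export
write_embedding_store <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)), all(vapply(x, is.matrix, logical(1))))
  if (grepl("\\.rds$", path)) {
    saveRDS(x, path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("m%04d.tsv", seq_along(x))
  idx <- data.frame(id = names(x), file = files,
                    nrow = vapply(x, nrow, integer(1)),
                    ncol = vapply(x, ncol, integer(1)))
  utils::write.table(idx, file.path(path, "index.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (i in seq_along(x)) {
    utils::write.table(matrix(sprintf("%.17g", x[[i]]), nrow(x[[i]])),
                       file.path(path, files[i]), sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read matrices from a keyed embedding store
#'
#' @param path `.rds` file or directory written by [write_embedding_store()].
#' @param ids ids to fetch; `NULL` fetches everything. Missing ids raise an
#'   error naming the absentees.
#' @return named list of numeric matrices.
#' @export
read_embedding_store <- function(path, ids = NULL) {
  if (grepl("\\.rds$", path)) {
    store <- readRDS(path)
  } else {
    idx <- utils::read.table(file.path(path, "index.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
    store <- lapply(seq_len(nrow(idx)), function(i) {
      m <- as.matrix(utils::read.table(file.path(path, idx$file[i]),
                                       sep = "\t", header = FALSE))
      dimnames(m) <- NULL
      m
    })
    names(store) <- idx$id
  }
  if (is.null(ids)) return(store)
  absent <- setdiff(ids, names(store))
  if (length(absent) > 0) {
    stop("id(s) absent from embedding store: ", paste(absent, collapse = ", "))
  }
  store[ids]
}

#' Write predictions alongside their triplets
#'
#' @param triplets triplet data frame; the `y` column, when present, is
#'   written too.
#' @param y_hat numeric vector of predictions, same length as
#'   `nrow(triplets)`.
#' @param path output file.
#' @param sep field separator.
#' @export
write_predictions <- function(triplets, y_hat, path, sep = ",") {
  if (nrow(triplets) != length(y_hat)) {
    stop("length mismatch: ", nrow(triplets), " triplets vs ",
         length(y_hat), " predictions")
  }
  out <- triplets[, intersect(c("drug_a", "drug_b", "cell_line", "y"),
                              names(triplets)), drop = FALSE]
  if ("y" %in% names(out)) out$y <- sprintf("%.17g", out$y)
  out$y_hat <- sprintf("%.17g", y_hat)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a prediction table written by [write_predictions()]
#'
#' @param path file path.
#' @param sep field separator.
#' @return data frame with numeric `y` (if present) and `y_hat`.
#' @export
read_predictions <- function(path, sep = ",") {
  out <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  out
}

#' Assemble and validate a dataset
#'
#' Checks that every triplet's drug and cell-line ids resolve, that token
#' and feature matrices are finite, and that no unordered (drug pair, cell
#' line) key occurs twice unless `allow_duplicates = TRUE`.
#'
#' @param triplets triplet data frame ([read_synergy_table()]).
#' @param drugs named list of drug records; each needs a `tokens` matrix
#'   (and may carry `smiles`).
#' @param cells named list of cell-line records; each needs an `expression`
#'   vector and may carry an enriched matrix `G`.
#' @param allow_duplicates allow repeated unordered (pair, cell) keys.
#' @return list of class `bs_dataset`.
#' @export
bs_dataset <- function(triplets, drugs, cells, allow_duplicates = FALSE) {
  miss_d <- setdiff(unique(c(triplets$drug_a, triplets$drug_b)), names(drugs))
  if (length(miss_d) > 0) {
    stop("unresolvable drug id(s): ", paste(utils::head(miss_d, 10), collapse = ", "))
  }
  miss_c <- setdiff(unique(triplets$cell_line), names(cells))
  if (length(miss_c) > 0) {
    stop("unresolvable cell line id(s): ", paste(utils::head(miss_c, 10), collapse = ", "))
  }
  if (!all(is.finite(triplets$y))) stop("non-finite synergy scores")
  key <- pair_key(triplets$drug_a, triplets$drug_b, triplets$cell_line)
  if (!allow_duplicates && anyDuplicated(key)) {
    stop("duplicate unordered (drug pair, cell line) key(s), e.g. ",
         key[which(duplicated(key))[1]])
  }
  for (id in names(drugs)) {
    tk <- drugs[[id]]$tokens
    if (!is.null(tk) && (!is.matrix(tk) || nrow(tk) < 1 || !all(is.finite(tk)))) {
      stop("invalid token matrix for drug ", id)
    }
  }
  structure(list(triplets = triplets, drugs = drugs, cells = cells),
            class = "bs_dataset")
}

#' Unordered (drug pair, cell line) key
#'
#' `(A, B, CL)` and `(B, A, CL)` map to the same key, matching the
#' order-invariance of a drug combination.
#'
#' @param drug_a,drug_b,cell_line character vectors.
#' @return character vector of keys.
#' @export
pair_key <- function(drug_a, drug_b, cell_line = NULL) {
  lo <- pmin(drug_a, drug_b)
  hi <- pmax(drug_a, drug_b)
  if (is.null(cell_line)) paste(lo, hi, sep = "||")
  else paste(lo, hi, cell_line, sep = "||")
}
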