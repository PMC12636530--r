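# Featurization: expression-enriched gene matrices and the ablation
# fallbacks (one-hot SMILES drugs, expression-only cells).

#' Enrich an expression vector with per-gene protein embeddings
#'
#' Row `i` of the result is `E_i * P_i`: the gene's expression value scales
#' its protein-sequence embedding. Linear in `E` by construction.
#'
#' @param expression numeric vector of length `L`.
#' @param P numeric matrix `L x D_P` of per-gene protein embeddings.
#' @return numeric matrix `L x D_P`.
#' @export
enrich_expression <- function(expression, P) {
  if (length(expression) != nrow(P)) {
    stop("expression length ", length(expression),
         " does not match nrow(P) = ", nrow(P))
  }
  unname(P * expression)
}

#' Expression-only cell features
#'
#' The degenerate `D_P = 1` enrichment used when the protein language-model
#' features are ablated: the expression vector becomes a single-column
#' matrix, so downstream shapes stay uniform.
#'
#' @param expression numeric vector of length `L`.
#' @return numeric matrix `L x 1`.
#' @export
expression_only_features <- function(expression) {
  if (!all(is.finite(expression))) stop("non-finite expression values")
  matrix(expression, ncol = 1)
}

#' Default SMILES character vocabulary
#'
#' Single characters covering organic-subset SMILES; two-character halogen
#' tokens (`Cl`, `Br`) are handled by [one_hot_smiles()] when
#' `two_char = TRUE`.
#'
#' @return character vector without duplicates.
#' @export
smiles_default_vocab <- function() {
  c("C", "N", "O", "S", "P", "F", "I", "B",
    "c", "n", "o", "s", "p",
    "(", ")", "[", "]", "=", "#", "+", "-", "@", "/", "\\", ".",
    "H", as.character(0:9))
}

#' One-hot encode a SMILES string
#'
#' Per-character tokenization (optionally recognising the two-character
#' tokens `Cl` and `Br`), producing one indicator row per token. Unknown
#' characters either map to an extra UNK column or raise an error naming
#' the character and its position.
#'
#' @param smiles SMILES text, at least one character.
#' @param vocab token vocabulary (no duplicates).
#' @param unk if `TRUE` (default), unknown tokens map to an appended UNK
#'   column; if `FALSE` they are an error.
#' @param max_len truncate token sequences longer than this.
#' @param two_char recognise `Cl`/`Br` as single tokens.
#' @param pad_to pad shorter sequences to this token count with a dedicated
#'   PAD indicator column (and truncate longer ones), so all drugs share one
#'   sequence length; `NULL` (default) keeps the native length.
#' @return numeric matrix `N_d x |vocab|` (plus an UNK column if
#'   `unk = TRUE`, plus a PAD column if `pad_to` is set); every row sums
#'   to 1.
#' @export
one_hot_smiles <- function(smiles, vocab = smiles_default_vocab(), unk = TRUE,
                           max_len = 128L, two_char = FALSE, pad_to = NULL) {
  if (anyDuplicated(vocab)) stop("vocabulary contains duplicates")
  if (!is.character(smiles) || length(smiles) != 1L || nchar(smiles) < 1L) {
    stop("smiles must be a non-empty string (N_d >= 1)")
  }
  toks <- strsplit(smiles, "")[[1]]
  if (two_char) {
    merged <- character(0)
    i <- 1L
    while (i <= length(toks)) {
      two <- if (i < length(toks)) paste0(toks[i], toks[i + 1]) else ""
      if (two %in% c("Cl", "Br") && two %in% vocab) {
        merged <- c(merged, two); i <- i + 2L
      } else {
        merged <- c(merged, toks[i]); i <- i + 1L
      }
    }
    toks <- merged
  }
  if (length(toks) > max_len) toks <- toks[seq_len(max_len)]
  if (!is.null(pad_to) && length(toks) > pad_to) toks <- toks[seq_len(pad_to)]
  idx <- match(toks, vocab)
  unk_col <- if (unk) length(vocab) + 1L
  if (anyNA(idx)) {
    if (!unk) {
      p <- which(is.na(idx))[1]
      stop("unknown SMILES character '", toks[p], "' at position ", p)
    }
    idx[is.na(idx)] <- unk_col
  }
  ncols <- length(vocab) + as.integer(unk) + as.integer(!is.null(pad_to))
  nrows <- if (is.null(pad_to)) length(toks) else max(pad_to, length(toks))
  m <- matrix(0, nrows, ncols)
  m[cbind(seq_along(toks), idx)] <- 1
  if (nrows > length(toks)) {
    m[(length(toks) + 1L):nrows, ncols] <- 1  # PAD indicator column
  }
  m
}
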