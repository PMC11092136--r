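# Fixed-width sequence encoders. Two encoders are computed in-package:
#  * onehot_mean - mean-pooled one-hot, i.e. the residue-composition vector
#    over the 21-symbol alphabet (width 21, entries in [0,1], rows sum to 1);
#  * sgt - the Sequence Graph Transform: one feature per ordered symbol pair
#    (u,v), accumulating exponentially decaying weights e^(-kappa * gap) over
#    all position pairs i<j with s_i = u, s_j = v, then normalizing and taking
#    the 1/kappa power (width 441 = 21^2, entries >= 0).
# Pretrained language-model embeddings (SeqVec/ProtBERT-like) are supported as
# precomputed matrices only, loaded from disk; no model inference happens here.

new_embedding_set <- function(method, ids, matrix, range_regime,
                              params = list()) {
  stopifnot(nrow(matrix) == length(ids))
  if (anyDuplicated(ids)) {
    stop_invalid("Embedding ids must be unique.", "drembed_duplicate_id")
  }
  rownames(matrix) <- ids
  structure(
    list(
      method = method, ids = ids, matrix = matrix,
      range_regime = range_regime, params = params
    ),
    class = "embedding_set"
  )
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(
    "<embedding_set> method=", x$method,
    " n=", length(x$ids), " d=", ncol(x$matrix),
    " regime=", x$range_regime, "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
as.matrix.embedding_set <- function(x, ...) x$matrix

#' @export
dim.embedding_set <- function(x) dim(x$matrix)

#' Tidy an embedding set into a tibble
#'
#' @param x An `embedding_set`.
#' @method tidy embedding_set
#' @param ... Unused.
#' @return A tibble with an `id` column followed by the `d` numeric feature
#'   columns, prefixed by the method label.
#' @export
tidy.embedding_set <- function(x, ...) {
  m <- x$matrix
  cols <- colnames(m) %||% paste0("f", seq_len(ncol(m)))
  out <- as_tibble(m, .name_repair = "minimal")
  names(out) <- paste(gsub("[^A-Za-z0-9]", "_", x$method), cols, sep = ".")
  dplyr::bind_cols(tibble(id = x$ids), out)
}

#' One-hot encode a sanitized sequence
#'
#' Returns the position-by-symbol indicator matrix: row `i` has a single 1 at
#' the alphabet index of residue `i`.
#'
#' @param sequence A single sanitized amino-acid string (see
#'   [sanitize_sequence()]).
#' @return A binary matrix of shape `length x 21`, columns named by
#'   [aa_alphabet()].
#' @examples
#' one_hot_encode("ACX")
#' @export
one_hot_encode <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  alpha <- aa_alphabet()
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- match(chars, alpha)
  if (anyNA(idx)) {
    stop_invalid(
      paste0(
        "Symbol(s) outside the 21-symbol alphabet: ",
        paste(unique(chars[is.na(idx)]), collapse = ", "),
        ". Run sanitize_sequence() first."
      ),
      "drembed_encoding_error"
    )
  }
  m <- matrix(0, nrow = length(idx), ncol = length(alpha),
              dimnames = list(NULL, alpha))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Mean-pool a position-by-feature matrix
#'
#' Averages over the sequence-position axis, turning a `length x d` per-residue
#' representation into a single width-`d` vector. Applied to a one-hot matrix
#' this yields exactly the residue-composition (symbol frequency) vector.
#'
#' @param position_matrix Numeric matrix, one row per sequence position.
#' @return Numeric vector of length `ncol(position_matrix)`.
#' @examples
#' mean_pool(one_hot_encode("AAC"))[c("A", "C")]
#' @export
mean_pool <- function(position_matrix) {
  if (!is.matrix(position_matrix) || nrow(position_matrix) == 0) {
    stop_invalid(
      "`position_matrix` must be a matrix with at least one row.",
      "drembed_encoding_error"
    )
  }
  colMeans(position_matrix)
}

#' Names of the 441 Sequence Graph Transform features
#'
#' Ordered first-symbol-major over [aa_alphabet()]: `A>A, A>C, ..., A>X, C>A,
#' ...` This ordering is part of the on-disk contract for embedding tables.
#'
#' @return Character vector of length 441.
#' @export
sgt_feature_names <- function() {
  alpha <- aa_alphabet()
  paste(rep(alpha, each = length(alpha)), rep(alpha, length(alpha)), sep = ">")
}

#' Sequence Graph Transform encoding
#'
#' Encodes a sequence as 441 ordered-pair features. For each ordered symbol
#' pair (u, v), all position pairs i < j with `s[i] == u`, `s[j] == v`
#' contribute weight `exp(-kappa * (j - i))`; the accumulated weight is divided
#' by a normalizer and raised to the power `1/kappa`. The normalizer is the
#' number of contributing position pairs (`length_insensitive`, the default) or
#' the sequence length (`length_sensitive`). Features with no contributing pair
#' are 0. Computed with an O(21 L) recurrence; deterministic.
#'
#' @param sequence A single sanitized amino-acid string.
#' @param kappa Positive decay constant (default 1).
#' @param mode `"length_insensitive"` (default) or `"length_sensitive"`.
#' @return Named numeric vector of length 441 (see [sgt_feature_names()]), all
#'   entries >= 0. A length-1 sequence returns the all-zero vector with a
#'   warning.
#' @examples
#' sgt_encode("AA")[["A>A"]] # exp(-1)
#' @export
sgt_encode <- function(sequence, kappa = 1,
                       mode = c("length_insensitive", "length_sensitive")) {
  mode <- match.arg(mode)
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0) {
    stop_invalid("`kappa` must be a single positive number.", "drembed_invalid_parameter")
  }
  alpha <- aa_alphabet()
  n_sym <- length(alpha)
  L <- nchar(sequence)
  if (L < 1) {
    stop_invalid("Cannot SGT-encode an empty sequence.", "drembed_encoding_error")
  }
  out <- stats::setNames(numeric(n_sym * n_sym), sgt_feature_names())
  if (L == 1) {
    warn("Length-1 sequence: SGT features are all zero.")
    return(out)
  }
  idx <- match(strsplit(sequence, "", fixed = TRUE)[[1]], alpha)
  if (anyNA(idx)) {
    stop_invalid(
      "Symbol(s) outside the 21-symbol alphabet; run sanitize_sequence() first.",
      "drembed_encoding_error"
    )
  }
  decay <- exp(-kappa)
  # weight[u] = sum over earlier positions i of exp(-kappa * (j - i)) [s_i = u]
  # count[u]  = number of earlier positions with s_i = u
  weight <- numeric(n_sym)
  count <- numeric(n_sym)
  wsum <- matrix(0, n_sym, n_sym) # accumulated decayed weights, [u, v]
  npair <- matrix(0, n_sym, n_sym) # number of contributing position pairs
  for (j in 2:L) {
    weight <- weight * decay
    weight[idx[j - 1]] <- weight[idx[j - 1]] + decay
    count[idx[j - 1]] <- count[idx[j - 1]] + 1
    v <- idx[j]
    wsum[, v] <- wsum[, v] + weight
    npair[, v] <- npair[, v] + count
  }
  norm <- if (mode == "length_insensitive") npair else L
  feat <- matrix(0, n_sym, n_sym)
  pos <- npair > 0
  feat[pos] <- (wsum[pos] / (if (is.matrix(norm)) norm[pos] else norm))^(1 / kappa)
  out[] <- as.vector(t(feat)) # first-symbol-major
  out
}

#' Embed a protein corpus
#'
#' Applies one of the in-package encoders to every record, producing an
#' `embedding_set` whose rows are aligned with the record order.
#'
#' @param records Protein-record tibble (sanitized and length-filtered).
#' @param method `"onehot_mean"` or `"sgt"`.
#' @param kappa,mode SGT parameters, ignored for `onehot_mean`.
#' @param verbose Log progress every 500 sequences.
#' @return An `embedding_set` with `range_regime = "nonnegative"`.
#' @export
embed_corpus <- function(records, method = c("onehot_mean", "sgt"),
                         kappa = 1,
                         mode = c("length_insensitive", "length_sensitive"),
                         verbose = FALSE) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  check_records(records)
  n <- nrow(records)
  if (method == "onehot_mean") {
    d <- 21L
    cols <- aa_alphabet()
    enc <- function(s) mean_pool(one_hot_encode(s))
    params <- list()
  } else {
    d <- 441L
    cols <- sgt_feature_names()
    enc <- function(s) sgt_encode(s, kappa = kappa, mode = mode)
    params <- list(kappa = kappa, mode = mode)
  }
  m <- matrix(0, nrow = n, ncol = d, dimnames = list(records$id, cols))
  for (i in seq_len(n)) {
    m[i, ] <- enc(records$sequence[i])
    if (verbose && i %% 500 == 0) {
      inform(paste0("embed_corpus[", method, "]: ", i, "/", n))
    }
  }
  new_embedding_set(method, records$id, m, "nonnegative", params)
}

#' Load precomputed external embeddings
#'
#' Reads a delimited table (TSV by default, CSV by `.csv` extension; optionally
#' gzipped) with an id column followed by a fixed number of numeric feature
#' columns — the interchange format for embeddings computed outside this
#' package by pretrained protein language models. External embeddings may
#' contain negative values, so their cosine distances live on [0, 2]; they are
#' loaded as-is, with no re-normalization.
#'
#' @param path Path to the matrix file.
#' @param method_name Short label for the source model (e.g. `"seqvec"`).
#' @return An `embedding_set` with `method = "external:<method_name>"` and
#'   `range_regime = "signed"`.
#' @export
load_external_embeddings <- function(path, method_name) {
  stopifnot(is.character(method_name), length(method_name) == 1)
  if (!file.exists(path)) {
    stop_invalid(paste0("Embedding file not found: ", path), "drembed_io_error")
  }
  reader <- if (grepl("\\.csv(\\.gz)?$", path)) readr::read_csv else readr::read_tsv
  df <- withr::with_options(
    list(readr.show_col_types = FALSE),
    suppressWarnings(reader(path, comment = "#", progress = FALSE, show_col_types = FALSE))
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop_invalid(
      paste0(
        "Ragged or non-numeric rows in ", path, " at line(s) ",
        paste(unique(probs$row + 1), collapse = ", "), "."
      ),
      "drembed_parse_error"
    )
  }
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop_invalid(
      paste0("Embedding table ", path, " needs >= 1 row and an id column plus >= 1 numeric column."),
      "drembed_parse_error"
    )
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop_invalid(
      paste0("Duplicate ids in embedding table ", path, "."),
      "drembed_duplicate_id"
    )
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) {
    stop_invalid(
      paste0("Non-numeric or missing embedding values in ", path, "."),
      "drembed_parse_error"
    )
  }
  new_embedding_set(paste0("external:", method_name), ids, m, "signed")
}

#' Write an embedding set to a TSV table
#'
#' The output round-trips through [load_external_embeddings()] (which will tag
#' it `signed`; the in-package encoders' values are nonnegative regardless).
#'
#' @param embeddings An `embedding_set`.
#' @param path Output path (`.gz` for compression).
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  stopifnot(inherits(embeddings, "embedding_set"))
  readr::write_tsv(tidy(embeddings), path, progress = FALSE)
  invisible(path)
}
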