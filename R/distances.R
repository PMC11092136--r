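# Cosine distances between embedding rows: distance = 1 - cos(theta) with
# cos(theta) = (a . b) / (||a|| ||b||). Nonnegative embeddings (onehot_mean,
# sgt) give distances on [0, 1]; signed (external) embeddings on [0, 2].
# The all-pairs background universe is streamed in chunks through a
# rank <-> (i, j) bijection so it is never materialised.

regime_upper <- function(range_regime) {
  switch(range_regime,
    nonnegative = 1,
    signed = 2,
    stop_invalid(paste0("Unknown range regime: ", range_regime), "drembed_invalid_parameter")
  )
}

#' Cosine distance between two vectors
#'
#' `1 - (a . b) / (||a|| ||b||)`. Identical directions give 0, orthogonal
#' vectors 1, opposite directions 2.
#'
#' @param a,b Numeric vectors of equal length with nonzero norm.
#' @return A single number.
#' @examples
#' cosine_distance(c(1, 0), c(0, 1))
#' @export
cosine_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop_invalid("Vectors must have the same width.", "drembed_invalid_parameter")
  }
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop_invalid(
      "Cosine distance is undefined for zero-norm vectors.",
      "drembed_undefined_distance"
    )
  }
  1 - sum(a * b) / (na * nb)
}

# Vectorized cosine distances between row blocks of a unit-normalized matrix.
row_normalize <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  list(unit = m / ifelse(nrm == 0, 1, nrm), norm = nrm)
}

clip_distances <- function(d, upper, slack = 1e-12) {
  if (any(d < -slack | d > upper + slack)) {
    warn("Distances outside the declared regime by more than 1e-12 were clipped.")
  }
  pmin(pmax(d, 0), upper)
}

#' Cosine distances for a table of protein pairs
#'
#' Computes one distance per requested unordered pair. Pairs referencing ids
#' absent from the embedding set (or rows with zero norm) are skipped with a
#' warning.
#'
#' @param embeddings An `embedding_set`.
#' @param pairs Data frame with columns `id_a`, `id_b` (extra columns are
#'   carried through).
#' @return A tibble with columns `id_a`, `id_b` (canonicalized), any extra
#'   columns from `pairs`, plus `method` and `distance`.
#' @export
pair_distances <- function(embeddings, pairs) {
  stopifnot(inherits(embeddings, "embedding_set"))
  stopifnot(all(c("id_a", "id_b") %in% names(pairs)))
  pairs <- as_tibble(pairs)
  if (any(pairs$id_a == pairs$id_b)) {
    stop_invalid("Self-pairs are not allowed in a pair table.", "drembed_invalid_records")
  }
  canon <- canonical_pairs(pairs$id_a, pairs$id_b)
  pairs$id_a <- canon$id_a
  pairs$id_b <- canon$id_b

  nr <- row_normalize(embeddings$matrix)
  usable <- embeddings$ids[nr$norm > 0]
  if (length(usable) < length(embeddings$ids)) {
    warn(paste0(
      sum(nr$norm == 0), " zero-norm embedding row(s) skipped in pair_distances()."
    ))
  }
  ok <- pairs$id_a %in% usable & pairs$id_b %in% usable
  if (!all(ok)) {
    warn(paste0(
      sum(!ok), " pair(s) referencing missing or zero-norm ids were skipped."
    ))
    pairs <- pairs[ok, , drop = FALSE]
  }
  u <- nr$unit
  ia <- match(pairs$id_a, embeddings$ids)
  ib <- match(pairs$id_b, embeddings$ids)
  d <- unname(1 - rowSums(u[ia, , drop = FALSE] * u[ib, , drop = FALSE]))
  pairs$method <- embeddings$method
  pairs$distance <- clip_distances(d, regime_upper(embeddings$range_regime))
  pairs
}

#' Stream (or sample) background pair distances
#'
#' Enumerates the unordered-pair universe of an embedding set through a
#' rank-to-index bijection, excluding a given pair table, and computes cosine
#' distances chunk by chunk (memory is bounded by `chunk_size * d`). With
#' `sample_cap` set, a uniform random subset of exactly
#' `min(sample_cap, available)` pairs is drawn, reproducibly under `seed`,
#' without materialising the pair list.
#'
#' @param embeddings An `embedding_set`.
#' @param exclude Optional data frame of pairs (`id_a`, `id_b`) to exclude.
#' @param sample_cap Optional maximum number of background pairs to return.
#' @param seed Integer seed for the uniform sample (required with
#'   `sample_cap`).
#' @param chunk_size Pairs processed per chunk (default 50000).
#' @return A tibble with columns `id_a`, `id_b`, `method`, `distance`, one row
#'   per retained pair.
#' @export
background_distances <- function(embeddings, exclude = NULL, sample_cap = NULL,
                                 seed = 1L, chunk_size = 50000L) {
  stopifnot(inherits(embeddings, "embedding_set"))
  if (chunk_size < 1) {
    stop_invalid("`chunk_size` must be >= 1.", "drembed_invalid_parameter")
  }
  nr <- row_normalize(embeddings$matrix)
  keep <- nr$norm > 0
  if (!all(keep)) {
    warn(paste0(sum(!keep), " zero-norm embedding row(s) skipped in background_distances()."))
  }
  # canonical id order makes pair ranks independent of input row order
  ids <- sort_c(embeddings$ids[keep])
  u <- nr$unit[match(ids, embeddings$ids), , drop = FALSE]
  n <- length(ids)
  total <- n_unordered_pairs(n)
  if (total < 1) {
    return(tibble(
      id_a = character(0), id_b = character(0),
      method = character(0), distance = numeric(0)
    ))
  }

  excl_ranks <- numeric(0)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    canon <- canonical_pairs(exclude$id_a, exclude$id_b)
    ia <- match(canon$id_a, ids)
    ib <- match(canon$id_b, ids)
    resolvable <- !is.na(ia) & !is.na(ib)
    excl_ranks <- unique(rank_of_pair(
      pmin(ia[resolvable], ib[resolvable]),
      pmax(ia[resolvable], ib[resolvable]), n
    ))
  }
  available <- total - length(excl_ranks)

  ranks <- if (is.null(sample_cap) || sample_cap >= available) {
    r <- seq_len(total)
    if (length(excl_ranks) > 0) r <- r[!(r %in% excl_ranks)]
    r
  } else {
    sample_pair_ranks(total, excl_ranks, sample_cap, seed)
  }

  upper <- regime_upper(embeddings$range_regime)
  chunks <- split(ranks, ceiling(seq_along(ranks) / chunk_size))
  out <- lapply(chunks, function(r) {
    ij <- unrank_pairs(r, n)
    d <- unname(1 - rowSums(u[ij$i, , drop = FALSE] * u[ij$j, , drop = FALSE]))
    tibble(
      id_a = ids[ij$i], id_b = ids[ij$j],
      method = embeddings$method,
      distance = clip_distances(d, upper)
    )
  })
  dplyr::bind_rows(out)
}

# Uniform sample of pair ranks avoiding excluded ranks. For small universes the
# ranks are enumerated; for large ones rejection sampling over the rank range
# is used (duplicate draws and exclusions rejected), which stays exact and
# memory-bounded.
sample_pair_ranks <- function(total, excl_ranks, cap, seed) {
  withr::with_seed(substream_seed(seed, "background-sample"), {
    if (total <= 2e6) {
      pool <- seq_len(total)
      if (length(excl_ranks) > 0) pool <- pool[!(pool %in% excl_ranks)]
      sort(sample(pool, cap))
    } else {
      chosen <- numeric(0)
      excl <- excl_ranks
      while (length(chosen) < cap) {
        draw <- floor(runif(ceiling((cap - length(chosen)) * 1.3)) * total) + 1
        draw <- draw[!(draw %in% excl) & !(draw %in% chosen)]
        chosen <- c(chosen, unique(draw))
      }
      sort(chosen[seq_len(cap)])
    }
  })
}

sort_c <- function(x) withr::with_collate("C", sort(x))

#' Summarize distances per embedding method
#'
#' Mean, population standard deviation, and median of the `distance` column,
#' grouped by `method`. The mean values are the below-mean thresholds used by
#' [call_candidates()].
#'
#' @param records Tibble of distance records (from [pair_distances()] or
#'   [background_distances()]).
#' @return A tibble with columns `method`, `n_pairs`, `mean`, `std`, `median`.
#' @export
summarize_distances <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop_invalid("Cannot summarize an empty distance table.", "drembed_invalid_records")
  }
  stopifnot(all(c("method", "distance") %in% names(records)))
  records |>
    group_by(.data$method) |>
    summarise(
      n_pairs = dplyr::n(),
      mean = mean(.data$distance),
      std = pop_sd(.data$distance),
      median = median(.data$distance),
      .groups = "drop"
    )
}
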