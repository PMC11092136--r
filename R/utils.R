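# Internal helpers shared across modules: deterministic seed substreams,
# canonical pair keys, and the (rank <-> index pair) bijection used to stream
# or sample the all-pairs universe without materialising it.

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one master seed. Named substreams
#' are derived with a small polynomial string hash so that independent stages
#' (background sampling, each resampling iteration, simulation, t-SNE) get
#' stable, decoupled seeds: changing the number of iterations never reshuffles
#' earlier iterations.
#'
#' @param seed Master integer seed.
#' @param name Substream name, e.g. `"mwu-iter-17"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, name) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed %% m)
  for (k in utf8ToInt(name)) {
    h <- (h * 31 + k) %% m
  }
  as.integer(h)
}

# Canonicalize unordered id pairs: id_a < id_b lexicographically (C collation,
# so results do not depend on the session locale).
canonical_pairs <- function(id_a, id_b) {
  swap <- withr::with_collate("C", id_a > id_b)
  a <- ifelse(swap, id_b, id_a)
  b <- ifelse(swap, id_a, id_b)
  tibble(id_a = a, id_b = b)
}

pair_key <- function(id_a, id_b) paste(id_a, id_b, sep = "\r")

# Bijection between pair ranks 1..n(n-1)/2 and index pairs (i < j) of
# seq_len(n), ordered (1,2),(1,3),...,(1,n),(2,3),... Ranks are doubles so the
# universe may exceed .Machine$integer.max.
n_unordered_pairs <- function(n) n * (n - 1) / 2

unrank_pairs <- function(rank, n) {
  total <- n_unordered_pairs(n)
  stopifnot(all(rank >= 1), all(rank <= total))
  i <- n - 1 - floor((sqrt(8 * (total - rank) + 1) - 1) / 2)
  # guard against floating-point edge error in the sqrt
  before <- function(i) (i - 1) * n - i * (i - 1) / 2
  too_high <- before(i) >= rank
  i[too_high] <- i[too_high] - 1
  too_low <- before(i + 1) < rank
  i[too_low] <- i[too_low] + 1
  j <- rank - before(i) + i
  list(i = as.integer(i), j = as.integer(j))
}

rank_of_pair <- function(i, j, n) {
  (i - 1) * n - i * (i - 1) / 2 + (j - i)
}

# Population standard deviation (descriptive, not sample-corrected).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

stop_invalid <- function(msg, class) {
  abort(msg, class = c(class, "drembed_error"))
}
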