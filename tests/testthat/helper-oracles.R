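# Independent oracles and fixture builders used across the suite.

# Brute-force O(L^2) Sequence Graph Transform: a direct double loop over all
# position pairs, kept deliberately independent of the package's O(21 L)
# recurrence.
sgt_oracle <- function(sequence, kappa = 1, mode = "length_insensitive") {
  alpha <- aa_alphabet()
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(s)
  W <- matrix(0, 21, 21, dimnames = list(alpha, alpha))
  C <- matrix(0, 21, 21, dimnames = list(alpha, alpha))
  if (L >= 2) {
    for (i in 1:(L - 1)) {
      for (j in (i + 1):L) {
        W[s[i], s[j]] <- W[s[i], s[j]] + exp(-kappa * (j - i))
        C[s[i], s[j]] <- C[s[i], s[j]] + 1
      }
    }
  }
  Z <- if (mode == "length_insensitive") C else L
  f <- matrix(0, 21, 21)
  pos <- C > 0
  f[pos] <- (W[pos] / (if (is.matrix(Z)) Z[pos] else Z))^(1 / kappa)
  stats::setNames(as.vector(t(f)), sgt_feature_names())
}

# Random sanitized sequences over the full 21-symbol alphabet.
random_sequences <- function(n, min_len = 2, max_len = 30, seed = 42) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      L <- sample(min_len:max_len, 1)
      paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
    }, character(1))
  })
}

# Naive all-pairs cosine distances (double loop) for an embedding set.
naive_all_pair_distances <- function(embeddings) {
  m <- as.matrix(embeddings)
  ids <- embeddings$ids
  ord <- order(ids, method = "radix")
  m <- m[ord, , drop = FALSE]
  ids <- ids[ord]
  n <- length(ids)
  out <- list()
  k <- 1
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      out[[k]] <- tibble::tibble(
        id_a = ids[i], id_b = ids[j],
        distance = cosine_distance(m[i, ], m[j, ])
      )
      k <- k + 1
    }
  }
  dplyr::bind_rows(out)
}

pair_key <- function(id_a, id_b) paste(id_a, id_b, sep = "|")

write_tmp_tsv <- function(df, name, dir = tempdir()) {
  path <- file.path(dir, name)
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# Minimal association fixture: two drugs, two diseases, two DR cases; drug D2
# shares its target with disease X2 (case must be dropped).
micro_tables <- function() {
  association_tables(
    drug_targets = tibble::tibble(
      drug_id = c("D1", "D2"),
      protein_id = c("T1", "T2")
    ),
    disease_proteins = tibble::tibble(
      disease_id = c("X1", "X1", "X2", "X2"),
      protein_id = c("P1", "P2", "T2", "P3")
    ),
    dr_cases = tibble::tibble(
      drug_id = c("D1", "D2"),
      disease_id = c("X1", "X2"),
      source = c("repodb", "literature")
    )
  )
}

# Small deterministic embedding fixture from explicit compositions.
toy_embeddings <- function() {
  recs <- tibble::tibble(
    id = c("p1", "p2", "p3", "p4", "p5"),
    sequence = c("AAAA", "AACC", "CCCC", "WYWY", "ACDE")
  )
  embed_corpus(recs, "onehot_mean")
}
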