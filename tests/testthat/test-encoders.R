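test_that("one-hot encoding places a single 1 per position at the alphabet index", {
  m <- one_hot_encode("A")
  expect_equal(dim(m), c(1L, 21L))
  expect_equal(sum(m), 1)
  expect_equal(unname(m[1, "A"]), 1)

  m2 <- one_hot_encode("AC")
  expect_equal(rowSums(m2), c(1, 1))
  expect_equal(m2[, "A"], c(1, 0))
  expect_equal(m2[, "C"], c(0, 1))

  m3 <- one_hot_encode("AX")
  expect_equal(unname(m3[2, "X"]), 1)
  expect_error(one_hot_encode("AZ"), class = "drembed_encoding_error")
})

test_that("mean pooling averages positions and equals residue composition", {
  pooled <- mean_pool(one_hot_encode("AAC"))
  expect_equal(pooled[["A"]], 2 / 3)
  expect_equal(pooled[["C"]], 1 / 3)
  expect_equal(sum(pooled), 1)

  row <- one_hot_encode("W")
  expect_equal(mean_pool(row), row[1, ])
  expect_equal(mean_pool(matrix(1, 4, 3)), rep(1, 3))
  expect_error(mean_pool(matrix(numeric(0), 0, 21)), class = "drembed_encoding_error")

  # composition identity on random sequences
  for (s in random_sequences(100, seed = 5)) {
    comp <- table(factor(strsplit(s, "")[[1]], levels = aa_alphabet())) / nchar(s)
    expect_equal(unname(mean_pool(one_hot_encode(s))), as.vector(comp), tolerance = 0)
  }
})

test_that("sgt_encode matches hand-derived values and respects order", {
  v <- sgt_encode("AA", kappa = 1)
  expect_equal(v[["A>A"]], exp(-1))
  expect_equal(sum(v > 0), 1L)

  v2 <- sgt_encode("AC", kappa = 1)
  expect_equal(v2[["A>C"]], exp(-1))
  expect_equal(v2[["C>A"]], 0)

  v3 <- sgt_encode("AAA", kappa = 1)
  expect_equal(v3[["A>A"]], (2 * exp(-1) + exp(-2)) / 3)

  expect_warning(z <- sgt_encode("A"), "zero")
  expect_equal(sum(z), 0)
  expect_error(sgt_encode("AC", kappa = -1), class = "drembed_invalid_parameter")
})

test_that("sgt_encode agrees with the brute-force oracle across kappa and modes", {
  seqs <- random_sequences(60, min_len = 2, max_len = 30, seed = 123)
  for (kappa in c(0.5, 1, 5)) {
    for (mode in c("length_insensitive", "length_sensitive")) {
      for (s in seqs[1:20]) {
        expect_equal(
          unname(sgt_encode(s, kappa, mode)),
          unname(sgt_oracle(s, kappa, mode)),
          tolerance = 1e-9
        )
      }
    }
  }
})

test_that("SGT keeps order information that pooled one-hot discards", {
  expect_false(isTRUE(all.equal(sgt_encode("AC"), sgt_encode("CA"))))
  recs <- tibble::tibble(id = c("x", "y"), sequence = c("AC", "CA"))
  oh <- embed_corpus(recs, "onehot_mean")
  expect_equal(as.matrix(oh)[1, ], as.matrix(oh)[2, ])
})

test_that("feature(A,A) decays monotonically as spacer length grows", {
  vals <- vapply(1:6, function(k) {
    s <- paste0("A", strrep("C", k), "A")
    sgt_encode(s, kappa = 1)[["A>A"]]
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("embed_corpus aligns rows, declares widths, and is deterministic", {
  recs <- tibble::tibble(
    id = c("a", "b"),
    sequence = c("AAC", "WY")
  )
  oh <- embed_corpus(recs, "onehot_mean")
  expect_equal(dim(oh), c(2L, 21L))
  expect_equal(oh$ids, recs$id)
  expect_equal(rowSums(as.matrix(oh)), c(1, 1), ignore_attr = TRUE)
  expect_equal(oh$range_regime, "nonnegative")

  sg <- embed_corpus(recs, "sgt")
  expect_equal(ncol(sg), 441L)
  expect_true(all(as.matrix(sg) >= 0))

  none <- embed_corpus(recs[0, ], "sgt")
  expect_equal(dim(none), c(0L, 441L))

  twice <- embed_corpus(recs, "sgt")
  expect_identical(as.matrix(sg), as.matrix(twice))
})

test_that("external embeddings load with inferred width and strict validation", {
  tab <- tibble::tibble(
    id = c("p1", "p2", "p3"),
    f1 = c(0.1, -0.2, 0.3), f2 = c(1, 2, 3), f3 = c(0, 0, 1), f4 = c(-1, 1, 0)
  )
  path <- write_tmp_tsv(tab, "emb.tsv")
  es <- load_external_embeddings(path, "seqvec")
  expect_equal(es$method, "external:seqvec")
  expect_equal(dim(es), c(3L, 4L))
  expect_equal(es$range_regime, "signed")

  ragged <- tempfile(fileext = ".tsv")
  writeLines(c("id\tf1\tf2", "p1\t0.1\t0.2", "p2\t0.3"), ragged)
  expect_error(load_external_embeddings(ragged, "x"), class = "drembed_parse_error")

  empty <- write_tmp_tsv(tab[0, ], "emb_empty.tsv")
  expect_error(load_external_embeddings(empty, "x"), class = "drembed_parse_error")

  dup <- write_tmp_tsv(dplyr::bind_rows(tab, tab[1, ]), "emb_dup.tsv")
  expect_error(load_external_embeddings(dup, "x"), class = "drembed_duplicate_id")
})

test_that("embedding tables round-trip through write_embeddings", {
  recs <- tibble::tibble(id = c("a", "b", "c"), sequence = c("AAC", "WYWY", "ACDE"))
  es <- embed_corpus(recs, "onehot_mean")
  path <- file.path(tempdir(), "oh.tsv")
  write_embeddings(es, path)
  back <- load_external_embeddings(path, "roundtrip")
  expect_equal(back$ids, es$ids)
  expect_equal(unname(as.matrix(back)), unname(as.matrix(es)), tolerance = 1e-12)
})
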