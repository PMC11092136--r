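test_that("cosine distance matches the analytic cases and validates input", {
  expect_equal(cosine_distance(c(3, 1, 2), c(3, 1, 2)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 0), c(-1, 0)), 2)
  expect_error(cosine_distance(c(0, 0), c(1, 0)), class = "drembed_undefined_distance")
  expect_error(cosine_distance(c(1, 0), c(1, 0, 0)), class = "drembed_invalid_parameter")
})

test_that("cosine distance is symmetric and scale invariant", {
  withr::with_seed(99, {
    for (k in 1:25) {
      a <- stats::rnorm(8)
      b <- stats::rnorm(8)
      c_pos <- stats::rexp(1)
      expect_equal(cosine_distance(a, b), cosine_distance(b, a))
      expect_equal(cosine_distance(c_pos * a, b), cosine_distance(a, b), tolerance = 1e-12)
    }
  })
})

test_that("pair_distances computes requested pairs and skips unresolvable ones", {
  es <- toy_embeddings()
  pairs <- tibble::tibble(
    id_a = c("p1", "p1", "p2"),
    id_b = c("p2", "p3", "p3")
  )
  d <- pair_distances(es, pairs)
  expect_equal(nrow(d), 3)
  expect_true(all(d$distance >= 0 & d$distance <= 1))
  expect_equal(d$method, rep("onehot_mean", 3))

  # order-insensitive: swapped ids give the same canonical rows
  d_swapped <- pair_distances(es, tibble::tibble(id_a = pairs$id_b, id_b = pairs$id_a))
  expect_equal(d, d_swapped)

  expect_warning(
    d2 <- pair_distances(es, tibble::tibble(id_a = "p1", id_b = c("p2", "ghost"))),
    "skipped"
  )
  expect_equal(nrow(d2), 1)

  expect_error(
    pair_distances(es, tibble::tibble(id_a = "p1", id_b = "p1")),
    class = "drembed_invalid_records"
  )
})

test_that("background stream yields the exact pair universe minus exclusions", {
  es <- toy_embeddings() # 5 proteins -> 10 pairs
  all_bg <- background_distances(es)
  expect_equal(nrow(all_bg), 10)

  excl <- tibble::tibble(id_a = c("p1", "p3"), id_b = c("p2", "p4"))
  some <- background_distances(es, exclude = excl)
  expect_equal(nrow(some), 8)
  expect_false(any(pair_key(some$id_a, some$id_b) %in% pair_key(excl$id_a, excl$id_b)))

  capped <- background_distances(es, sample_cap = 100, seed = 1)
  expect_equal(nrow(capped), 10) # cap exceeds the universe
})

test_that("streamed distances equal the naive double loop, at any chunk size", {
  recs <- tibble::tibble(
    id = sprintf("q%03d", 1:60),
    sequence = random_sequences(60, min_len = 5, max_len = 40, seed = 21)
  )
  es <- embed_corpus(recs, "onehot_mean")
  naive <- naive_all_pair_distances(es)
  for (chunk in c(7, 1000, 100000)) {
    streamed <- background_distances(es, chunk_size = chunk)
    expect_equal(streamed$id_a, naive$id_a)
    expect_equal(streamed$id_b, naive$id_b)
    expect_equal(streamed$distance, naive$distance, tolerance = 1e-12)
  }
})

test_that("capped background sampling is uniform-sized, exclusion-free, reproducible", {
  recs <- tibble::tibble(
    id = sprintf("q%03d", 1:40),
    sequence = random_sequences(40, min_len = 5, max_len = 30, seed = 8)
  )
  es <- embed_corpus(recs, "onehot_mean")
  excl <- tibble::tibble(id_a = recs$id[1:5], id_b = recs$id[6:10])
  s1 <- background_distances(es, exclude = excl, sample_cap = 50, seed = 33)
  s2 <- background_distances(es, exclude = excl, sample_cap = 50, seed = 33)
  s3 <- background_distances(es, exclude = excl, sample_cap = 50, seed = 34)
  expect_equal(nrow(s1), 50)
  expect_identical(s1, s2)
  expect_false(identical(s1$id_a, s3$id_a) && identical(s1$id_b, s3$id_b))
  expect_false(any(pair_key(s1$id_a, s1$id_b) %in% pair_key(excl$id_a, excl$id_b)))
})

test_that("distance summaries report mean, population std, median per method", {
  d <- tibble::tibble(
    id_a = "a", id_b = "b",
    method = "m", distance = c(0.1, 0.3)
  )
  s <- summarize_distances(d)
  expect_equal(s$mean, 0.2)
  expect_equal(s$median, 0.2)

  single <- summarize_distances(tibble::tibble(method = "m", distance = 0.5))
  expect_equal(single$mean, 0.5)
  expect_equal(single$std, 0)

  both <- summarize_distances(tibble::tibble(method = "m", distance = c(0, 1)))
  expect_equal(both$std, 0.5) # population, not sample, standard deviation

  expect_error(summarize_distances(d[0, ]), class = "drembed_invalid_records")
})

test_that("nonnegative embeddings stay on [0,1], signed tables on [0,2]", {
  recs <- tibble::tibble(
    id = sprintf("r%02d", 1:12),
    sequence = random_sequences(12, min_len = 3, max_len = 25, seed = 17)
  )
  for (m in c("onehot_mean", "sgt")) {
    es <- embed_corpus(recs, m)
    d <- background_distances(es)
    expect_true(all(d$distance >= 0 & d$distance <= 1))
  }
  signed <- tibble::tibble(
    id = c("s1", "s2", "s3", "s4"),
    f1 = c(1, -1, 0.5, -0.2), f2 = c(0.1, -0.1, -3, 2)
  )
  path <- write_tmp_tsv(signed, "signed.tsv")
  es <- load_external_embeddings(path, "toy")
  d <- background_distances(es)
  expect_true(all(d$distance >= 0 & d$distance <= 2))
  expect_true(any(d$distance > 1)) # signed vectors do exceed the nonnegative bound
})
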