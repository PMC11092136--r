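test_that("class profiles are normalized, seeded, and flatten as concentration grows", {
  p <- make_class_profiles(3, concentration = 1, seed = 5)
  expect_equal(dim(p), c(3L, 21L))
  expect_equal(rowSums(p), rep(1, 3), ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(p >= 0))
  expect_identical(p, make_class_profiles(3, concentration = 1, seed = 5))
  flat <- make_class_profiles(3, concentration = 1e6, seed = 5)
  expect_lt(max(abs(flat - 1 / 21)), 0.01)
  expect_error(make_class_profiles(0, 1), class = "drembed_invalid_parameter")
})

test_that("sample_proteome draws class-typed proteins with requested lengths", {
  spec <- synthetic_spec(
    seed = 2, n_classes = 2, proteins_per_class = 10,
    length_range = c(50, 50), n_drugs = 5, n_diseases = 5, n_dr_cases = 5
  )
  prot <- sample_proteome(spec)
  expect_equal(nrow(prot$records), 20)
  expect_true(all(lengths(prot$records$classes) == 1))
  expect_true(all(prot$records$length == 50))
  expect_equal(sort(unique(prot$classes$class)), c("CLASS01", "CLASS02"))
})

test_that("class structure separates compositions: within-class closer than between", {
  spec <- synthetic_spec(seed = 4, n_classes = 3, proteins_per_class = 15,
                         n_drugs = 5, n_diseases = 5, n_dr_cases = 5)
  prot <- sample_proteome(spec)
  es <- embed_corpus(prot$records, "onehot_mean")
  d <- background_distances(es)
  cls <- stats::setNames(prot$classes$class, prot$classes$id)
  same <- cls[d$id_a] == cls[d$id_b]
  expect_lt(mean(d$distance[same]), mean(d$distance[!same]))
})

test_that("planted cases pair a target with its mutated copy at the requested divergence", {
  spec0 <- synthetic_spec(seed = 3, dr_divergence = 0, n_dr_cases = 5,
                          n_classes = 2, proteins_per_class = 10,
                          n_drugs = 5, n_diseases = 5)
  prot <- sample_proteome(spec0)
  planted <- plant_dr_cases(prot$records, spec0)
  expect_equal(nrow(planted$truth), 5)
  expect_equal(nrow(planted$tables$dr_cases), 5)
  # divergence 0: mutant sequence identical to its target, distance 0
  seqs <- stats::setNames(planted$records$sequence, planted$records$id)
  expect_identical(
    unname(seqs[planted$truth$disease_protein_id]),
    unname(seqs[planted$truth$target_id])
  )
  es <- embed_corpus(planted$records, "onehot_mean")
  d <- pair_distances(es, planted$truth[c("id_a", "id_b")])
  expect_equal(d$distance, rep(0, 5), tolerance = 1e-12)

  # the planted target never sits in its disease's protein set
  dp <- planted$tables$disease_proteins
  for (k in seq_len(nrow(planted$truth))) {
    expect_false(
      planted$truth$target_id[k] %in%
        dp$protein_id[dp$disease_id == planted$truth$disease_id[k]]
    )
  }
  # mutant disease proteins are unannotated
  mut <- planted$records[planted$records$id %in% planted$truth$disease_protein_id, ]
  expect_true(all(lengths(mut$classes) == 0))

  expect_error(
    synthetic_spec(dr_divergence = 1.5),
    class = "drembed_invalid_parameter"
  )
})

test_that("planted-pair distance grows monotonically with divergence", {
  means <- vapply(c(0, 0.05, 0.2, 1.0), function(div) {
    spec <- synthetic_spec(
      seed = 6, dr_divergence = div, n_dr_cases = 8,
      n_classes = 2, proteins_per_class = 15, n_drugs = 8, n_diseases = 8
    )
    prot <- sample_proteome(spec)
    planted <- plant_dr_cases(prot$records, spec)
    es <- embed_corpus(planted$records, "onehot_mean")
    mean(pair_distances(es, planted$truth[c("id_a", "id_b")])$distance)
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("generated bundles load end-to-end and regenerate bitwise-identically", {
  spec <- synthetic_spec(
    seed = 9, n_classes = 2, proteins_per_class = 8,
    n_drugs = 4, n_diseases = 4, n_dr_cases = 4
  )
  dir1 <- file.path(tempdir(), "synth1")
  dir2 <- file.path(tempdir(), "synth2")
  p1 <- suppressWarnings(generate_dataset(spec, dir1))
  p2 <- suppressWarnings(generate_dataset(spec, dir2))
  for (nm in names(p1)) {
    expect_identical(
      unname(tools::md5sum(p1[[nm]])), unname(tools::md5sum(p2[[nm]])),
      info = nm
    )
  }
  # bundle is consumable by the io layer
  recs <- read_fasta(p1$fasta)
  expect_equal(nrow(recs), 2 * 8 + 4) # proteome plus mutants
  ann <- read_class_annotations(p1$classes)
  tb <- association_tables(
    read_drug_targets(p1$drug_targets),
    read_disease_proteins(p1$disease_proteins),
    read_dr_cases(p1$dr_cases),
    records = recs
  )
  pairs <- suppressMessages(build_dr_pairs(tb))
  expect_gt(nrow(pairs), 0)
  truth <- readr::read_tsv(p1$truth, show_col_types = FALSE)
  expect_true(all(pair_key(truth$id_a, truth$id_b) %in% pair_key(pairs$id_a, pairs$id_b)))
})

test_that("long-sequence specs exercise the length filter downstream", {
  spec <- synthetic_spec(
    seed = 12, n_classes = 1, proteins_per_class = 30,
    length_range = c(5000, 7000), n_drugs = 3, n_diseases = 3, n_dr_cases = 3
  )
  prot <- sample_proteome(spec)
  flt <- filter_by_length(prot$records)
  expect_gt(nrow(flt$discarded), 0)
  expect_gt(nrow(flt$kept), 0)
  expect_true(all(flt$discarded$length > 6024))
})
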