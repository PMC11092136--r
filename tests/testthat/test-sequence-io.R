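test_that("sanitize_sequence normalizes case, maps non-canonical symbols, is idempotent", {
  expect_equal(sanitize_sequence("acdef"), "ACDEF")
  expect_equal(sanitize_sequence("ACUZ"), "ACXX")
  expect_equal(sanitize_sequence("AC-D*B.Z"), "ACXDXXXX")
  expect_equal(sanitize_sequence(" AC\nDE "), "ACDE")
  expect_error(sanitize_sequence(""), class = "drembed_invalid_sequence")
  expect_error(sanitize_sequence("  \t"), class = "drembed_invalid_sequence")
  expect_error(sanitize_sequence("AC1D"), class = "drembed_invalid_sequence")
  seqs <- random_sequences(50, seed = 7)
  expect_identical(sanitize_sequence(sanitize_sequence(seqs)), sanitize_sequence(seqs))
})

test_that("read_fasta parses records, strips descriptions, rejects duplicates", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "acd", ">P2", "WY"), fa)
  recs <- read_fasta(fa)
  expect_equal(recs$id, c("P1", "P2"))
  expect_equal(recs$sequence, c("ACD", "WY"))
  expect_equal(recs$length, c(3L, 2L))

  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">P1", "ACD", ">P1", "WY"), dup)
  expect_error(read_fasta(dup), "P1", class = "drembed_duplicate_id")

  bad <- tempfile(fileext = ".fasta")
  writeLines(c("ACD", ">P1", "WY"), bad)
  expect_error(read_fasta(bad), class = "drembed_parse_error")

  expect_error(read_fasta(tempfile()), class = "drembed_io_error")
})

test_that("FASTA writing round-trips, plain and gzipped", {
  recs <- tibble::tibble(
    id = c("A1", "B2", "C3"),
    sequence = sanitize_sequence(random_sequences(3, min_len = 10, max_len = 200, seed = 3))
  )
  for (ext in c(".fasta", ".fasta.gz")) {
    path <- tempfile(fileext = ext)
    write_fasta(recs, path)
    back <- read_fasta(path)
    expect_equal(back$id, recs$id)
    expect_equal(back$sequence, recs$sequence)
  }
})

test_that("filter_by_length keeps the 6024 boundary and partitions any input", {
  recs <- tibble::tibble(
    id = c("short", "boundary", "over"),
    sequence = c(strrep("A", 16), strrep("A", 6024), strrep("A", 6025))
  )
  flt <- filter_by_length(recs)
  expect_setequal(flt$kept$id, c("short", "boundary"))
  expect_equal(flt$discarded$id, "over")

  empty <- recs[0, ]
  flt0 <- filter_by_length(empty)
  expect_equal(nrow(flt0$kept), 0)
  expect_equal(nrow(flt0$discarded), 0)

  small <- tibble::tibble(id = c("a", "b"), sequence = c(strrep("A", 10), strrep("C", 20)))
  flt2 <- filter_by_length(small, max_len = 5)
  expect_equal(nrow(flt2$kept), 0)
  expect_setequal(flt2$discarded$id, c("a", "b"))

  # partition property across random cut-offs
  recs2 <- tibble::tibble(
    id = paste0("r", 1:30),
    sequence = random_sequences(30, min_len = 2, max_len = 60, seed = 11)
  )
  for (cut in c(1, 5, 30, 100)) {
    f <- filter_by_length(recs2, cut)
    expect_setequal(c(f$kept$id, f$discarded$id), recs2$id)
    expect_length(intersect(f$kept$id, f$discarded$id), 0)
  }
  expect_error(filter_by_length(recs2, 0), class = "drembed_invalid_parameter")
})

test_that("class annotations read with set semantics and select_single_class filters", {
  path <- write_tmp_tsv(
    tibble::tibble(
      id = c("P1", "P1", "P2", "P1"),
      class = c("kinase", "ligase", "kinase", "kinase")
    ),
    "classes.tsv"
  )
  ann <- read_class_annotations(path)
  expect_equal(nrow(ann), 3) # duplicate (P1, kinase) collapsed
  expect_setequal(ann$class[ann$id == "P1"], c("kinase", "ligase"))

  empty <- write_tmp_tsv(tibble::tibble(id = character(), class = character()), "empty.tsv")
  expect_equal(nrow(read_class_annotations(empty)), 0)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("id\tclass", "P1\tkinase\textra", "P2\tligase"), bad)
  expect_error(read_class_annotations(bad), "line", class = "drembed_parse_error")

  recs <- tibble::tibble(
    id = c("P1", "P2", "P3"),
    sequence = c("ACD", "ACD", "ACD")
  )
  annotated <- annotate_classes(recs, ann)
  expect_equal(lengths(annotated$classes), c(2L, 1L, 0L))
  single <- select_single_class(annotated)
  expect_equal(single$id, "P2")

  none <- annotate_classes(recs, ann[0, ])
  expect_equal(nrow(select_single_class(none)), 0)
  all_single <- annotate_classes(recs, tibble::tibble(
    id = c("P1", "P2", "P3"), class = "kinase"
  ))
  expect_equal(select_single_class(all_single)$id, recs$id)
})

test_that("association tables validate uniqueness and report unresolved ids", {
  tb <- micro_tables()
  expect_s3_class(tb, "association_tables")
  expect_error(
    association_tables(
      tb$drug_targets, tb$disease_proteins,
      dplyr::bind_rows(tb$dr_cases, tb$dr_cases[1, ])
    ),
    class = "drembed_invalid_records"
  )
  recs <- tibble::tibble(id = c("T1", "P1"), sequence = c("ACD", "ACD"))
  expect_warning(
    association_tables(tb$drug_targets, tb$disease_proteins, tb$dr_cases, records = recs),
    "no sequence record"
  )
})

test_that("dr_cases reader validates sources and gzipped tables load", {
  ok <- write_tmp_tsv(
    tibble::tibble(drug_id = "D1", disease_id = "X1", source = "repodb"),
    "cases.tsv"
  )
  expect_equal(read_dr_cases(ok)$source, "repodb")
  bad <- write_tmp_tsv(
    tibble::tibble(drug_id = "D1", disease_id = "X1", source = "guesswork"),
    "cases_bad.tsv"
  )
  expect_error(read_dr_cases(bad), class = "drembed_parse_error")

  gz <- file.path(tempdir(), "targets.tsv.gz")
  readr::write_tsv(
    tibble::tibble(drug_id = "D1", protein_id = "T1"), gz,
    progress = FALSE
  )
  expect_equal(read_drug_targets(gz)$protein_id, "T1")
})
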