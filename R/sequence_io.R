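# Reading, sanitizing, filtering and annotating protein sequences and the
# pipeline's association tables. FASTA handling is delegated to Biostrings;
# delimited tables are tab-separated with a header row and '#' comments, plain
# or gzip-compressed.

#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly gzip-compressed) FASTA file into a protein-record tibble.
#' The record id is the first whitespace-delimited token of the header line;
#' sequences are passed through [sanitize_sequence()].
#'
#' @param path Path to a FASTA file (`.fasta`, `.fa`, optionally `.gz`).
#' @return A tibble with columns `id`, `sequence`, `length`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 desc", "acd", ">P2", "WY"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop_invalid(paste0("FASTA file not found: ", path), "drembed_io_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) {
      stop_invalid(
        paste0("Malformed FASTA in ", path, ": ", conditionMessage(e)),
        "drembed_parse_error"
      )
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop_invalid(
      paste0(
        "Duplicate record ids in ", path, ": ",
        paste(dups, collapse = ", ")
      ),
      "drembed_duplicate_id"
    )
  }
  seqs <- unname(sanitize_sequence(as.character(set)))
  tibble(id = ids, sequence = seqs, length = nchar(seqs))
}

#' Write protein records to a FASTA file
#'
#' @param records Protein-record tibble with `id` and `sequence` columns.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  check_records(records)
  set <- Biostrings::BStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(
    set, path,
    compress = grepl("\\.gz$", path), width = 60L
  )
  invisible(path)
}

check_records <- function(records, need_classes = FALSE) {
  if (!is.data.frame(records) ||
    !all(c("id", "sequence") %in% names(records))) {
    stop_invalid(
      "`records` must be a data frame with `id` and `sequence` columns.",
      "drembed_invalid_records"
    )
  }
  if (anyDuplicated(records$id)) {
    stop_invalid("Protein ids must be unique.", "drembed_duplicate_id")
  }
  if (need_classes && !"classes" %in% names(records)) {
    stop_invalid(
      "`records` must carry a `classes` list-column; see annotate_classes().",
      "drembed_invalid_records"
    )
  }
  invisible(records)
}

#' Partition protein records by sequence length
#'
#' Very long sequences are dropped before embedding: the default cut-off keeps
#' sequences of up to 6,024 residues and discards strictly longer ones (the
#' boundary itself is kept).
#'
#' @param records Protein-record tibble (see [read_fasta()]).
#' @param max_len Maximum length kept (default 6024).
#' @return A list with tibbles `kept` and `discarded`; together they partition
#'   the input.
#' @examples
#' recs <- tibble::tibble(id = c("a", "b"), sequence = c("ACD", "WYACD"))
#' filter_by_length(recs, max_len = 3)
#' @export
filter_by_length <- function(records, max_len = 6024) {
  check_records(records)
  if (!is.numeric(max_len) || length(max_len) != 1 || max_len < 1) {
    stop_invalid("`max_len` must be a single integer >= 1.", "drembed_invalid_parameter")
  }
  len <- nchar(records$sequence)
  list(
    kept = records[len <= max_len, , drop = FALSE],
    discarded = records[len > max_len, , drop = FALSE]
  )
}

read_table_checked <- function(path, n_cols, col_names, what) {
  if (!file.exists(path)) {
    stop_invalid(paste0(what, " table not found: ", path), "drembed_io_error")
  }
  df <- withr::with_options(
    list(readr.show_col_types = FALSE, readr.show_progress = FALSE),
    suppressWarnings(readr::read_tsv(
      path,
      comment = "#", col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    ))
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop_invalid(
      paste0(
        "Malformed ", what, " table ", path, " at line(s) ",
        paste(unique(probs$row + 1), collapse = ", "),
        " (expected ", n_cols, " tab-separated columns)."
      ),
      "drembed_parse_error"
    )
  }
  if (ncol(df) != n_cols) {
    stop_invalid(
      paste0(
        "Malformed ", what, " table ", path, ": expected ", n_cols,
        " columns, found ", ncol(df), "."
      ),
      "drembed_parse_error"
    )
  }
  stats::setNames(df, col_names)
}

#' Read protein functional-class annotations
#'
#' Reads a two-column tab-separated table (protein id, class label; header row,
#' `#` comments) into a tidy annotation tibble. Duplicate (id, class) rows are
#' collapsed (set semantics). Proteins absent from the table are treated
#' downstream as unannotated (empty class set).
#'
#' @param path Path to the annotation TSV (optionally gzipped).
#' @return A tibble with columns `id`, `class`, one row per association.
#' @export
read_class_annotations <- function(path) {
  df <- read_table_checked(path, 2, c("id", "class"), "class-annotation")
  distinct(df)
}

#' Attach class annotations to protein records
#'
#' Adds a `classes` list-column holding each protein's set of functional-class
#' labels (a character vector, empty for unannotated proteins).
#'
#' @param records Protein-record tibble.
#' @param classes Annotation tibble from [read_class_annotations()].
#' @return `records` with a `classes` list-column.
#' @export
annotate_classes <- function(records, classes) {
  check_records(records)
  stopifnot(all(c("id", "class") %in% names(classes)))
  sets <- split(classes$class, classes$id)
  records$classes <- lapply(records$id, function(i) {
    unique(sets[[i]]) %||% character(0)
  })
  records
}

#' Select proteins annotated with exactly one functional class
#'
#' Visualisation of the embedding space is restricted to proteins associated
#' exclusively with a single functional class, so each point has one
#' unambiguous colour.
#'
#' @param records Protein-record tibble with a `classes` list-column.
#' @return The subset of `records` with exactly one class label.
#' @export
select_single_class <- function(records) {
  check_records(records, need_classes = TRUE)
  records[lengths(records$classes) == 1L, , drop = FALSE]
}

#' Read drug-to-target associations
#'
#' @param path Two-column TSV (drug id, target protein id).
#' @return Tibble with columns `drug_id`, `protein_id`.
#' @export
read_drug_targets <- function(path) {
  distinct(read_table_checked(path, 2, c("drug_id", "protein_id"), "drug-target"))
}

#' Read disease-to-protein associations
#'
#' @param path Two-column TSV (disease id, protein id).
#' @return Tibble with columns `disease_id`, `protein_id`.
#' @export
read_disease_proteins <- function(path) {
  distinct(read_table_checked(path, 2, c("disease_id", "protein_id"), "disease-protein"))
}

#' Read drug-repurposing cases
#'
#' Each row records a successful repurposing event: a drug, the new disease it
#' was repurposed to, and the evidence source (`repodb` or `literature`).
#'
#' @param path Three-column TSV (drug id, disease id, source).
#' @return Tibble with columns `drug_id`, `disease_id`, `source`.
#' @export
read_dr_cases <- function(path) {
  df <- read_table_checked(path, 3, c("drug_id", "disease_id", "source"), "DR-case")
  bad <- setdiff(unique(df$source), c("repodb", "literature"))
  if (length(bad) > 0) {
    stop_invalid(
      paste0(
        "Unknown DR-case source(s): ", paste(bad, collapse = ", "),
        " (expected 'repodb' or 'literature')."
      ),
      "drembed_parse_error"
    )
  }
  if (anyDuplicated(df)) {
    warn("Duplicate (drug, disease, source) triples found; keeping one of each.")
    df <- distinct(df)
  }
  df
}

#' Bundle association tables
#'
#' Validates and bundles the three association tables the repurposing analysis
#' consumes. When `records` is supplied, protein ids that do not resolve to a
#' sequence record are reported with a warning (they are skipped later, at
#' distance time, not here).
#'
#' @param drug_targets Tibble from [read_drug_targets()].
#' @param disease_proteins Tibble from [read_disease_proteins()].
#' @param dr_cases Tibble from [read_dr_cases()].
#' @param records Optional protein-record tibble used to check id resolution.
#' @return An object of class `association_tables` (a named list of the three
#'   tibbles).
#' @export
association_tables <- function(drug_targets, disease_proteins, dr_cases,
                               records = NULL) {
  stopifnot(
    all(c("drug_id", "protein_id") %in% names(drug_targets)),
    all(c("disease_id", "protein_id") %in% names(disease_proteins)),
    all(c("drug_id", "disease_id", "source") %in% names(dr_cases))
  )
  if (anyDuplicated(dr_cases[c("drug_id", "disease_id", "source")])) {
    stop_invalid(
      "(drug, disease, source) triples must be unique.",
      "drembed_invalid_records"
    )
  }
  if (!is.null(records)) {
    referenced <- unique(c(drug_targets$protein_id, disease_proteins$protein_id))
    unresolved <- setdiff(referenced, records$id)
    if (length(unresolved) > 0) {
      warn(paste0(
        length(unresolved), " protein id(s) in the association tables have no ",
        "sequence record and will be skipped: ",
        paste(head(unresolved, 5), collapse = ", "),
        if (length(unresolved) > 5) ", ..." else ""
      ))
    }
  }
  structure(
    list(
      drug_targets = as_tibble(drug_targets),
      disease_proteins = as_tibble(disease_proteins),
      dr_cases = as_tibble(dr_cases)
    ),
    class = "association_tables"
  )
}

#' @export
print.association_tables <- function(x, ...) {
  cat(
    "<association_tables>\n",
    " drug-target rows:     ", nrow(x$drug_targets), "\n",
    " disease-protein rows: ", nrow(x$disease_proteins), "\n",
    " DR cases:             ", nrow(x$dr_cases),
    " (", paste(unique(x$dr_cases$source), collapse = ", "), ")\n",
    sep = ""
  )
  invisible(x)
}
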