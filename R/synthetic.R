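# Self-contained synthetic studies: a proteome with class-specific residue
# composition, association tables, and planted repurposing cases whose two
# members are sequence copies at a controlled per-site divergence. The
# generator emulates the statistical structure the analysis assumes -- classes
# that differ in composition (so composition embeddings separate them) and
# repurposing pairs that are more similar in sequence than background pairs --
# with `dr_divergence` as the effect-size dial (0 = identical pair members,
# 1 = every site substituted, no planted effect).

#' Parameterize a synthetic study
#'
#' @param seed Master integer seed; every random choice in the generated study
#'   derives from it.
#' @param n_classes Number of functional classes.
#' @param proteins_per_class Proteins sampled per class.
#' @param length_range Integer `(min, max)` sequence lengths, sampled
#'   uniformly; `min >= 2`.
#' @param class_concentration Dirichlet concentration of the per-class residue
#'   composition profiles; lower values give sharper, more distinct profiles,
#'   large values approach the uniform composition.
#' @param n_drugs,n_diseases Number of drugs/diseases in the association
#'   tables (at least `n_dr_cases`; the surplus gets random associations when
#'   `background_noise` is on).
#' @param n_dr_cases Number of planted repurposing cases.
#' @param dr_divergence Per-site substitution probability between a planted
#'   pair's two sequences, in `[0, 1]`.
#' @param n_decoys_per_disease Random decoy proteins attached to each planted
#'   disease (only with `background_noise`).
#' @param background_noise Add decoy disease proteins and random associations
#'   for the surplus drugs/diseases, as in real many-to-many tables.
#' @return A validated `synthetic_spec` object (named list).
#' @export
synthetic_spec <- function(seed = 1L,
                           n_classes = 5,
                           proteins_per_class = 50,
                           length_range = c(100L, 400L),
                           class_concentration = 1,
                           n_drugs = 20,
                           n_diseases = 20,
                           n_dr_cases = 20,
                           dr_divergence = 0.05,
                           n_decoys_per_disease = 3,
                           background_noise = TRUE) {
  spec <- list(
    seed = as.integer(seed), n_classes = as.integer(n_classes),
    proteins_per_class = as.integer(proteins_per_class),
    length_range = as.integer(length_range),
    class_concentration = class_concentration,
    n_drugs = as.integer(n_drugs), n_diseases = as.integer(n_diseases),
    n_dr_cases = as.integer(n_dr_cases),
    dr_divergence = dr_divergence,
    n_decoys_per_disease = as.integer(n_decoys_per_disease),
    background_noise = isTRUE(background_noise)
  )
  with(spec, {
    if (n_classes < 1 || proteins_per_class < 1) {
      stop_invalid("Need n_classes >= 1 and proteins_per_class >= 1.", "drembed_invalid_parameter")
    }
    if (length(length_range) != 2 || length_range[1] < 2 ||
      length_range[2] < length_range[1]) {
      stop_invalid("`length_range` must be (min >= 2, max >= min).", "drembed_invalid_parameter")
    }
    if (class_concentration <= 0) {
      stop_invalid("`class_concentration` must be > 0.", "drembed_invalid_parameter")
    }
    if (dr_divergence < 0 || dr_divergence > 1) {
      stop_invalid("`dr_divergence` must be in [0, 1].", "drembed_invalid_parameter")
    }
    if (n_dr_cases < 1 || n_drugs < n_dr_cases || n_diseases < n_dr_cases) {
      stop_invalid("Need n_drugs >= n_dr_cases >= 1 and n_diseases >= n_dr_cases.", "drembed_invalid_parameter")
    }
    if (n_classes * proteins_per_class < n_dr_cases + n_decoys_per_disease + 1) {
      stop_invalid("Proteome too small for the requested cases and decoys.", "drembed_invalid_parameter")
    }
  })
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec>\n")
  for (nm in names(x)) {
    cat("  ", nm, ": ", paste(x[[nm]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Draw per-class residue-composition profiles
#'
#' Profiles are symmetric-Dirichlet draws over the 21-symbol alphabet
#' (generated as normalized gamma variates). Lower `concentration` gives
#' sharper, more distinct profiles; as `concentration` grows, profiles
#' approach the uniform composition.
#'
#' @param n_classes Number of profiles.
#' @param concentration Positive Dirichlet concentration.
#' @param seed Integer seed.
#' @return A `n_classes x 21` matrix of probability vectors, rows named
#'   `CLASS01, ...`, columns by [aa_alphabet()].
#' @export
make_class_profiles <- function(n_classes, concentration, seed = 1L) {
  if (n_classes < 1 || concentration <= 0) {
    stop_invalid("Need n_classes >= 1 and concentration > 0.", "drembed_invalid_parameter")
  }
  alpha <- aa_alphabet()
  withr::with_seed(substream_seed(seed, "class-profiles"), {
    g <- matrix(rgamma(n_classes * length(alpha), shape = concentration),
      nrow = n_classes
    )
    profiles <- g / rowSums(g)
    dimnames(profiles) <- list(sprintf("CLASS%02d", seq_len(n_classes)), alpha)
    profiles
  })
}

#' Sample a synthetic proteome
#'
#' Each protein's residues are drawn i.i.d. from its class profile; lengths are
#' uniform on `length_range`; each protein is annotated with exactly its
#' generating class.
#'
#' @param spec A `synthetic_spec`.
#' @return A list: `records` (protein tibble with a `classes` list-column),
#'   `classes` (tidy annotation tibble), `profiles` (the class profile matrix).
#' @export
sample_proteome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  profiles <- make_class_profiles(
    spec$n_classes, spec$class_concentration, spec$seed
  )
  alpha <- aa_alphabet()
  n <- spec$n_classes * spec$proteins_per_class
  withr::with_seed(substream_seed(spec$seed, "proteome"), {
    class_of <- rep(rownames(profiles), each = spec$proteins_per_class)
    len_pool <- seq(spec$length_range[1], spec$length_range[2])
    lens <- len_pool[sample.int(length(len_pool), n, replace = TRUE)]
    seqs <- vapply(seq_len(n), function(i) {
      paste(
        sample(alpha, lens[i], replace = TRUE, prob = profiles[class_of[i], ]),
        collapse = ""
      )
    }, character(1))
  })
  ids <- sprintf("SYNP%06d", seq_len(n))
  classes <- tibble(id = ids, class = class_of)
  records <- annotate_classes(
    tibble(id = ids, sequence = seqs, length = nchar(seqs)), classes
  )
  list(records = records, classes = classes, profiles = profiles)
}

mutate_sequence <- function(sequence, divergence) {
  if (divergence == 0) {
    return(sequence)
  }
  alpha <- aa_alphabet()
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < divergence
  if (any(hit)) {
    chars[hit] <- vapply(
      chars[hit],
      function(a) sample(setdiff(alpha, a), 1),
      character(1),
      USE.NAMES = FALSE
    )
  }
  paste(chars, collapse = "")
}

#' Plant repurposing cases into a synthetic proteome
#'
#' For each case, picks a distinct target protein T, creates a disease protein
#' P as a copy of T with per-site substitution probability `dr_divergence`
#' (substitutes uniform over the other 20 symbols), and registers
#' drug -> \{T\}, disease -> \{P, decoys\}, and the (drug, disease, source) case,
#' alternating sources between `repodb` and `literature`. T is never placed in
#' the disease's protein set, so planted cases survive the shared-target
#' exclusion. Mutant disease proteins carry no class annotation. With
#' `background_noise`, surplus drugs and diseases get random associations.
#'
#' @param records Protein-record tibble from [sample_proteome()].
#' @param spec The `synthetic_spec`.
#' @return A list: `records` (input plus the mutant disease proteins),
#'   `tables` (an `association_tables`), `truth` (tibble of planted pairs with
#'   canonical `id_a`, `id_b`, plus case bookkeeping).
#' @export
plant_dr_cases <- function(records, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  check_records(records)
  n_cases <- spec$n_dr_cases
  withr::with_seed(substream_seed(spec$seed, "plant-dr"), {
    target_ids <- sample(records$id, n_cases)
    mutant_seqs <- vapply(seq_len(n_cases), function(k) {
      t_seq <- records$sequence[records$id == target_ids[k]]
      mutate_sequence(t_seq, spec$dr_divergence)
    }, character(1))
    mutant_ids <- sprintf("SYNM%04d", seq_len(n_cases))
    drug_ids <- sprintf("SYNDRUG%03d", seq_len(spec$n_drugs))
    disease_ids <- sprintf("SYNDIS%03d", seq_len(spec$n_diseases))
    sources <- rep(c("repodb", "literature"), length.out = n_cases)

    drug_targets <- tibble(drug_id = drug_ids[seq_len(n_cases)], protein_id = target_ids)
    disease_proteins <- tibble(
      disease_id = disease_ids[seq_len(n_cases)], protein_id = mutant_ids
    )
    if (spec$background_noise && spec$n_decoys_per_disease > 0) {
      decoys <- lapply(seq_len(n_cases), function(k) {
        pool <- setdiff(records$id, target_ids[k])
        tibble(
          disease_id = disease_ids[k],
          protein_id = sample(pool, spec$n_decoys_per_disease)
        )
      })
      disease_proteins <- bind_rows(disease_proteins, bind_rows(decoys))
    }
    if (spec$background_noise) {
      extra_drugs <- setdiff(drug_ids, drug_ids[seq_len(n_cases)])
      if (length(extra_drugs) > 0) {
        drug_targets <- bind_rows(drug_targets, tibble(
          drug_id = rep(extra_drugs, each = 2),
          protein_id = sample(records$id, 2 * length(extra_drugs), replace = TRUE)
        ))
      }
      extra_dis <- setdiff(disease_ids, disease_ids[seq_len(n_cases)])
      if (length(extra_dis) > 0) {
        disease_proteins <- bind_rows(disease_proteins, tibble(
          disease_id = rep(extra_dis, each = 3),
          protein_id = sample(records$id, 3 * length(extra_dis), replace = TRUE)
        ))
      }
    }
  })
  mutants <- tibble(
    id = mutant_ids, sequence = mutant_seqs, length = nchar(mutant_seqs),
    classes = rep(list(character(0)), n_cases)
  )
  if (!"classes" %in% names(records)) {
    records$classes <- rep(list(character(0)), nrow(records))
  }
  all_records <- bind_rows(records, mutants)
  dr_cases <- tibble(
    drug_id = drug_ids[seq_len(n_cases)],
    disease_id = disease_ids[seq_len(n_cases)],
    source = sources
  )
  canon <- canonical_pairs(mutant_ids, target_ids)
  truth <- tibble(
    id_a = canon$id_a, id_b = canon$id_b,
    disease_protein_id = mutant_ids, target_id = target_ids,
    drug_id = dr_cases$drug_id, disease_id = dr_cases$disease_id,
    source = sources, divergence = spec$dr_divergence
  )
  tables <- association_tables(
    distinct(drug_targets), distinct(disease_proteins), dr_cases,
    records = all_records
  )
  list(records = all_records, tables = tables, truth = truth)
}

#' Generate a synthetic study as a file bundle
#'
#' Writes the full study -- FASTA proteome (originals plus mutant disease
#' proteins), class annotations, association tables, the planted-pair truth
#' table, and the serialized spec -- into `dir`. Regeneration under the same
#' spec is bitwise-identical. The truth table is for evaluation only and is not
#' a pipeline input.
#'
#' @param spec A `synthetic_spec`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
generate_dataset <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prot <- sample_proteome(spec)
  planted <- plant_dr_cases(prot$records, spec)
  paths <- list(
    fasta = file.path(dir, "proteome.fasta"),
    classes = file.path(dir, "classes.tsv"),
    drug_targets = file.path(dir, "drug_targets.tsv"),
    disease_proteins = file.path(dir, "disease_proteins.tsv"),
    dr_cases = file.path(dir, "dr_cases.tsv"),
    truth = file.path(dir, "truth.tsv"),
    spec = file.path(dir, "spec.json")
  )
  write_fasta(planted$records, paths$fasta)
  readr::write_tsv(prot$classes, paths$classes, progress = FALSE)
  readr::write_tsv(planted$tables$drug_targets, paths$drug_targets, progress = FALSE)
  readr::write_tsv(planted$tables$disease_proteins, paths$disease_proteins, progress = FALSE)
  readr::write_tsv(planted$tables$dr_cases, paths$dr_cases, progress = FALSE)
  readr::write_tsv(planted$truth, paths$truth, progress = FALSE)
  jsonlite::write_json(
    unclass(spec), paths$spec,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(paths)
}
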