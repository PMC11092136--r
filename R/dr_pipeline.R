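# Construction of repurposing pair sets, the shared-class filter, and
# below-mean consensus candidate calling. A pair table is a tibble of
# canonicalized unordered protein-id pairs with a label ("repurposing" or
# "background") and, for repurposing pairs, an evidence source.

#' Validate a pair table
#'
#' Checks the pair-table contract: canonical id order, no self pairs, no
#' duplicate pairs within a label/source stratum, and `source = "none"` for
#' background pairs.
#'
#' @param pairs Data frame with columns `id_a`, `id_b`, `label`, `source`.
#' @return `pairs` as a tibble, invisibly usable downstream.
#' @export
validate_pair_table <- function(pairs) {
  stopifnot(all(c("id_a", "id_b", "label", "source") %in% names(pairs)))
  pairs <- as_tibble(pairs)
  if (any(pairs$id_a == pairs$id_b)) {
    stop_invalid("Pair table contains self-pairs.", "drembed_invalid_records")
  }
  canon <- canonical_pairs(pairs$id_a, pairs$id_b)
  if (any(canon$id_a != pairs$id_a)) {
    stop_invalid("Pair ids must be in canonical (lexicographic) order.", "drembed_invalid_records")
  }
  if (!all(pairs$label %in% c("repurposing", "background"))) {
    stop_invalid("Pair labels must be 'repurposing' or 'background'.", "drembed_invalid_records")
  }
  if (any(pairs$label == "background" & pairs$source != "none")) {
    stop_invalid("Background pairs must have source 'none'.", "drembed_invalid_records")
  }
  if (anyDuplicated(pairs[c("id_a", "id_b", "label", "source")])) {
    stop_invalid("Duplicate pairs within a label/source stratum.", "drembed_invalid_records")
  }
  pairs
}

#' Build repurposing protein pairs from association tables
#'
#' For every repurposing case (drug, new disease, source), pairs each protein
#' associated with the new disease with each target of the drug. Cases where
#' the drug and the disease share a target protein are dropped entirely: in
#' such cases the repurposing is explained by the shared target itself, not by
#' target similarity, which is what the analysis is after. Cases whose drug has
#' no targets or whose disease has no proteins are skipped with a message.
#' Pairs are canonicalized and deduplicated within each source.
#'
#' @param tables An `association_tables` object.
#' @return A repurposing pair table (tibble with `id_a`, `id_b`,
#'   `label = "repurposing"`, `source`).
#' @export
build_dr_pairs <- function(tables) {
  stopifnot(inherits(tables, "association_tables"))
  targets_by_drug <- split(tables$drug_targets$protein_id, tables$drug_targets$drug_id)
  prots_by_disease <- split(
    tables$disease_proteins$protein_id, tables$disease_proteins$disease_id
  )
  cases <- tables$dr_cases
  if (nrow(cases) == 0) {
    stop_invalid("No DR cases to build pairs from.", "drembed_invalid_records")
  }
  n_skipped <- 0L
  n_shared <- 0L
  out <- vector("list", nrow(cases))
  for (k in seq_len(nrow(cases))) {
    tg <- unique(targets_by_drug[[cases$drug_id[k]]])
    dp <- unique(prots_by_disease[[cases$disease_id[k]]])
    if (length(tg) == 0 || length(dp) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (length(intersect(tg, dp)) > 0) {
      n_shared <- n_shared + 1L
      next
    }
    grid <- tidyr::expand_grid(disease_protein = dp, target = tg)
    grid <- grid[grid$disease_protein != grid$target, , drop = FALSE]
    if (nrow(grid) == 0) next
    canon <- canonical_pairs(grid$disease_protein, grid$target)
    out[[k]] <- tibble(
      id_a = canon$id_a, id_b = canon$id_b,
      label = "repurposing", source = cases$source[k]
    )
  }
  if (n_skipped > 0) {
    inform(paste0(n_skipped, " DR case(s) skipped (drug without targets or disease without proteins)."))
  }
  if (n_shared > 0) {
    inform(paste0(n_shared, " DR case(s) dropped (drug and disease share a target protein)."))
  }
  pairs <- distinct(dplyr::bind_rows(out))
  if (nrow(pairs) == 0) {
    stop_invalid("No repurposing pairs could be built.", "drembed_invalid_records")
  }
  validate_pair_table(pairs)
}

#' Remove pairs whose proteins share a functional class
#'
#' Keeps pairs whose class-label sets are disjoint. Pairs with one or both
#' members unannotated are kept (an empty set is disjoint from everything):
#' proteins of the same family score similar trivially, so shared-class pairs
#' add no repurposing insight. Idempotent.
#'
#' @param pairs A pair table.
#' @param classes Annotation tibble (`id`, `class`), e.g. from
#'   [read_class_annotations()].
#' @return The filtered pair table.
#' @export
filter_shared_class <- function(pairs, classes) {
  stopifnot(all(c("id_a", "id_b") %in% names(pairs)))
  stopifnot(all(c("id", "class") %in% names(classes)))
  if (nrow(pairs) == 0 || nrow(classes) == 0) {
    return(as_tibble(pairs))
  }
  shared <- pairs |>
    inner_join(classes, by = c(id_a = "id"), relationship = "many-to-many") |>
    semi_join(classes, by = c(id_b = "id", class = "class"))
  anti_join(as_tibble(pairs), shared, by = c("id_a", "id_b"))
}

#' Call below-mean consensus candidates
#'
#' For each pair with a distance under every summarized method, flags the
#' methods where the pair's distance is strictly below that method's mean
#' distance, and counts the consensus across methods. Pairs missing a method's
#' distance are excluded with a message. The result is sorted by descending
#' consensus count, then by ascending mean distance.
#'
#' @param records Long distance tibble (`id_a`, `id_b`, `method`, `distance`)
#'   covering the candidate pairs.
#' @param summaries Method summaries from [summarize_distances()] computed on
#'   the distance universe of the run; the `mean` column is the threshold.
#' @return A tibble with columns `id_a`, `id_b`, one `distance_<method>` and
#'   one `below_<method>` column per method, `consensus_count`, and
#'   `mean_distance`.
#' @export
call_candidates <- function(records, summaries) {
  stopifnot(all(c("id_a", "id_b", "method", "distance") %in% names(records)))
  stopifnot(all(c("method", "mean") %in% names(summaries)))
  methods <- sort(unique(summaries$method))
  n_methods <- length(methods)
  # the same pair may be listed under several sources; its distance per method
  # is unique, so collapse before pivoting
  rec <- records |>
    distinct(.data$id_a, .data$id_b, .data$method, .data$distance) |>
    filter(.data$method %in% methods) |>
    left_join(summaries[c("method", "mean")], by = "method") |>
    mutate(below = .data$distance < .data$mean)

  counts <- rec |>
    group_by(.data$id_a, .data$id_b) |>
    summarise(n_methods_seen = dplyr::n_distinct(.data$method), .groups = "drop")
  incomplete <- counts[counts$n_methods_seen < n_methods, , drop = FALSE]
  if (nrow(incomplete) > 0) {
    inform(paste0(
      nrow(incomplete),
      " pair(s) missing a distance for some method were excluded from calling."
    ))
    rec <- anti_join(rec, incomplete, by = c("id_a", "id_b"))
  }
  if (nrow(rec) == 0) {
    stop_invalid("No pairs with complete per-method distances.", "drembed_invalid_records")
  }

  wide <- rec |>
    select("id_a", "id_b", "method", "distance", "below") |>
    tidyr::pivot_wider(
      names_from = "method", values_from = c("distance", "below"),
      names_sep = "_"
    )
  below_cols <- paste0("below_", methods)
  dist_cols <- paste0("distance_", methods)
  wide$consensus_count <- rowSums(as.matrix(wide[below_cols]))
  wide$mean_distance <- rowMeans(as.matrix(wide[dist_cols]))
  out <- arrange(wide, desc(.data$consensus_count), .data$mean_distance)
  attr(out, "n_methods") <- n_methods
  out
}

#' Fraction of candidate calls reaching a consensus level
#'
#' @param calls Candidate-call tibble from [call_candidates()].
#' @param k Minimum consensus count.
#' @return Percentage (0-100) of calls with `consensus_count >= k`.
#' @examples
#' # 37 of 67 pairs below the mean in all 4 methods -> 55.22
#' @export
consensus_fraction <- function(calls, k) {
  if (!is.data.frame(calls) || nrow(calls) == 0) {
    stop_invalid("`calls` must be a nonempty candidate-call table.", "drembed_invalid_records")
  }
  stopifnot("consensus_count" %in% names(calls))
  100 * mean(calls$consensus_count >= k)
}
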