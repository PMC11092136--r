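# End-to-end orchestration: read -> length filter -> embed (each method) ->
# pair construction (+/- class filter) -> distances -> resampled MWU ->
# candidate calls -> machine-readable report. Every random stage draws from a
# named substream of the single master seed, so a config fully determines the
# report (reports carry no timestamps: identical config => identical bytes).

#' Configure a pipeline run
#'
#' Validates paths and parameters before any stage runs; the config is
#' serialized verbatim into the run report.
#'
#' @param fasta Path to the protein FASTA (plain or gzipped).
#' @param drug_targets,disease_proteins,dr_cases Paths to the association TSVs.
#' @param classes Optional path to the class-annotation TSV (required when
#'   `filtered` includes `TRUE`).
#' @param methods Embedding methods to run: any of `"onehot_mean"`, `"sgt"`.
#' @param external_embeddings Optional named list of paths to precomputed
#'   embedding tables, loaded via [load_external_embeddings()]; names become
#'   `external:<name>` method labels.
#' @param kappa,sgt_mode SGT parameters.
#' @param max_len Length cut-off for [filter_by_length()].
#' @param n_iterations Resampling iterations for [resampled_mwu()].
#' @param seed Master integer seed.
#' @param sources DR sources to analyse: `"all"` (each source present,
#'   separately) or a subset of `c("repodb", "literature")`.
#' @param filtered Logical vector: run the shared-class-filtered subset, the
#'   unfiltered one, or both (default `c(FALSE, TRUE)` when `classes` is given,
#'   else `FALSE`).
#' @param alternative MWU alternative, `"two_sided"` (default) or `"less"`.
#' @param background_cap Uniform sample size of the background pair universe
#'   (default 20000).
#' @param out_dir Optional directory for TSV/JSON artifacts.
#' @return A validated `run_config` object.
#' @export
run_config <- function(fasta, drug_targets, disease_proteins, dr_cases,
                       classes = NULL,
                       methods = c("onehot_mean", "sgt"),
                       external_embeddings = NULL,
                       kappa = 1,
                       sgt_mode = c("length_insensitive", "length_sensitive"),
                       max_len = 6024,
                       n_iterations = 1000,
                       seed = 1L,
                       sources = "all",
                       filtered = NULL,
                       alternative = c("two_sided", "less"),
                       background_cap = 20000,
                       out_dir = NULL) {
  sgt_mode <- match.arg(sgt_mode)
  alternative <- match.arg(alternative)
  for (p in c(fasta, drug_targets, disease_proteins, dr_cases, classes,
              unlist(external_embeddings))) {
    if (!file.exists(p)) {
      stop_invalid(paste0("Input file not found: ", p), "drembed_config_error")
    }
  }
  if (!all(methods %in% c("onehot_mean", "sgt"))) {
    stop_invalid(
      "`methods` must be drawn from 'onehot_mean', 'sgt'.",
      "drembed_config_error"
    )
  }
  if (!is.null(external_embeddings) &&
    (is.null(names(external_embeddings)) || any(!nzchar(names(external_embeddings))))) {
    stop_invalid("`external_embeddings` must be a named list of paths.", "drembed_config_error")
  }
  if (length(methods) + length(external_embeddings) < 1) {
    stop_invalid("At least one embedding method is required.", "drembed_config_error")
  }
  if (!identical(sources, "all") &&
    !all(sources %in% c("repodb", "literature"))) {
    stop_invalid(
      "`sources` must be 'all' or a subset of c('repodb', 'literature').",
      "drembed_config_error"
    )
  }
  if (is.null(filtered)) filtered <- if (is.null(classes)) FALSE else c(FALSE, TRUE)
  if (any(filtered) && is.null(classes)) {
    stop_invalid(
      "`filtered = TRUE` requires a class-annotation table.",
      "drembed_config_error"
    )
  }
  if (n_iterations < 1 || background_cap < 2 || max_len < 1) {
    stop_invalid(
      "`n_iterations`, `background_cap` and `max_len` must be positive.",
      "drembed_config_error"
    )
  }
  structure(
    list(
      fasta = fasta, drug_targets = drug_targets,
      disease_proteins = disease_proteins, dr_cases = dr_cases,
      classes = classes, methods = methods,
      external_embeddings = external_embeddings,
      kappa = kappa, sgt_mode = sgt_mode, max_len = max_len,
      n_iterations = as.integer(n_iterations), seed = as.integer(seed),
      sources = sources, filtered = filtered, alternative = alternative,
      background_cap = background_cap, out_dir = out_dir
    ),
    class = "run_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(
      paste0("[stage: ", stage, "] ", conditionMessage(e)),
      class = c("drembed_stage_error", "drembed_error")
    )
  })
}

#' Run the full repurposing-distance pipeline
#'
#' Executes every stage on the configured inputs and returns a
#' `dr_run_report`: per-(method, source, filtered) resampled-MWU results,
#' per-method distance summaries, below-mean consensus candidate calls, stage
#' counts, the verbatim config, and content checksums of any written artifacts.
#'
#' @param config A `run_config`.
#' @return A `dr_run_report` object.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  counts <- list()

  records <- run_stage("read", read_fasta(config$fasta))
  counts$proteins_read <- nrow(records)
  flt <- run_stage("length-filter", filter_by_length(records, config$max_len))
  counts$proteins_discarded_by_length <- nrow(flt$discarded)
  records <- flt$kept

  classes <- if (!is.null(config$classes)) {
    run_stage("classes", read_class_annotations(config$classes))
  } else {
    tibble(id = character(0), class = character(0))
  }

  tables <- run_stage("associations", association_tables(
    read_drug_targets(config$drug_targets),
    read_disease_proteins(config$disease_proteins),
    read_dr_cases(config$dr_cases),
    records = records
  ))

  dr_pairs <- run_stage("pair-construction", build_dr_pairs(tables))
  counts$dr_pairs_built <- nrow(dr_pairs)

  embeddings <- run_stage("embed", {
    es <- lapply(config$methods, function(m) {
      embed_corpus(records, m, kappa = config$kappa, mode = config$sgt_mode)
    })
    ext <- lapply(names(config$external_embeddings), function(nm) {
      load_external_embeddings(config$external_embeddings[[nm]], nm)
    })
    all <- c(es, ext)
    stats::setNames(all, vapply(all, function(e) e$method, character(1)))
  })

  sources_run <- if (identical(config$sources, "all")) {
    sort(unique(dr_pairs$source))
  } else {
    intersect(config$sources, unique(dr_pairs$source))
  }

  dist_long <- list()
  background_long <- list()
  tests <- list()
  counts$dr_pairs_after_class_filter <- NA_integer_
  for (method in names(embeddings)) {
    emb <- embeddings[[method]]
    background <- run_stage("background-distances", background_distances(
      emb,
      exclude = dr_pairs, sample_cap = config$background_cap,
      seed = substream_seed(config$seed, paste0("background-", method))
    ))
    dr_dist <- run_stage("dr-distances", pair_distances(emb, dr_pairs))
    dist_long[[method]] <- dr_dist
    background_long[[method]] <- background
    for (src in sources_run) {
      for (filt in config$filtered) {
        sub <- dr_dist[dr_dist$source == src, , drop = FALSE]
        if (filt) {
          sub <- filter_shared_class(sub, classes)
          counts$dr_pairs_after_class_filter <- nrow(distinct(sub[c("id_a", "id_b")]))
        }
        if (nrow(sub) < 2) {
          warn(paste0(
            "Skipping (", method, ", ", src, ", filtered=", filt,
            "): fewer than 2 DR pairs."
          ))
          next
        }
        key <- paste(method, src, filt, sep = "|")
        tests[[key]] <- run_stage("resampled-mwu", resampled_mwu(
          sub$distance, background$distance,
          n_iterations = config$n_iterations,
          seed = substream_seed(
            config$seed, paste0("mwu-", method, "-", src, "-", filt)
          ),
          alternative = config$alternative,
          method = method, source = src, filtered = filt
        ))
      }
    }
  }

  # distance universe for thresholds = background sample + DR pairs
  core_cols <- c("id_a", "id_b", "method", "distance")
  universe <- bind_rows(
    bind_rows(background_long)[core_cols],
    bind_rows(dist_long)[core_cols]
  )
  summaries <- run_stage("summaries", summarize_distances(universe))

  calls <- run_stage("candidate-calling", call_candidates(
    bind_rows(dist_long)[core_cols], summaries
  ))
  n_methods <- length(embeddings)
  consensus_pct <- consensus_fraction(calls, n_methods)

  report <- structure(
    list(
      package_version = as.character(utils::packageVersion("drembed")),
      config = unclass(config),
      counts = counts,
      summaries = summaries,
      tests = bind_rows(lapply(tests, glance)),
      p_values = lapply(tests, function(t) t$p_values),
      candidate_calls = calls,
      n_methods = n_methods,
      consensus_fraction_pct = consensus_pct,
      artifacts = list()
    ),
    class = "dr_run_report"
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      dr_distances = file.path(config$out_dir, "dr_distances.tsv"),
      background_distances = file.path(config$out_dir, "background_distances.tsv"),
      summaries = file.path(config$out_dir, "distance_summaries.tsv"),
      candidate_calls = file.path(config$out_dir, "candidate_calls.tsv"),
      tests = file.path(config$out_dir, "tests.tsv")
    )
    readr::write_tsv(bind_rows(dist_long), paths$dr_distances, progress = FALSE)
    readr::write_tsv(bind_rows(background_long), paths$background_distances, progress = FALSE)
    readr::write_tsv(summaries, paths$summaries, progress = FALSE)
    readr::write_tsv(calls, paths$candidate_calls, progress = FALSE)
    readr::write_tsv(report$tests, paths$tests, progress = FALSE)
    report$artifacts <- lapply(paths, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
    write_run_report(report, file.path(config$out_dir, "report.json"))
  }
  report
}

#' @export
print.dr_run_report <- function(x, ...) {
  cat("<dr_run_report> drembed ", x$package_version, "\n", sep = "")
  cat(
    "  proteins: ", x$counts$proteins_read, " read, ",
    x$counts$proteins_discarded_by_length, " discarded by length\n",
    "  DR pairs built: ", x$counts$dr_pairs_built, "\n",
    sep = ""
  )
  cat("  tests:\n")
  print(x$summaries)
  print(x$tests[c("method", "source", "filtered", "p_mean", "p_median", "dr_mean", "background_mean")])
  cat(sprintf(
    "  consensus: %.2f%% of called pairs below the mean in all %d methods\n",
    x$consensus_fraction_pct, x$n_methods
  ))
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' The JSON carries everything needed to reproduce the run (config, seed,
#' counts, per-iteration p-values, summaries, calls, artifact checksums) and no
#' timestamps, so identical configs yield byte-identical reports.
#'
#' @param report A `dr_run_report`.
#' @param path Output `.json` path.
#' @return The report's md5 checksum (of the written file), invisibly.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "dr_run_report"))
  jsonlite::write_json(
    unclass(report), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(unname(tools::md5sum(path)))
}
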