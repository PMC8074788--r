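#' End-to-end species identification run
#'
#' Runs the full identification workflow on a PSM table: marker
#' assignment, cleavage annotation, per-marker MAD score cut-offs,
#' detection matrices, per-sample species calls, the degradation summary
#' (marker counts by class, undetermined-cleavage percentages) and the PTM
#' report. When `out_dir` is given, writes `cutoffs.tsv`,
#' `detection_counts.tsv`, `detection_max_score.tsv`,
#' `species_call_<sample>.json`, `degradation_summary.tsv`,
#' `undetermined_cleavage.tsv` and `ptm_oxidation.tsv`; every table embeds
#' reproducibility provenance (database content hash, settings) in
#' `run_info.json`.
#'
#' @param psm A `psm_cohort` or path to a PSM table.
#' @param db A `marker_db` (default: bundled database).
#' @param out_dir Optional output directory (created if missing).
#' @param exclude_classes Classes excluded from species assignment.
#' @param mad Apply the per-marker MAD cut-off (default `TRUE`).
#' @param per_sample_cutoffs Compute cut-offs per sample instead of pooled.
#' @param score_floor Optional ingestion score floor when `psm` is a path.
#' @return Invisibly, a list: `cohort`, `cutoffs`, `counts`, `max_scores`,
#'   `calls`, `undetermined`, `degradation`, `ptm`.
#' @export
run_identify <- function(psm, db = bundled_marker_db(), out_dir = NULL,
                         exclude_classes = "D", mad = TRUE,
                         per_sample_cutoffs = FALSE, score_floor = NULL) {
  cohort <- if (is.character(psm)) read_psm_table(psm, score_floor) else psm
  cohort <- assign_markers(cohort, db)
  cohort <- annotate_cleavage(cohort, db)
  if (nrow(cohort) == 0) {
    warning("empty PSM table: all calls inconclusive")
  }
  filt <- if (mad) apply_marker_cutoffs(cohort, db,
                                        per_sample = per_sample_cutoffs)
          else list(cohort = cohort,
                    cutoffs = tibble::tibble(marker_id = character(0),
                                             cutoff = numeric(0)))
  counts <- detection_matrix(filt$cohort, db, "count")
  max_scores <- detection_matrix(filt$cohort, db, "max_score")
  calls <- lapply(colnames(counts), function(s) {
    assign_species(rownames(counts)[counts[, s] > 0], db,
                   exclude_classes = exclude_classes)
  })
  names(calls) <- colnames(counts)
  # cleavage degradation is summarized over all PSMs combined (before the
  # score filter: unassigned peptides have no per-marker cut-off, so
  # filtering would skew the undetermined share upward)
  undet <- list(
    overall = undetermined_fraction(cohort, "overall"),
    by_class = undetermined_fraction(cohort, "class"),
    by_sample = undetermined_fraction(cohort, "sample")
  )
  class_of <- setNames(db$markers$class_id, db$markers$marker_id)
  degradation <- if (ncol(counts) == 0) {
    tibble::tibble(sample = character(0), class_id = character(0),
                   n_markers_detected = integer(0),
                   n_markers_total = integer(0))
  } else {
    tibble::as_tibble(as.data.frame.table(
      counts > 0, responseName = "detected", stringsAsFactors = FALSE)) |>
      dplyr::rename(marker_id = "Var1", sample = "Var2") |>
      dplyr::mutate(class_id = unname(class_of[.data$marker_id])) |>
      dplyr::group_by(.data$sample, .data$class_id) |>
      dplyr::summarise(n_markers_detected = sum(.data$detected),
                       n_markers_total = dplyr::n(), .groups = "drop")
  }
  ptm <- tryCatch(
    oxidation_percentages(filt$cohort, db, group_by = "sample"),
    error = function(e) tibble::tibble()
  )
  res <- list(cohort = filt$cohort, cutoffs = filt$cutoffs, counts = counts,
              max_scores = max_scores, calls = calls, undetermined = undet,
              degradation = degradation, ptm = ptm)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(filt$cutoffs, file.path(out_dir, "cutoffs.tsv"),
                     progress = FALSE)
    write_matrix_tsv(counts, file.path(out_dir, "detection_counts.tsv"))
    write_matrix_tsv(max_scores,
                     file.path(out_dir, "detection_max_score.tsv"))
    for (s in names(calls)) {
      species_call_json(calls[[s]],
                        file.path(out_dir, paste0("species_call_",
                                                  gsub("[^A-Za-z0-9_.-]", "_", s),
                                                  ".json")))
    }
    readr::write_tsv(degradation,
                     file.path(out_dir, "degradation_summary.tsv"),
                     progress = FALSE)
    readr::write_tsv(dplyr::bind_rows(
      dplyr::mutate(undet$by_sample, group = "sample"),
      dplyr::mutate(dplyr::rename(undet$by_class, sample = "class"),
                    group = "class"),
      dplyr::mutate(undet$overall, sample = "all", group = "overall")
    ), file.path(out_dir, "undetermined_cleavage.tsv"), progress = FALSE)
    if (nrow(ptm) > 0) {
      readr::write_tsv(ptm, file.path(out_dir, "ptm_oxidation.tsv"),
                       progress = FALSE)
    }
    jsonlite::write_json(
      list(db_hash = marker_db_hash(db), n_psm = nrow(cohort),
           mad = mad, per_sample_cutoffs = per_sample_cutoffs,
           exclude_classes = exclude_classes,
           calls = vapply(calls, `[[`, character(1), "call")),
      file.path(out_dir, "run_info.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}

write_matrix_tsv <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "marker_id")
  readr::write_tsv(df, path, progress = FALSE)
}

# Content hash of a database: digest-free stable checksum (sum of
# integer-coded characters of the serialized marker table).
marker_db_hash <- function(db) {
  s <- paste(db$markers$marker_id, db$markers$sequence,
             vapply(db$markers$species_validated, paste, character(1),
                    collapse = ","),
             collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)) %%
            .Machine$integer.max)
}

#' Train on a modern reference cohort and classify query samples
#'
#' Builds the PCA + SOM + elbow-k-means reference system from the modern
#' cohort and assigns each query (e.g. archaeological) sample to a cluster;
#' queries never influence training.
#'
#' @param reference,query `psm_cohort`s or PSM table paths (reference needs
#'   >= 2 samples).
#' @param db A `marker_db`.
#' @param grid,iterations,seed Passed to [som_train()].
#' @param mad Apply MAD cut-offs before building features.
#' @param out_dir Optional output directory (`classifier.json`,
#'   `cluster_report.tsv`).
#' @return Invisibly, a list: `classifier`, `reference_report`,
#'   `query_report`.
#' @export
run_classify <- function(reference, query = NULL, db = bundled_marker_db(),
                         grid = c(4, 4), iterations = 10000L, seed = 1L,
                         mad = TRUE, out_dir = NULL) {
  prep <- function(x) {
    cohort <- if (is.character(x)) read_psm_table(x) else x
    cohort <- assign_markers(cohort, db)
    cohort <- annotate_cleavage(cohort, db)
    if (mad) apply_marker_cutoffs(cohort, db)$cohort else cohort
  }
  ref <- prep(reference)
  X_ref <- feature_matrix(ref, db)
  classifier <- build_classifier(X_ref, grid = grid,
                                 iterations = iterations, seed = seed)
  query_report <- NULL
  if (!is.null(query)) {
    qc <- prep(query)
    X_q <- feature_matrix(qc, db)
    query_report <- classify_new(classifier, X_q)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_classifier_json(classifier, file.path(out_dir, "classifier.json"))
    report <- dplyr::bind_rows(
      dplyr::mutate(classifier$reference, set = "reference"),
      if (!is.null(query_report))
        dplyr::mutate(query_report[, c("sample", "bmu", "cluster",
                                       "PC1", "PC2")], set = "query")
    )
    readr::write_tsv(report, file.path(out_dir, "cluster_report.tsv"),
                     progress = FALSE)
  }
  invisible(list(classifier = classifier,
                 reference_report = classifier$reference,
                 query_report = query_report))
}

#' Generate a synthetic cohort and write it to disk
#'
#' @param configs A `generator_config` or list of them (or path to a
#'   YAML/JSON config file with a list of config fields).
#' @param db A `marker_db`.
#' @param out_dir Output directory: writes `psm_table.tsv` and
#'   `truth.json`.
#' @return Invisibly, the generated `psm_cohort`.
#' @export
run_simulate <- function(configs, db = synthetic_panel_db(), out_dir) {
  if (is.character(configs)) {
    raw <- jsonlite::read_json(configs, simplifyVector = TRUE)
    if (!is.null(raw$species)) raw <- list(raw)
    configs <- lapply(raw, function(x) do.call(generator_config, x))
  }
  cohort <- generate_cohort(configs, db)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_psm_table(cohort, file.path(out_dir, "psm_table.tsv"))
  truth <- attr(cohort, "truth")
  truth_slim <- lapply(truth, function(t) {
    list(sample = t$sample, species = t$species, d = t$d,
         detected_markers = t$detected_markers,
         n_psm = if (is.null(t$psms)) 0L else nrow(t$psms),
         n_undetermined_truth = if (is.null(t$psms)) 0L else
           sum(t$psms$cleavage_truth == "undetermined"))
  })
  jsonlite::write_json(truth_slim, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}
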