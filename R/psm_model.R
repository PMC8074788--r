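#' PSM cohorts
#'
#' A cohort is a tibble of peptide-spectrum matches, one row per PSM, with
#' columns `sample` (specimen id; all runs of a specimen pooled), `peptide`,
#' `score` (-10lgP, higher is better), `mods` (list-column of tibbles with
#' `name`, `pos`, `delta`), `prev_residue`/`next_residue` (flanks, `"-"` at
#' protein termini, `NA` unknown), and after annotation `marker_id`,
#' `class_id` and `cleavage`. Sample-level metadata (e.g. true species for
#' synthetic cohorts) travels in the `sample_meta` attribute.
#'
#' @name psm_cohort
NULL

empty_psm_tibble <- function() {
  tibble::tibble(sample = character(0), peptide = character(0),
                 score = numeric(0), mods = list(),
                 prev_residue = character(0), next_residue = character(0))
}

new_psm_cohort <- function(df, sample_meta = NULL, truth = NULL) {
  df <- tibble::as_tibble(df)
  if (nrow(df) == 0) {
    base <- empty_psm_tibble()
    for (col in setdiff(names(base), names(df))) df[[col]] <- base[[col]]
  }
  for (col in c("marker_id", "class_id", "cleavage")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  stopifnot(all(is.finite(df$score)))
  structure(df, class = c("psm_cohort", class(tibble::tibble()))) -> out
  attr(out, "sample_meta") <- sample_meta
  attr(out, "truth") <- truth
  out
}

#' Parse a modification string
#'
#' Dialect: `"Oxidation@4;Carbamidomethyl@2"` (name at 1-based position,
#' semicolon-separated; empty string or `NA` means unmodified).
#'
#' @param x Character vector of modification strings.
#' @return List of tibbles with columns `name`, `pos`, `delta`.
#' @export
parse_mods <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) {
      return(tibble::tibble(name = character(0), pos = integer(0),
                            delta = numeric(0)))
    }
    parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^\\s*([A-Za-z]+)@([0-9]+)\\s*$", parts))
    bad <- vapply(m, length, integer(1)) == 0
    if (any(bad)) {
      stop("unparseable modification token(s): ",
           paste(parts[bad], collapse = ", "))
    }
    name <- vapply(m, `[[`, character(1), 2)
    pos <- as.integer(vapply(m, `[[`, character(1), 3))
    tibble::tibble(name = name, pos = pos, delta = mod_delta(name))
  })
}

format_mods <- function(mods) {
  vapply(mods, function(m) {
    if (nrow(m) == 0) "" else paste(paste0(m$name, "@", m$pos), collapse = ";")
  }, character(1))
}

#' Read a PSM table
#'
#' Reads a TSV/CSV with required columns `sample`, `peptide`, `score` and
#' optional `mods`, `prev`, `next`. Modification strings follow the
#' [parse_mods()] dialect. An optional generic score floor mirrors typical
#' search-engine export filters.
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.csv` is comma, anything else tab).
#' @param score_floor Optional minimum -10lgP; rows below are dropped.
#' @return A `psm_cohort` tibble.
#' @export
read_psm_table <- function(path, score_floor = NULL) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample", "peptide", "score")
  if (!all(required %in% names(df))) {
    stop("PSM table lacks required column(s): ",
         paste(setdiff(required, names(df)), collapse = ", "))
  }
  mods <- if ("mods" %in% names(df)) {
    tryCatch(parse_mods(df$mods), error = function(e) {
      stop("modification parse failure: ", conditionMessage(e))
    })
  } else {
    parse_mods(rep("", nrow(df)))
  }
  bad_pos <- vapply(seq_len(nrow(df)), function(i) {
    any(mods[[i]]$pos > nchar(df$peptide[i]) | mods[[i]]$pos < 1L)
  }, logical(1))
  if (any(bad_pos)) {
    stop("modification position outside peptide at data row(s): ",
         paste(which(bad_pos), collapse = ", "))
  }
  out <- tibble::tibble(
    sample = as.character(df$sample),
    peptide = toupper(df$peptide),
    score = as.numeric(df$score),
    mods = mods,
    prev_residue = if ("prev" %in% names(df)) as.character(df$prev) else NA_character_,
    next_residue = if ("next" %in% names(df)) as.character(df[["next"]]) else NA_character_
  )
  if (!is.null(score_floor)) out <- out[out$score >= score_floor, ]
  new_psm_cohort(out)
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]: columns `sample`, `peptide`, `score`,
#' `mods`, `prev`, `next`.
#'
#' @param cohort A `psm_cohort`.
#' @param path Output path (TSV).
#' @return `cohort`, invisibly.
#' @export
write_psm_table <- function(cohort, path) {
  df <- tibble::tibble(
    sample = cohort$sample, peptide = cohort$peptide,
    score = cohort$score, mods = format_mods(cohort$mods),
    prev = cohort$prev_residue, `next` = cohort$next_residue
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(cohort)
}

#' Split a cohort into per-sample runs
#' @param cohort A `psm_cohort`.
#' @return Named list of tibbles, one per sample.
#' @export
sample_runs <- function(cohort) {
  split(tibble::as_tibble(cohort), cohort$sample)
}

#' Assign PSM peptides to database markers
#'
#' Three-stage assignment: exact sequence match to a marker (I/L-equivalent
#' when requested); unique substring containment (a degraded peptide
#' trimmed from one marker, or spanning beyond it); otherwise the peptide
#' keeps `marker_id = NA` and receives only an inferred `class_id` from
#' [classify_peptide()]. Peptides contained in several markers stay
#' unassigned: the repertoires are template-derived and fragments can be
#' shared.
#'
#' @param cohort A `psm_cohort`.
#' @param db A `marker_db`.
#' @param il_equivalent Treat I and L as equivalent in the exact stage.
#' @return The cohort with `marker_id` and `class_id` filled in.
#' @export
assign_markers <- function(cohort, db, il_equivalent = TRUE) {
  mk <- db$markers
  key <- if (il_equivalent) gsub("I", "L", mk$sequence) else mk$sequence
  lookup <- setNames(mk$marker_id, key)
  if (il_equivalent && anyDuplicated(key)) {
    warning("markers indistinguishable under I/L equivalence: ",
            paste(mk$marker_id[duplicated(key) | duplicated(key, fromLast = TRUE)],
                  collapse = ", "))
  }
  class_of <- setNames(mk$class_id, mk$marker_id)

  peps <- unique(cohort$peptide)
  pkey <- if (il_equivalent) gsub("I", "L", peps) else peps
  hit <- unname(lookup[pkey])
  # substring containment for the remainder
  todo <- which(is.na(hit))
  for (i in todo) {
    inside <- which(vapply(mk$sequence, function(s) {
      grepl(peps[i], s, fixed = TRUE) || grepl(s, peps[i], fixed = TRUE)
    }, logical(1)))
    if (length(inside) == 1L) hit[i] <- mk$marker_id[inside]
  }
  cls <- unname(class_of[hit])
  # class inference for still-unassigned peptides
  for (i in which(is.na(hit))) {
    cls[i] <- classify_peptide(peps[i], db,
                               il_equivalent = il_equivalent)$class_id
  }
  idx <- match(cohort$peptide, peps)
  cohort$marker_id <- hit[idx]
  cohort$class_id <- cls[idx]
  cohort
}

#' Annotate cleavage status for every PSM
#'
#' Marker-assigned PSMs are judged against their marker's canonical
#' boundaries (plus flanks when present) with [cleavage_status()];
#' unassigned PSMs are judged from flanking evidence alone, and are
#' `"undetermined"` when no flanks are available.
#'
#' @param cohort A `psm_cohort` with markers assigned.
#' @param db A `marker_db`.
#' @return The cohort with the `cleavage` column filled in.
#' @export
annotate_cleavage <- function(cohort, db) {
  mk <- db$markers
  seq_of <- setNames(mk$sequence, mk$marker_id)
  term_of <- setNames(
    db$templates$tryptic_termini[match(
      vapply(mk$class_id, function(cl) {
        # any template row of the reporting class carries the termini label
        db$templates$class_id[reporting_class(db$templates$class_id) == cl][1]
      }, character(1)),
      db$templates$class_id)],
    mk$marker_id
  )
  keyed <- paste(cohort$peptide, cohort$marker_id,
                 cohort$prev_residue, cohort$next_residue, sep = "\r")
  uk <- !duplicated(keyed)
  res <- vapply(which(uk), function(i) {
    m <- cohort$marker_id[i]
    if (is.na(m)) {
      cleavage_status_flanks(cohort$peptide[i], cohort$prev_residue[i],
                             cohort$next_residue[i])
    } else {
      suppressWarnings(
        cleavage_status(cohort$peptide[i], seq_of[[m]], term_of[[m]],
                        cohort$prev_residue[i], cohort$next_residue[i])
      )
    }
  }, character(1))
  cohort$cleavage <- unname(setNames(res, keyed[uk])[keyed])
  cohort
}

#' MAD score cut-off
#'
#' The per-marker outlier cut-off: the median of the scores minus their
#' (unscaled) median absolute deviation. No normal-consistency factor is
#' applied: the cut-off is plain `median - median(|x - median|)`.
#'
#' @param scores Numeric vector of -10lgP scores (length >= 1).
#' @return The cut-off score.
#' @examples
#' mad_cutoff(c(30, 32, 35, 40, 50))  # 30
#' @export
mad_cutoff <- function(scores) {
  if (length(scores) == 0) stop("no scores supplied")
  stopifnot(all(is.finite(scores)))
  median(scores) - stats::mad(scores, constant = 1)
}

#' Apply per-marker MAD cut-offs to a cohort
#'
#' For each marker, the cut-off is computed from the pooled eligible PSMs
#' across the whole cohort — those carrying no modification other than
#' carbamidomethylation — and PSMs of that marker scoring below the cut-off
#' are removed. Markers with no eligible PSM keep all their PSMs and are
#' flagged. Unassigned PSMs are untouched. `per_sample = TRUE` computes
#' cut-offs within each sample instead of pooling the cohort.
#'
#' @param cohort A `psm_cohort` with markers assigned.
#' @param db A `marker_db`.
#' @param per_sample Compute cut-offs per sample rather than pooled.
#' @return A list with `cohort` (filtered) and `cutoffs` (tibble with
#'   `marker_id`, `cutoff`, `n_eligible`, `flagged`, and `sample` when
#'   `per_sample`).
#' @export
apply_marker_cutoffs <- function(cohort, db, per_sample = FALSE) {
  if (nrow(cohort) == 0) {
    return(list(cohort = cohort,
                cutoffs = tibble::tibble(marker_id = character(0),
                                         cutoff = numeric(0),
                                         n_eligible = integer(0),
                                         flagged = logical(0))))
  }
  eligible <- vapply(cohort$mods, function(m) {
    all(tolower(m$name) == "carbamidomethyl")
  }, logical(1))
  df <- tibble::tibble(
    i = seq_len(nrow(cohort)), sample = cohort$sample,
    marker_id = cohort$marker_id, score = cohort$score, eligible = eligible
  )
  grp_cols <- if (per_sample) c("marker_id", "sample") else "marker_id"
  cut_tbl <- df |>
    dplyr::filter(!is.na(.data$marker_id)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::summarise(
      n_eligible = sum(.data$eligible),
      cutoff = if (any(.data$eligible)) mad_cutoff(.data$score[.data$eligible])
               else -Inf,
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = .data$n_eligible == 0)
  keep <- rep(TRUE, nrow(cohort))
  assigned <- !is.na(df$marker_id)
  j <- if (per_sample) {
    match(paste(df$marker_id, df$sample), paste(cut_tbl$marker_id, cut_tbl$sample))
  } else {
    match(df$marker_id, cut_tbl$marker_id)
  }
  keep[assigned] <- df$score[assigned] >= cut_tbl$cutoff[j[assigned]]
  out <- cohort[keep, ]
  attr(out, "sample_meta") <- attr(cohort, "sample_meta")
  attr(out, "truth") <- attr(cohort, "truth")
  list(cohort = out, cutoffs = cut_tbl)
}

#' Marker-by-sample detection matrix
#'
#' Rows are all database markers (undetected markers appear as zero rows),
#' columns the cohort samples; cells hold filtered PSM counts or the
#' highest retained score. Unassigned PSMs are excluded.
#'
#' @param cohort A filtered, marker-assigned `psm_cohort`.
#' @param db A `marker_db`.
#' @param value_kind `"count"` or `"max_score"`.
#' @return A numeric matrix with `value_kind` attribute.
#' @export
detection_matrix <- function(cohort, db, value_kind = c("count", "max_score")) {
  value_kind <- match.arg(value_kind)
  samples <- sort(unique(cohort$sample))
  m <- matrix(0, nrow = nrow(db$markers), ncol = length(samples),
              dimnames = list(db$markers$marker_id, samples))
  hit <- !is.na(cohort$marker_id)
  df <- cohort[hit, c("marker_id", "sample", "score")]
  if (nrow(df) > 0) {
    agg <- df |>
      dplyr::group_by(.data$marker_id, .data$sample) |>
      dplyr::summarise(
        v = if (value_kind == "count") dplyr::n() else max(.data$score),
        .groups = "drop"
      )
    m[cbind(agg$marker_id, agg$sample)] <- agg$v
  }
  attr(m, "value_kind") <- value_kind
  m
}

#' Percentage of PSMs with undetermined cleavages
#'
#' `100 * #undetermined / #PSMs`, overall or grouped by peptide class or by
#' sample — the degradation metric that roughly doubles from modern
#' reference scutes to archaeological tortoiseshell.
#'
#' @param cohort A cleavage-annotated `psm_cohort`.
#' @param group_by `"overall"`, `"class"` or `"sample"`.
#' @return A tibble with the grouping column (absent for `"overall"`),
#'   `n_psm` and `pct_undetermined`. Empty groups are absent (undefined).
#' @export
undetermined_fraction <- function(cohort,
                                  group_by = c("overall", "class", "sample")) {
  group_by <- match.arg(group_by)
  if (any(is.na(cohort$cleavage))) {
    stop("cleavage status not annotated; run annotate_cleavage() first")
  }
  df <- tibble::tibble(
    group = switch(group_by,
      overall = rep("overall", nrow(cohort)),
      class = cohort$class_id,
      sample = cohort$sample
    ),
    undet = cohort$cleavage == "undetermined"
  )
  df <- df[!is.na(df$group), ]
  out <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_psm = dplyr::n(),
                     pct_undetermined = 100 * mean(.data$undet),
                     .groups = "drop")
  if (group_by == "overall") out$group <- NULL
  else names(out)[1] <- group_by
  out
}
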