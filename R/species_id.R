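marker_label_sets <- function(db, level = c("species", "genus")) {
  level <- match.arg(level)
  sets <- db$markers$species_validated
  if (level == "genus") {
    sets <- lapply(sets, function(sp) unique(unname(db$genus_map[sp])))
  }
  setNames(sets, db$markers$marker_id)
}

#' Markers unique to one species or genus
#'
#' A marker is unique to a label when it is validated in that label and in
#' no other label at the requested level. Species with exclusive
#' substitutions carry the diagnostic power of the panel: a degraded sample
#' is only called confidently when at least one of its detected markers is
#' unique to the called species.
#'
#' @param db A `marker_db`.
#' @param level `"species"` or `"genus"`.
#' @return Named list: label -> character vector of marker ids (labels with
#'   no unique marker map to an empty vector).
#' @export
unique_markers <- function(db, level = c("species", "genus")) {
  level <- match.arg(level)
  sets <- marker_label_sets(db, level)
  labels <- if (level == "species") db$species else
    unique(unname(db$genus_map[db$species]))
  out <- lapply(labels, function(lb) {
    names(sets)[vapply(sets, function(s) identical(s, lb), logical(1))]
  })
  setNames(out, labels)
}

#' Markers shared by a set of species or genera
#'
#' Returns markers validated in every one of the given labels. With
#' `exclusive = TRUE` the marker must be validated in exactly those labels
#' and no others at the same level (species vs genus is inferred from the
#' labels).
#'
#' @param db A `marker_db`.
#' @param labels Character vector of species or genus labels.
#' @param exclusive Require the validation set to equal `labels` exactly.
#' @return Character vector of marker ids.
#' @export
shared_markers <- function(db, labels, exclusive = FALSE) {
  genera <- unique(unname(db$genus_map[db$species]))
  level <- if (all(labels %in% db$species)) "species"
           else if (all(labels %in% genera)) "genus"
           else stop("unknown label(s): ",
                     paste(setdiff(labels, c(db$species, genera)),
                           collapse = ", "))
  sets <- marker_label_sets(db, level)
  keep <- vapply(sets, function(s) {
    if (exclusive) setequal(s, labels) else all(labels %in% s)
  }, logical(1))
  names(sets)[keep]
}

#' Assign a species from a set of detected markers
#'
#' For each species the fraction of its validated markers present in the
#' detection set is computed (class D markers — the conserved beta-sheet
#' core, prone to random cleavage — are excluded by default; E1 can be
#' excluded too via `exclude_classes`). The call is the highest-fraction
#' species among those with at least one detected unique marker
#' (confidence `"unique_markers"`); when no species has unique support the
#' unique argmax-fraction species is called with confidence
#' `"fraction_only"`; ties and empty detection sets are `"inconclusive"`.
#'
#' @param detections Character vector of detected marker ids (a detection
#'   matrix column with value > 0, after score filtering). Duplicates and
#'   order are irrelevant.
#' @param db A `marker_db`.
#' @param exclude_classes Reporting classes removed from numerator and
#'   denominator (default `"D"`).
#' @return A `species_call` list: `fractions` (tibble with per-species
#'   percent, detected and total counts), `unique_markers_hit` (named
#'   list), `call`, `confidence` (`"unique_markers"`, `"fraction_only"` or
#'   `"none"`), `candidates`, `excluded_classes`.
#' @export
assign_species <- function(detections, db, exclude_classes = "D") {
  detections <- unique(detections)
  unknown <- setdiff(detections, db$markers$marker_id)
  if (length(unknown) > 0) {
    warning("ignoring unknown marker id(s): ", paste(unknown, collapse = ", "))
    detections <- setdiff(detections, unknown)
  }
  mk <- db$markers[!db$markers$class_id %in% exclude_classes, ]
  detections <- intersect(detections, mk$marker_id)
  uniq <- unique_markers(db, "species")
  uniq <- lapply(uniq, function(ids) setdiff(ids, db$markers$marker_id[
    db$markers$class_id %in% exclude_classes]))
  fractions <- dplyr::bind_rows(lapply(db$species, function(sp) {
    validated <- mk$marker_id[vapply(mk$species_validated,
                                     function(v) sp %in% v, logical(1))]
    det <- intersect(detections, validated)
    tibble::tibble(species = sp,
                   detected = length(det),
                   total = length(validated),
                   fraction = if (length(validated) > 0)
                     100 * length(det) / length(validated) else NA_real_)
  }))
  hits <- lapply(db$species, function(sp) intersect(detections, uniq[[sp]]))
  names(hits) <- db$species

  # Call rule. Unique markers are the primary evidence: among species with
  # at least one detected unique marker, the one with the highest fraction
  # is called (confidence "unique_markers"). A high shared-marker fraction
  # alone is not diagnostic when repertoires nest (a small repertoire
  # inside a larger one inflates its own fraction), so unique evidence
  # always outranks it. Only when no species has unique support does the
  # call fall back to the plain argmax fraction, labelled "fraction_only";
  # ties are inconclusive.
  call <- "inconclusive"
  confidence <- "none"
  candidates <- character(0)
  if (length(detections) > 0 && any(fractions$fraction > 0, na.rm = TRUE)) {
    top <- max(fractions$fraction, na.rm = TRUE)
    candidates <- fractions$species[!is.na(fractions$fraction) &
                                      fractions$fraction == top]
    supported <- fractions$species[vapply(fractions$species,
                                          function(sp) length(hits[[sp]]) > 0,
                                          logical(1))]
    if (length(supported) > 0) {
      sup_frac <- fractions$fraction[match(supported, fractions$species)]
      best <- supported[sup_frac == max(sup_frac)]
      candidates <- unique(c(best, candidates))
      if (length(best) == 1) {
        call <- best
        confidence <- "unique_markers"
      }
    } else if (length(candidates) == 1) {
      call <- candidates
      confidence <- "fraction_only"
    }
  }
  structure(
    list(fractions = fractions, unique_markers_hit = hits, call = call,
         confidence = confidence, candidates = candidates,
         excluded_classes = exclude_classes),
    class = "species_call"
  )
}

#' @export
print.species_call <- function(x, ...) {
  cat("<species_call>", x$call, paste0("(", x$confidence, ")"), "\n")
  df <- x$fractions[order(-x$fractions$fraction), ]
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-24s %5.1f%% (%d/%d), unique hits: %d\n",
                df$species[i], df$fraction[i], df$detected[i], df$total[i],
                length(x$unique_markers_hit[[df$species[i]]])))
  }
  invisible(x)
}

#' Serialize a species call to JSON
#' @param x A `species_call`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
species_call_json <- function(x, path = NULL) {
  payload <- list(
    call = x$call,
    confidence = x$confidence,
    candidates = x$candidates,
    excluded_classes = x$excluded_classes,
    fractions = x$fractions,
    unique_markers_hit = x$unique_markers_hit
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
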