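#' Marker database for sea turtle corneous beta-proteins
#'
#' A `marker_db` bundles (i) the wildcard class templates describing the
#' recurring tryptic peptide regions of the CBPs (classes A-F, with the
#' glycine-rich region subdivided into E1-E4), (ii) validated marker peptide
#' sequences with their curated class and the set of species each was
#' validated in, and (iii) the species list and the species-to-genus map
#' (the two *Lepidochelys* species share one genus label).
#'
#' @name marker_db
NULL

# Declared template lengths per class; E4a has a 25- and a 28-residue form.
TEMPLATE_LENGTHS <- c(
  A = 14L, B = 14L, C = 10L, D = 30L, E1 = 19L, E2a = 28L, E2b = 16L,
  E2c = 9L, E2d = 9L, E3 = 12L, E4a_short = 25L, E4a_long = 28L,
  E4b = 8L, F = 9L
)

SEA_TURTLE_SPECIES <- c(
  "Chelonia mydas", "Caretta caretta", "Eretmochelys imbricata",
  "Lepidochelys olivacea", "Lepidochelys kempii"
)

SEA_TURTLE_GENUS_MAP <- c(
  "Chelonia mydas"         = "Chelonia",
  "Caretta caretta"        = "Caretta",
  "Eretmochelys imbricata" = "Eretmochelys",
  "Lepidochelys olivacea"  = "Lepidochelys",
  "Lepidochelys kempii"    = "Lepidochelys"
)

new_marker_db <- function(templates, markers, species, genus_map) {
  db <- structure(
    list(templates = templates, markers = markers,
         species = species, genus_map = genus_map),
    class = "marker_db"
  )
  validate_marker_db(db)
  db
}

#' Validate a marker database
#'
#' Checks every type invariant: template strings match their declared
#' lengths and alphabet, marker ids are unique, marker sequences have the
#' length of their class template (E4a markers may take either length),
#' classes are known, and validated species appear in the species list.
#'
#' @param db A `marker_db`.
#' @return `db`, invisibly; errors list the offending marker ids.
#' @export
validate_marker_db <- function(db) {
  tl <- db$templates
  stopifnot(is.data.frame(tl), is.data.frame(db$markers))
  bad_len <- tl$class_id[nchar(tl$template) != TEMPLATE_LENGTHS[tl$class_id]]
  if (length(bad_len) > 0) {
    stop("template length mismatch for class(es): ", paste(bad_len, collapse = ", "))
  }
  chars_ok <- vapply(strsplit(tl$template, ""), function(ch) {
    all(ch %in% c(AA20, "X")) && any(ch != "X")
  }, logical(1))
  if (!all(chars_ok)) {
    stop("illegal template characters (or all-wildcard) for class(es): ",
         paste(tl$class_id[!chars_ok], collapse = ", "))
  }
  if (!all(tl$tryptic_termini %in% c("N_only", "C_only", "N_and_C"))) {
    stop("unknown tryptic_termini label in templates")
  }
  mk <- db$markers
  if (nrow(mk) == 0) return(invisible(db))
  if (anyDuplicated(mk$marker_id)) {
    stop("duplicate marker_id: ",
         paste(unique(mk$marker_id[duplicated(mk$marker_id)]), collapse = ", "))
  }
  if (!all(mk$class_id %in% CLASS_ORDER)) {
    bad <- unique(mk$marker_id[!mk$class_id %in% CLASS_ORDER])
    stop("unknown class_id for marker(s): ", paste(bad, collapse = ", "))
  }
  allowed <- split(TEMPLATE_LENGTHS, reporting_class(names(TEMPLATE_LENGTHS)))
  ok_len <- mapply(function(s, cl) nchar(s) %in% allowed[[cl]],
                   mk$sequence, mk$class_id)
  if (!all(ok_len)) {
    stop("sequence length does not match class template for marker(s): ",
         paste(mk$marker_id[!ok_len], collapse = ", "))
  }
  seq_ok <- vapply(strsplit(mk$sequence, ""), function(ch) all(ch %in% AA20),
                   logical(1))
  if (!all(seq_ok)) {
    stop("illegal residues in marker(s): ",
         paste(mk$marker_id[!seq_ok], collapse = ", "))
  }
  sp <- unique(unlist(mk$species_validated))
  if (!all(sp %in% db$species)) {
    stop("species_validated contains unknown species: ",
         paste(setdiff(sp, db$species), collapse = ", "))
  }
  invisible(db)
}

#' @export
print.marker_db <- function(x, ...) {
  cat("<marker_db>", nrow(x$templates), "class templates,",
      nrow(x$markers), "markers,", length(x$species), "species\n")
  invisible(x)
}

#' Bundled sea turtle CBP marker database
#'
#' Returns the built-in database: the 14 class templates (A, B, C, D, E1,
#' E2a-d, E3, E4a in 25- and 28-residue forms, E4b, F) with their expected
#' tryptic termini, the five sea turtle species with their genus map, and
#' the five individually published marker sequences (C-2, C-8, E2c-4,
#' E4a-19.1, all validated only in *E. imbricata*, and E1-7). The bundled
#' markers can be extended from a supplementary marker table with
#' [import_supplementary_markers()] or replaced wholesale with
#' [synthetic_reference_panel()].
#'
#' @return A `marker_db`.
#' @examples
#' db <- bundled_marker_db()
#' db$templates$template[db$templates$class_id == "C"]
#' @export
bundled_marker_db <- function() {
  templates <- tibble::tribble(
    ~class_id,    ~tryptic_termini, ~species_scope,            ~template,
    "A",          "N_and_C",        "all",                     "XXSXLXYPEXGVAR",
    "B",          "N_and_C",        "all",                     "PXPXXGSXNXPXVR",
    "C",          "N_and_C",        "all",                     "QCPDSEVVIX",
    "D",          "N_only",         "all",                     "PSPVVVTIPGPILSNFPQQSEVAAVGAPVV",
    "E1",         "C_only",         "all",                     "GXGXGGSFGXGGLYGYGGR",
    "E2a",        "N_and_C",        "Chelonia mydas",          "YGGLYGLGGLGGYGGHYGYAGLXGYGGR",
    "E2b",        "C_only",         "all",                     "YGGLYGYGGXGGYGGR",
    "E2c",        "N_and_C",        "all",                     "LGGFGGLXR",
    "E2d",        "C_only",         "all",                     "XGXXXGYGR",
    "E3",         "N_and_C",        "all",                     "YGXGGLXGYGGR",
    "E4a_short",  "C_only",         "all but Chelonia mydas",  "YGGXCGYGGGYGYGGLSGSGVSXHR",
    "E4a_long",   "C_only",         "all",                     "XGYGGLGGYXGGYGYGXGLXGSGVSXHR",
    "E4b",        "N_and_C",        "all",                     "YGGXXGYR",
    "F",          "N_only",         "all",                     "YLXGXCGPC"
  )
  ei <- "Eretmochelys imbricata"
  markers <- tibble::tibble(
    marker_id = c("C-2", "C-8", "E2c-4", "E4a-19.1", "E1-7"),
    class_id  = c("C", "C", "E2c", "E4a", "E1"),
    sequence  = c("QAQDSEVVIR", "QCQDSEVVIR", "YGGLHGLGR",
                  "AGYGGLGGYLGGYGYGGGLAGSGVSAHR", "GPGLGGSFGPGGLYGYGGR"),
    species_validated = list(ei, ei, ei, ei, ei),
    notes = c("P31Q substitution in the beta-sheet-adjacent region",
              "P31Q substitution in the beta-sheet-adjacent region",
              "curated class label; template inference prefers E2d",
              "long-form E4a, Y-type wildcard pattern",
              "validated in a single Caribbean specimen")
  )
  new_marker_db(templates, markers, SEA_TURTLE_SPECIES, SEA_TURTLE_GENUS_MAP)
}

#' Read a marker database from FASTA + metadata TSV
#'
#' The FASTA headers carry `marker_id|class_id`; the TSV carries columns
#' `marker_id`, `class_id`, `sequence`, then one 0/1 column per species.
#' Lowercase sequence letters are accepted and uppercased (with a message).
#'
#' @param fasta_path Path to the marker FASTA.
#' @param metadata_tsv_path Path to the metadata TSV.
#' @return A validated `marker_db`.
#' @seealso [write_marker_db()]
#' @export
load_marker_db <- function(fasta_path, metadata_tsv_path) {
  seqs <- tryCatch(Biostrings::readAAStringSet(fasta_path),
                   error = function(e) stop("malformed FASTA '", fasta_path,
                                            "': ", conditionMessage(e)))
  ids <- sub("\\|.*$", "", names(seqs))
  fa <- tibble::tibble(marker_id = ids, fasta_seq = as.character(seqs))
  raw <- readLines(fasta_path, warn = FALSE)
  if (any(grepl("[a-z]", raw[!startsWith(raw, ">")]))) {
    message("lowercase residues uppercased in FASTA records of ", fasta_path)
  }
  fa$fasta_seq <- toupper(fa$fasta_seq)
  meta <- readr::read_tsv(metadata_tsv_path, show_col_types = FALSE,
                          progress = FALSE)
  required <- c("marker_id", "class_id", "sequence")
  if (!all(required %in% names(meta))) {
    stop("metadata TSV lacks required column(s): ",
         paste(setdiff(required, names(meta)), collapse = ", "))
  }
  species_cols <- setdiff(names(meta), required)
  mk <- dplyr::left_join(meta, fa, by = "marker_id")
  if (any(is.na(mk$fasta_seq))) {
    stop("metadata rows without FASTA record: ",
         paste(mk$marker_id[is.na(mk$fasta_seq)], collapse = ", "))
  }
  if (any(toupper(mk$sequence) != mk$fasta_seq)) {
    stop("FASTA/TSV sequence disagreement for: ",
         paste(mk$marker_id[toupper(mk$sequence) != mk$fasta_seq],
               collapse = ", "))
  }
  markers <- tibble::tibble(
    marker_id = mk$marker_id,
    class_id  = mk$class_id,
    sequence  = toupper(mk$sequence),
    species_validated = lapply(seq_len(nrow(mk)), function(i) {
      species_cols[as.logical(unlist(mk[i, species_cols]))]
    }),
    notes = ""
  )
  template <- bundled_marker_db()
  new_marker_db(template$templates, markers, species_cols,
                SEA_TURTLE_GENUS_MAP[species_cols])
}

#' Write a marker database to FASTA + metadata TSV
#'
#' @param db A `marker_db`.
#' @param fasta_path,metadata_tsv_path Output paths.
#' @return `db`, invisibly.
#' @export
write_marker_db <- function(db, fasta_path, metadata_tsv_path) {
  seqs <- Biostrings::AAStringSet(db$markers$sequence)
  names(seqs) <- paste(db$markers$marker_id, db$markers$class_id, sep = "|")
  Biostrings::writeXStringSet(seqs, fasta_path)
  flags <- vapply(db$species, function(sp) {
    as.integer(vapply(db$markers$species_validated, function(v) sp %in% v,
                      logical(1)))
  }, integer(nrow(db$markers)))
  meta <- tibble::as_tibble(cbind(
    db$markers[, c("marker_id", "class_id", "sequence")],
    as.data.frame(matrix(flags, nrow = nrow(db$markers),
                         dimnames = list(NULL, db$species)))
  ))
  readr::write_tsv(meta, metadata_tsv_path, progress = FALSE)
  invisible(db)
}

#' Merge a supplementary marker table into a database
#'
#' Ingests a marker TSV (columns `marker_id`, `class_id`, `sequence`, then
#' one 0/1 column per species) such as an electronic supplementary marker
#' inventory, merging it into `db`. Duplicate marker ids are resolved in
#' favour of the incoming rows (with a message).
#'
#' @param tsv_path Path to the supplementary TSV, or a data frame with the
#'   same columns.
#' @param db The `marker_db` to merge into.
#' @return The merged, validated `marker_db`.
#' @export
import_supplementary_markers <- function(tsv_path, db) {
  inc <- if (is.data.frame(tsv_path)) {
    tibble::as_tibble(tsv_path)
  } else {
    readr::read_tsv(tsv_path, show_col_types = FALSE, progress = FALSE)
  }
  if (nrow(inc) == 0) return(db)
  required <- c("marker_id", "class_id", "sequence")
  if (!all(required %in% names(inc))) {
    stop("supplementary table lacks required column(s): ",
         paste(setdiff(required, names(inc)), collapse = ", "))
  }
  species_cols <- intersect(names(inc), db$species)
  incoming <- tibble::tibble(
    marker_id = inc$marker_id,
    class_id  = inc$class_id,
    sequence  = toupper(inc$sequence),
    species_validated = lapply(seq_len(nrow(inc)), function(i) {
      species_cols[as.logical(unlist(inc[i, species_cols]))]
    }),
    notes = ""
  )
  dup <- intersect(incoming$marker_id, db$markers$marker_id)
  if (length(dup) > 0) {
    message("replacing ", length(dup), " existing marker(s): ",
            paste(dup, collapse = ", "))
  }
  markers <- dplyr::bind_rows(
    db$markers[!db$markers$marker_id %in% dup, ],
    incoming
  )
  new_marker_db(db$templates, markers, db$species, db$genus_map)
}

#' Species validated for each marker, as a named list
#' @param db A `marker_db`.
#' @return Named list marker_id -> character vector of species.
#' @export
marker_species <- function(db) {
  setNames(db$markers$species_validated, db$markers$marker_id)
}
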