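#' Synthetic reference marker panel (stand-in for the full validated inventory)
#'
#' The complete validated marker inventory for the five sea turtle species
#' (187 peptide sequences) is distributed only as electronic supplementary
#' material of the originating study and is not bundled here. This function
#' deterministically constructs a *synthetic* stand-in panel whose
#' bookkeeping structure reproduces every published count:
#'
#' * 187 markers in total; 34 class A, 53 class B, 47 class E4a;
#' * 33 markers validated in all five species, 56 across all four genera;
#' * species-unique markers: *E. imbricata* 20, *C. mydas* 19,
#'   *C. caretta* 17, *L. olivacea* 15, *L. kempii* 2 (both E4b);
#' * 21 markers shared exclusively by *E. imbricata*, *C. caretta* and
#'   *Lepidochelys*; 7 by *C. mydas*, *C. caretta* and *Lepidochelys*;
#' * 124 markers validated in *E. imbricata* in total.
#'
#' The five individually published sequences (C-2, C-8, E2c-4, E4a-19.1,
#' E1-7) are included verbatim with their true species assignment; all other
#' sequences are derived from the class templates by substituting wildcard
#' positions (never K/R, which would create internal tryptic sites, and
#' never I, which is indistinguishable from L in mass spectra). The panel is
#' therefore suitable for exercising marker-set algebra, species assignment
#' and the synthetic PSM generator, but its non-published sequences are not
#' real turtle peptides.
#'
#' @return A tibble with columns `marker_id`, `class_id`, `sequence`, and
#'   one 0/1 column per species, ready for [import_supplementary_markers()].
#' @examples
#' panel <- synthetic_reference_panel()
#' nrow(panel)  # 187
#' @export
synthetic_reference_panel <- function() {
  SP <- c(CM = "Chelonia mydas", CC = "Caretta caretta",
          EI = "Eretmochelys imbricata", LO = "Lepidochelys olivacea",
          LK = "Lepidochelys kempii")
  groups <- list(
    G1     = c("CM", "CC", "EI", "LO", "LK"),
    G2a    = c("CM", "CC", "EI", "LO"),
    G2b    = c("CM", "CC", "EI", "LK"),
    G3a    = c("CC", "EI", "LO"),
    G3b    = c("CC", "EI", "LO", "LK"),
    G4     = c("CM", "CC", "LO"),
    U_EI   = "EI", U_CM = "CM", U_CC = "CC", U_LO = "LO", U_LK = "LK",
    P_EICC = c("EI", "CC"), P_EILO = c("EI", "LO"),
    P_EICM = c("EI", "CM"), P_CCLO = c("CC", "LO")
  )
  # class, group, number of synthetic markers in that (class, group) cell
  alloc <- tibble::tribble(
    ~class, ~group,   ~n,
    "A",    "G1",     10L, "A",   "G2a",  6L, "A",   "G2b",  1L,
    "A",    "G3a",     4L, "A",   "G3b",  2L, "A",   "G4",   2L,
    "A",    "U_EI",    1L, "A",   "P_EICC", 3L, "A", "P_EILO", 3L,
    "A",    "P_EICM",  2L,
    "B",    "G1",     12L, "B",   "G2a",  8L, "B",   "G2b",  1L,
    "B",    "G3a",     6L, "B",   "G3b",  2L, "B",   "G4",   3L,
    "B",    "U_EI",    1L, "B",   "U_CM", 6L, "B",   "U_CC", 6L,
    "B",    "U_LO",    2L, "B",   "P_EICC", 3L, "B", "P_EILO", 2L,
    "B",    "P_EICM",  1L,
    "C",    "G1",      3L, "C",   "U_CM", 3L,
    "D",    "G1",      4L,
    "E1",   "G1",      2L, "E1",  "G3a",  2L, "E1",  "G4",   1L,
    "E1",   "P_CCLO",  1L,
    "E2a",  "U_CM",    2L,
    "E2b",  "G2a",     1L, "E2b", "G3a",  1L, "E2b", "G3b",  1L,
    "E2b",  "U_LO",    2L, "E2b", "P_CCLO", 2L,
    "E2c",  "G2a",     1L, "E2c", "G3a",  1L, "E2c", "G4",   1L,
    "E2c",  "P_EICM",  1L,
    "E2d",  "G2a",     1L, "E2d", "G3a",  1L, "E2d", "P_EICC", 1L,
    "E2d",  "P_EILO",  1L,
    "E3",   "G2a",     2L, "E3",  "G3b",  1L, "E3",  "P_EICC", 1L,
    "E3",   "P_EILO",  1L, "E3",  "P_EICM", 1L,
    "E4a",  "U_EI",   11L, "E4a", "U_CM", 8L, "E4a", "U_CC", 10L,
    "E4a",  "U_LO",   10L, "E4a", "P_EICC", 2L, "E4a", "P_EILO", 3L,
    "E4a",  "P_EICM",  2L,
    "E4b",  "U_EI",    2L, "E4b", "U_CC", 1L, "E4b", "U_LO", 1L,
    "E4b",  "U_LK",    2L,
    "F",    "G1",      2L, "F",   "G2a",  1L, "F",   "G2b",  1L
  )
  real <- bundled_marker_db()$markers
  real_group <- "U_EI"  # all five published markers are E. imbricata-unique

  tpl <- setNames(bundled_marker_db()$templates$template,
                  bundled_marker_db()$templates$class_id)
  # substitution alphabet for wildcard positions: no K/R, no I (see docs)
  alph <- setdiff(AA20, c("K", "R", "I"))

  variant_seq <- function(class, i) {
    # deterministic i-th sequence variant of a class template
    if (class == "C") {
      # terminal wildcard must stay tryptic (R or K); extra variation at
      # position 6 when the two terminal choices are exhausted
      ch <- strsplit(tpl[["C"]], "")[[1]]
      ch[10] <- c("R", "K")[(i - 1) %% 2 + 1]
      ch[6] <- alph[(i - 1) %/% 2 + 1]
      return(paste(ch, collapse = ""))
    }
    if (class == "D") {
      # no wildcards; vary at the positions where substitutions were seen
      ch <- strsplit(tpl[["D"]], "")[[1]]
      ch[12] <- alph[i]
      return(paste(ch, collapse = ""))
    }
    template <- switch(class,
      E4a = if (i %% 5 == 0) tpl[["E4a_short"]] else tpl[["E4a_long"]],
      tpl[[class]]
    )
    ch <- strsplit(template, "")[[1]]
    xpos <- which(ch == "X")
    idx <- i - 1L
    for (p in xpos) {
      ch[p] <- alph[idx %% length(alph) + 1L]
      idx <- idx %/% length(alph)
    }
    paste(ch, collapse = "")
  }

  counter <- new.env()
  rows <- list()
  seen_seqs <- real$sequence
  next_variant <- new.env()
  for (r in seq_len(nrow(alloc))) {
    cl <- alloc$class[r]; gr <- alloc$group[r]; n <- alloc$n[r]
    for (k in seq_len(n)) {
      # skip ids taken by the published markers of this class
      repeat {
        id_n <- (get0(cl, counter, inherits = FALSE) %||% 0L) + 1L
        assign(cl, id_n, counter)
        mid <- paste0(cl, "-", id_n)
        if (!mid %in% real$marker_id) break
      }
      cm_in <- "CM" %in% groups[[gr]]
      repeat {
        vi <- (get0(cl, next_variant, inherits = FALSE) %||% 0L) + 1L
        assign(cl, vi, next_variant)
        sq <- variant_seq(cl, vi)
        # the 25-residue E4a form is absent from C. mydas
        if (cl == "E4a" && cm_in && nchar(sq) == 25L) next
        if (!sq %in% seen_seqs) break
      }
      seen_seqs <- c(seen_seqs, sq)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        marker_id = mid, class_id = cl, sequence = sq, group = gr
      )
    }
  }
  synth <- dplyr::bind_rows(rows)
  panel <- dplyr::bind_rows(
    tibble::tibble(marker_id = real$marker_id, class_id = real$class_id,
                   sequence = real$sequence, group = real_group),
    synth
  )
  for (ab in names(SP)) {
    panel[[SP[[ab]]]] <- vapply(panel$group, function(g) {
      as.integer(ab %in% groups[[g]])
    }, integer(1))
  }
  panel$group <- NULL
  panel
}

#' Bundled database enriched with the synthetic reference panel
#'
#' Convenience wrapper: [bundled_marker_db()] with the 187-marker
#' [synthetic_reference_panel()] merged in.
#'
#' @return A `marker_db` with 187 markers.
#' @export
synthetic_panel_db <- function() {
  suppressMessages(
    import_supplementary_markers(synthetic_reference_panel(),
                                 bundled_marker_db())
  )
}
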