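#' Match a peptide against a wildcard class template
#'
#' Position-by-position comparison of a peptide with a template over the 20
#' amino-acid letters plus `X` (any residue). Peptides of a different length
#' never match. With `il_equivalent` (the default elsewhere in the package),
#' leucine and isoleucine are interchangeable at non-wildcard positions,
#' since the two isomers cannot be told apart by mass.
#'
#' @param peptide Uppercase amino-acid string.
#' @param template Uppercase string over the amino-acid letters plus `X`.
#' @param il_equivalent Treat I and L as equivalent at non-X positions.
#' @param max_mismatch Maximum number of substitutions tolerated at non-X
#'   positions for the peptide to count as matched.
#' @return A list with `matched` (logical), `mismatch_positions` (1-based,
#'   non-X positions only) and `wildcard_assignments` (named integer-keyed
#'   list of the residues observed at X positions).
#' @examples
#' match_template("QCQDSEVVIR", "QCPDSEVVIX")  # one substitution, matched
#' @export
match_template <- function(peptide, template, il_equivalent = TRUE,
                           max_mismatch = 2L) {
  stopifnot(is.character(peptide), length(peptide) == 1L, nzchar(peptide),
            is.character(template), length(template) == 1L, nzchar(template))
  pc <- strsplit(peptide, "")[[1]]
  tc <- strsplit(template, "")[[1]]
  if (!all(pc %in% AA20)) {
    stop("illegal peptide character(s): ",
         paste(unique(pc[!pc %in% AA20]), collapse = ", "))
  }
  if (!all(tc %in% c(AA20, "X"))) {
    stop("illegal template character(s): ",
         paste(unique(tc[!tc %in% c(AA20, "X")]), collapse = ", "))
  }
  if (length(pc) != length(tc)) {
    return(list(matched = FALSE, mismatch_positions = integer(0),
                wildcard_assignments = list()))
  }
  wild <- tc == "X"
  p <- pc; t <- tc
  if (il_equivalent) {
    p[p == "I"] <- "L"
    t[t == "I"] <- "L"
  }
  mismatch <- which(!wild & p != t)
  wa <- as.list(pc[wild])
  names(wa) <- which(wild)
  list(matched = length(mismatch) <= max_mismatch,
       mismatch_positions = mismatch,
       wildcard_assignments = wa)
}

#' Assign a peptide to a CBP class by template inference
#'
#' Evaluates all class templates of compatible length and assigns the class
#' with the fewest substitutions at non-wildcard positions (within
#' `max_mismatch`). Ties on mismatch count are broken by the fixed class
#' order A, B, C, D, E1, E2a, E2b, E2c, E2d, E3, E4a, E4b, F and flagged as
#' ambiguous: the glycine-repeat region produces short peptides that can fit
#' several locations. Curated class labels on database markers are
#' authoritative; this inference is meant for unlabelled or novel peptides.
#'
#' @param peptide Uppercase amino-acid string.
#' @param db A `marker_db` supplying the templates.
#' @param max_mismatch Substitution budget (default 2, the largest count
#'   observed among validated markers relative to their template).
#' @param il_equivalent Treat I and L as equivalent.
#' @return A list with `class_id` (reporting class, or `NA`),
#'   `mismatch_count`, `ambiguous`, and `candidates` (tibble of all
#'   length-compatible templates with their mismatch counts).
#' @export
classify_peptide <- function(peptide, db, max_mismatch = 2L,
                             il_equivalent = TRUE) {
  tl <- db$templates
  len_ok <- nchar(tl$template) == nchar(peptide)
  if (!any(len_ok)) {
    return(list(class_id = NA_character_, mismatch_count = NA_integer_,
                ambiguous = FALSE,
                candidates = tibble::tibble(class_id = character(0),
                                            mismatch_count = integer(0))))
  }
  cand <- tl[len_ok, ]
  mm <- vapply(cand$template, function(t) {
    r <- match_template(peptide, t, il_equivalent = il_equivalent,
                        max_mismatch = nchar(peptide))
    length(r$mismatch_positions)
  }, integer(1))
  candidates <- tibble::tibble(
    class_id = reporting_class(cand$class_id),
    mismatch_count = unname(mm)
  )
  hits <- candidates[candidates$mismatch_count <= max_mismatch, ]
  if (nrow(hits) == 0) {
    return(list(class_id = NA_character_, mismatch_count = NA_integer_,
                ambiguous = FALSE, candidates = candidates))
  }
  best <- hits[hits$mismatch_count == min(hits$mismatch_count), ]
  tied_classes <- unique(best$class_id)
  pick <- tied_classes[order(match(tied_classes, CLASS_ORDER))][1]
  list(class_id = pick,
       mismatch_count = min(best$mismatch_count),
       ambiguous = length(tied_classes) > 1,
       candidates = candidates)
}

#' In-silico tryptic digestion
#'
#' Enumerates tryptic peptides of a protein. Cleavage occurs after K or R;
#' by default also before proline (`cleave_before_proline = FALSE` enables
#' the classical no-cleavage-before-P variant). In `"specific"` mode both
#' termini must be tryptic junctions (preceded by K/R or the protein
#' N-terminus; ending in K/R or at the protein C-terminus); in
#' `"semispecific"` mode one terminus may be non-tryptic. Missed cleavages
#' count internal cleavage sites spanned by the peptide.
#'
#' @param protein Uppercase amino-acid string.
#' @param mode `"specific"` or `"semispecific"`.
#' @param missed_cleavages Maximum internal cleavage sites (default 1).
#' @param min_len,max_len Peptide length bounds (defaults 6 and 45).
#' @param cleave_before_proline Cleave K/R-P bonds (default `TRUE`).
#' @return A tibble with one row per distinct peptide position:
#'   `sequence`, `start`, `end` (1-based inclusive), `prev_residue`,
#'   `next_residue` (`"-"` at protein termini), `n_missed`, `specificity`
#'   (`fully_tryptic`, `semi_N` = non-tryptic N-terminus, `semi_C` =
#'   non-tryptic C-terminus).
#' @export
digest <- function(protein, mode = c("semispecific", "specific"),
                   missed_cleavages = 1L, min_len = 6L, max_len = 45L,
                   cleave_before_proline = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is.character(protein), length(protein) == 1L, nzchar(protein))
  ch <- strsplit(protein, "")[[1]]
  if (!all(ch %in% AA20)) stop("illegal residue(s) in protein")
  n <- length(ch)
  # cleavage site after position i
  is_site <- ch %in% c("K", "R")
  if (!cleave_before_proline) {
    nxt <- c(ch[-1], "")
    is_site <- is_site & nxt != "P"
  }
  is_site[n] <- FALSE  # cleavage after the last residue is the C-terminus
  sites <- which(is_site)
  n_tryp <- function(i) i == 1L | (i - 1L) %in% sites
  c_tryp <- function(j) j == n | j %in% sites

  out <- list()
  for (i in seq_len(n)) {
    j_max <- min(n, i + max_len - 1L)
    j_min <- i + min_len - 1L
    if (j_min > n) next
    for (j in j_min:j_max) {
      nt <- n_tryp(i); ct <- c_tryp(j)
      if (mode == "specific" && !(nt && ct)) next
      if (mode == "semispecific" && !(nt || ct)) next
      missed <- sum(sites >= i & sites < j)
      if (missed > missed_cleavages) next
      spec <- if (nt && ct) "fully_tryptic" else if (ct) "semi_N" else "semi_C"
      out[[length(out) + 1L]] <- list(
        sequence = substr(protein, i, j), start = i, end = j,
        prev_residue = if (i == 1L) "-" else ch[i - 1L],
        next_residue = if (j == n) "-" else ch[j + 1L],
        n_missed = missed, specificity = spec
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(sequence = character(0), start = integer(0),
                          end = integer(0), prev_residue = character(0),
                          next_residue = character(0), n_missed = integer(0),
                          specificity = character(0)))
  }
  dplyr::bind_rows(out)
}

# Align a peptide inside a marker sequence: exact substring first, then a
# single-offset scan allowing <= max_mismatch substitutions. Returns the
# 1-based offset, or NA when there is no (unique) alignment.
align_to_marker <- function(peptide, marker_seq, max_mismatch = 2L) {
  lp <- nchar(peptide); lm <- nchar(marker_seq)
  if (lp > lm) return(NA_integer_)
  pc <- strsplit(peptide, "")[[1]]
  mc <- strsplit(marker_seq, "")[[1]]
  offs <- seq_len(lm - lp + 1L)
  mism <- vapply(offs, function(o) sum(pc != mc[o:(o + lp - 1L)]), integer(1))
  exact <- offs[mism == 0L]
  if (length(exact) == 1L) return(exact)
  if (length(exact) > 1L) return(NA_integer_)
  best <- min(mism)
  if (best > max_mismatch) return(NA_integer_)
  hit <- offs[mism == best]
  if (length(hit) == 1L) hit else NA_integer_
}

#' Cleavage status of a PSM peptide relative to its marker
#'
#' Classifies each terminus of an observed peptide as tryptic-"determined"
#' or not, relative to the canonical boundaries of the marker it belongs to.
#' A terminus is determined when it coincides with the marker's boundary on
#' a side the class template marks as tryptic, or, when flanking residues
#' are available, when the N-side follows K/R (or the protein N-terminus
#' `"-"`) and the C-side ends in K/R (or sits at the protein C-terminus).
#' Peptides with no unique alignment to the marker are `"undetermined"`,
#' the degradation proxy used for ancient samples: hydrolytic damage
#' produces random, non-tryptic cleavage.
#'
#' @param psm_peptide Observed peptide sequence.
#' @param marker_seq Marker sequence the peptide is assigned to.
#' @param tryptic_termini The marker class's expected termini
#'   (`"N_only"`, `"C_only"`, `"N_and_C"`).
#' @param prev_residue,next_residue Optional flanking residues (`"-"` for
#'   protein termini, `NA` when unknown).
#' @param max_mismatch Alignment substitution budget.
#' @return One of `"determined"` (both ends), `"semi"` (one end),
#'   `"undetermined"` (neither end, or no unique alignment).
#' @export
cleavage_status <- function(psm_peptide, marker_seq, tryptic_termini,
                            prev_residue = NA_character_,
                            next_residue = NA_character_,
                            max_mismatch = 2L) {
  off <- align_to_marker(psm_peptide, marker_seq, max_mismatch)
  if (is.na(off)) {
    warning("peptide not uniquely alignable to marker; status undetermined")
    return("undetermined")
  }
  lp <- nchar(psm_peptide)
  start <- off
  end <- off + lp - 1L
  n_marked <- tryptic_termini %in% c("N_only", "N_and_C")
  c_marked <- tryptic_termini %in% c("C_only", "N_and_C")
  last_res <- substr(psm_peptide, lp, lp)
  n_det <- (start == 1L && n_marked) ||
    (!is.na(prev_residue) && prev_residue %in% c("K", "R", "-"))
  c_det <- (end == nchar(marker_seq) && c_marked) ||
    last_res %in% c("K", "R") ||
    (!is.na(next_residue) && next_residue == "-")
  if (n_det && c_det) "determined" else if (n_det || c_det) "semi"
  else "undetermined"
}

# Cleavage call from flanking evidence alone (peptides without a marker).
cleavage_status_flanks <- function(peptide, prev_residue, next_residue) {
  if (is.na(prev_residue) || is.na(next_residue)) return("undetermined")
  lp <- nchar(peptide)
  n_det <- prev_residue %in% c("K", "R", "-")
  c_det <- substr(peptide, lp, lp) %in% c("K", "R") || next_residue == "-"
  if (n_det && c_det) "determined" else if (n_det || c_det) "semi"
  else "undetermined"
}

# Monoisotopic residue masses (Da).
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)
WATER_MASS <- 18.010565

# Named modification mass deltas (Da).
MOD_DELTAS <- c(
  Carbamidomethyl = 57.02146,
  Oxidation       = 15.99491,
  Dioxidation     = 31.98983,
  Phosphorylation = 79.96633,
  Deamidation     = 0.98402,
  Pyroglutamate   = -17.02655
)

mod_delta <- function(name) {
  i <- match(tolower(name), tolower(names(MOD_DELTAS)))
  if (anyNA(i)) {
    stop("unknown modification name(s): ",
         paste(unique(name[is.na(i)]), collapse = ", "))
  }
  unname(MOD_DELTAS[i])
}

#' Monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus one water, plus any modification
#' mass deltas. Named deltas: carbamidomethyl +57.02146, oxidation
#' +15.99491, dioxidation +31.98983, phosphorylation +79.96633, deamidation
#' +0.98402, pyroglutamate -17.02655.
#'
#' @param sequence Uppercase amino-acid string.
#' @param modifications Optional list of `(position, delta)` pairs, or a
#'   data frame with columns `pos` and `delta`.
#' @return Mass in Da.
#' @examples
#' peptide_mass("GG")  # 132.0535
#' @export
peptide_mass <- function(sequence, modifications = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty peptide")
  ch <- strsplit(sequence, "")[[1]]
  if (!all(ch %in% names(RESIDUE_MASS))) {
    stop("illegal residue(s): ",
         paste(unique(ch[!ch %in% names(RESIDUE_MASS)]), collapse = ", "))
  }
  m <- sum(RESIDUE_MASS[ch]) + WATER_MASS
  if (!is.null(modifications)) {
    if (is.data.frame(modifications)) {
      pos <- modifications$pos; delta <- modifications$delta
    } else {
      pos <- vapply(modifications, `[[`, numeric(1), 1)
      delta <- vapply(modifications, `[[`, numeric(1), 2)
    }
    if (any(pos < 1 | pos > length(ch))) {
      stop("modification position out of range")
    }
    m <- m + sum(delta)
  }
  m
}
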