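# Independent brute-force oracles and small in-code fixtures.

# Tryptic digestion oracle: enumerate every substring, filter by junction
# rules, missed-cleavage count and length bounds. Written independently of
# digest()'s site-list generation.
oracle_digest <- function(protein, mode, missed_cleavages, min_len, max_len,
                          cleave_before_proline = TRUE) {
  ch <- strsplit(protein, "")[[1]]
  n <- length(ch)
  cuts_after <- function(k) {
    # is there a cleavage between k and k+1? (k < n)
    ch[k] %in% c("K", "R") && (cleave_before_proline || ch[k + 1] != "P")
  }
  rows <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      len <- j - i + 1
      if (len < min_len || len > max_len) next
      nt <- i == 1 || cuts_after(i - 1)
      ct <- j == n || cuts_after(j)
      keep <- if (mode == "specific") nt && ct else nt || ct
      if (!keep) next
      internal <- if (j - 1 >= i) sum(vapply(i:(j - 1), cuts_after,
                                             logical(1))) else 0L
      if (internal > missed_cleavages) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(protein, i, j), start = i, end = j,
        n_missed = internal,
        specificity = if (nt && ct) "fully_tryptic" else if (ct) "semi_N"
                      else "semi_C",
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), n_missed = integer(0),
                      specificity = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), ]
}

random_protein <- function(n) {
  paste(sample(cbpid:::AA20, n, replace = TRUE), collapse = "")
}

# Toy database: bundled templates/species plus two extra markers with known
# species validation, for set-algebra checks.
toy_db <- function() {
  extra <- data.frame(
    marker_id = c("T-1", "T-2"),
    class_id = c("E4b", "E4b"),
    sequence = c("YGGAAGYR", "YGGDDGYR"),
    check.names = FALSE
  )
  extra[["Chelonia mydas"]] <- c(1L, 1L)
  extra[["Caretta caretta"]] <- c(0L, 1L)
  extra[["Eretmochelys imbricata"]] <- c(0L, 0L)
  extra[["Lepidochelys olivacea"]] <- c(0L, 0L)
  extra[["Lepidochelys kempii"]] <- c(0L, 0L)
  suppressMessages(import_supplementary_markers(extra, bundled_marker_db()))
}

# Minimal single-sample cohort built directly from vectors.
make_cohort <- function(sample, peptide, score, mods = NULL,
                        prev = NA_character_, nxt = NA_character_) {
  n <- length(peptide)
  tibble::tibble(
    sample = rep_len(sample, n), peptide = peptide, score = score,
    mods = mods %||% parse_mods(rep("", n)),
    prev_residue = rep_len(prev, n), next_residue = rep_len(nxt, n),
    marker_id = NA_character_, class_id = NA_character_,
    cleavage = NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
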