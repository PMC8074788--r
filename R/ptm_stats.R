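#' Count potential oxidation sites
#'
#' Oxidation and dioxidation in degraded scute keratin concentrate on
#' proline, tyrosine, histidine and tryptophan; the number of potential
#' sites of a sequence is its count of P, Y, H and W residues.
#'
#' @param sequence Character vector of amino-acid strings.
#' @return Integer vector of site counts.
#' @examples
#' potential_sites("AGYGGLGGYLGGYGYGGGLAGSGVSAHR")  # 5
#' @export
potential_sites <- function(sequence) {
  stringr::str_count(sequence, "[PYHW]")
}

#' Oxidation and dioxidation site-occupancy percentages
#'
#' For each (marker, sample) pair the number of potential sites of the
#' marker is multiplied by its PSM count, giving the total number of
#' opportunities for oxidation; the numerators count site-level
#' observations of oxidation (+15.99 Da) and dioxidation (+31.99 Da) on
#' P/Y/H/W residues (a PSM with two oxidized residues contributes two).
#' Oxidation observed on other residues (e.g. methionine) is excluded from
#' both numerator and denominator and reported in the `n_ox_other` column.
#' Classes default to A, B and E4a, which carry the large majority of the
#' oxidative modifications.
#'
#' @param cohort A marker-assigned `psm_cohort`.
#' @param db A `marker_db`.
#' @param classes Reporting classes included (default `c("A","B","E4a")`).
#' @param group_by `"genus"`, `"species"` or `"sample"`. Genus/species
#'   grouping requires sample metadata (`sample_meta` attribute or the
#'   `sample_meta` argument) mapping samples to species.
#' @param sample_meta Optional tibble with columns `sample`, `species`.
#' @return A tibble per group: `percent_oxidation`, `percent_dioxidation`,
#'   `potential_sites`, `observed_ox_sites`, `observed_diox_sites`,
#'   `n_ox_other`, and across-specimen standard deviations `sd_oxidation`,
#'   `sd_dioxidation`.
#' @export
oxidation_percentages <- function(cohort, db, classes = c("A", "B", "E4a"),
                                  group_by = c("genus", "species", "sample"),
                                  sample_meta = NULL) {
  group_by <- match.arg(group_by)
  sample_meta <- sample_meta %||% attr(cohort, "sample_meta")
  mk <- db$markers
  sites_of <- setNames(potential_sites(mk$sequence), mk$marker_id)
  sel <- !is.na(cohort$marker_id) &
    mk$class_id[match(cohort$marker_id, mk$marker_id)] %in% classes
  df <- cohort[sel, ]
  if (nrow(df) == 0) return(tibble::tibble())

  per_psm <- lapply(seq_len(nrow(df)), function(i) {
    m <- df$mods[[i]]
    res <- strsplit(df$peptide[i], "")[[1]]
    oxidative <- tolower(m$name) %in% c("oxidation", "dioxidation")
    on_site <- oxidative & res[m$pos] %in% c("P", "Y", "H", "W")
    c(ox = sum(on_site & tolower(m$name) == "oxidation"),
      diox = sum(on_site & tolower(m$name) == "dioxidation"),
      other = sum(oxidative & !on_site))
  })
  counts <- do.call(rbind, per_psm)
  per_sample <- tibble::tibble(
    sample = df$sample,
    potential = unname(sites_of[df$marker_id]),
    ox = counts[, "ox"], diox = counts[, "diox"], other = counts[, "other"]
  ) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(potential = sum(.data$potential), ox = sum(.data$ox),
                     diox = sum(.data$diox), other = sum(.data$other),
                     .groups = "drop")

  grp <- switch(group_by,
    sample = per_sample$sample,
    {
      if (is.null(sample_meta)) {
        stop("grouping by ", group_by, " requires sample metadata")
      }
      sp <- sample_meta$species[match(per_sample$sample, sample_meta$sample)]
      if (group_by == "genus") unname(db$genus_map[sp]) else sp
    }
  )
  per_sample$group <- grp
  per_sample |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      percent_oxidation = 100 * sum(.data$ox) / sum(.data$potential),
      percent_dioxidation = 100 * sum(.data$diox) / sum(.data$potential),
      potential_sites = sum(.data$potential),
      observed_ox_sites = sum(.data$ox),
      observed_diox_sites = sum(.data$diox),
      n_ox_other = sum(.data$other),
      sd_oxidation = sd(100 * .data$ox / .data$potential),
      sd_dioxidation = sd(100 * .data$diox / .data$potential),
      n_specimens = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::rename(!!group_by := "group")
}

#' Phosphoserine motif summary
#'
#' Tallies phosphorylation (+79.97 Da) on serine residues by the residue
#' immediately following the serine and by C-terminal context: serines
#' inside a `SAHR` suffix motif are frequently phosphorylated in these
#' proteins, serines in `SCHR` are not. Occurrence counts of serines in
#' each context are reported alongside, so occupancy can be computed.
#'
#' @param cohort A `psm_cohort`.
#' @return A list with `by_context` (tibble: context `SAHR`/`SCHR`/`other`,
#'   `n_serine`, `n_phospho`) and `by_next_residue` (tibble: residue after
#'   the phosphoserine, count).
#' @export
phospho_motif_summary <- function(cohort) {
  ctx_of <- function(peptide, pos) {
    frag <- substr(peptide, pos, pos + 3L)
    if (frag == "SAHR") "SAHR" else if (frag == "SCHR") "SCHR" else "other"
  }
  ser <- list(); pho <- list()
  for (i in seq_len(nrow(cohort))) {
    pep <- cohort$peptide[i]
    res <- strsplit(pep, "")[[1]]
    spos <- which(res == "S")
    if (length(spos) > 0) {
      ser[[length(ser) + 1L]] <- vapply(spos, ctx_of, character(1),
                                        peptide = pep)
    }
    m <- cohort$mods[[i]]
    ppos <- m$pos[tolower(m$name) %in% c("phosphorylation", "phospho") &
                    res[m$pos] == "S"]
    if (length(ppos) > 0) {
      pho[[length(pho) + 1L]] <- tibble::tibble(
        context = vapply(ppos, ctx_of, character(1), peptide = pep),
        next_residue = ifelse(ppos < nchar(pep),
                              substr(pep, ppos + 1L, ppos + 1L), "-")
      )
    }
  }
  ser_all <- unlist(ser) %||% character(0)
  pho_all <- if (length(pho) > 0) dplyr::bind_rows(pho) else
    tibble::tibble(context = character(0), next_residue = character(0))
  contexts <- c("SAHR", "SCHR", "other")
  by_context <- tibble::tibble(
    context = contexts,
    n_serine = unname(vapply(contexts, function(cx) sum(ser_all == cx),
                             integer(1))),
    n_phospho = unname(vapply(contexts, function(cx) sum(pho_all$context == cx),
                              integer(1)))
  )
  by_next <- pho_all |>
    dplyr::count(.data$next_residue, name = "n_phospho")
  list(by_context = by_context, by_next_residue = by_next)
}
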