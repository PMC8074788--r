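#' Synthetic PSM generator configuration
#'
#' Bundles the generative parameters for one species' specimens. The
#' defaults emulate the study conditions of well-preserved modern scute
#' keratin; `d` moves a specimen towards the archaeological regime:
#' class-biased marker loss (E4a/E4b fastest, then A), score depression,
#' more non-tryptic termini, loss of the alpha-keratin background.
#'
#' @param species Species label (must be in the database).
#' @param n_specimens Number of specimens to simulate.
#' @param d Degradation fraction in \[0, 1\] (0 = modern reference).
#' @param base_detect_p Per-marker detection probability at `d = 0`.
#' @param class_weights Named class -> multiplier shaping dropout under
#'   degradation: detection probability is
#'   `base_detect_p * (1 - d * weight)`. Defaults degrade E4a/E4b fastest,
#'   then A, reflecting preferential loss of the matrix-forming termini.
#' @param score_mean,score_sd Normal parameters of the -10lgP score
#'   (truncated at `score_floor`); the mean drops by `5 * d`.
#' @param score_floor Lower truncation of scores (the usual export filter).
#' @param psm_count_mean Mean PSM count per detected marker (a detected
#'   marker emits `1 + Poisson(psm_count_mean - 1)` PSMs).
#' @param u0 Undetermined-cleavage probability at `d = 0`.
#' @param u_slope Increase of that probability with `d`:
#'   `u(d) = u0 * (1 + (u_slope / u0) * d)`.
#' @param p_ox Per-site oxidation probability on P/Y/H/W residues.
#' @param p_diox Per-site dioxidation probability (default `p_ox / 2`).
#' @param p_phospho_SAHR Phosphorylation probability of serines in a SAHR
#'   context.
#' @param p_phospho_SCHR Same for SCHR context (0: never observed there).
#' @param bg_mean Mean count of alpha-keratin background PSMs per specimen
#'   at `d = 0`; scales with `(1 - d)` (these proteins are rapidly lost in
#'   ancient samples).
#' @param seed Optional integer seed; when set, generation is fully
#'   reproducible.
#' @return A `generator_config` list.
#' @export
generator_config <- function(species, n_specimens = 1L, d = 0,
                             base_detect_p = 0.85,
                             class_weights = NULL,
                             score_mean = 45, score_sd = 8, score_floor = 25,
                             psm_count_mean = 4,
                             u0 = 0.30, u_slope = 0.30,
                             p_ox = 0.05, p_diox = NULL,
                             p_phospho_SAHR = 0.5, p_phospho_SCHR = 0,
                             bg_mean = 30, seed = NULL) {
  default_w <- c(A = 0.8, B = 0.5, C = 0.4, D = 0.4, E1 = 0.4, E2a = 0.4,
                 E2b = 0.4, E2c = 0.4, E2d = 0.4, E3 = 0.4, E4a = 1,
                 E4b = 1, F = 0.4)
  if (!is.null(class_weights)) {
    default_w[names(class_weights)] <- class_weights
  }
  p_diox <- p_diox %||% (p_ox / 2)
  cfg <- list(species = species, n_specimens = as.integer(n_specimens),
              d = d, base_detect_p = base_detect_p,
              class_weights = default_w, score_mean = score_mean,
              score_sd = score_sd, score_floor = score_floor,
              psm_count_mean = psm_count_mean, u0 = u0, u_slope = u_slope,
              p_ox = p_ox, p_diox = p_diox,
              p_phospho_SAHR = p_phospho_SAHR,
              p_phospho_SCHR = p_phospho_SCHR,
              bg_mean = bg_mean, seed = seed)
  probs <- c(base_detect_p, u0, u_slope, p_ox, p_diox, p_phospho_SAHR,
             p_phospho_SCHR)
  if (any(probs < 0 | probs > 1) || d < 0 || d > 1) {
    stop("probabilities and d must lie in [0, 1]")
  }
  structure(cfg, class = "generator_config")
}

# Invented non-CBP-like tryptic decoys standing in for the alpha-keratin
# background; lengths avoid every class template length so they never
# classify into a CBP class.
ALPHA_KERATIN_DECOYS <- c(
  "LDNSTAVELTK", "SSEVNDLTAEK", "AQYEDLANQVK", "TNAENEFVALK",
  "QLDSLTNEMAR", "DLNMDNLVEDFVK", "ASYLDNVQALE", "TLNNDFASYLE",
  "NVQALEVELQSQL", "SEMNNLQLALD", "DVDNAYMNLQK", "QNLNDSLMLLK",
  "ESLQEELALLK", "ANLENQLTELR"
)

truncnorm1 <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lower)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

# Trim both termini of a marker so that neither end looks tryptic:
# the residue preceding the new start and the new final residue must not
# be K/R. Returns list(peptide, start, end) or NULL if impossible.
trim_undetermined <- function(marker_seq, min_len = 6L) {
  ch <- strsplit(marker_seq, "")[[1]]
  n <- length(ch)
  for (a in 1:3) {
    for (b in 1:3) {
      start <- 1L + a; end <- n - b
      if (end - start + 1L < min_len) next
      if (ch[start - 1L] %in% c("K", "R")) next
      if (ch[end] %in% c("K", "R")) next
      return(list(peptide = substr(marker_seq, start, end),
                  prev = ch[start - 1L], nxt = ch[end + 1L]))
    }
  }
  NULL
}

draw_mods <- function(peptide, cfg) {
  res <- strsplit(peptide, "")[[1]]
  rows <- list()
  for (p in which(res == "C")) {
    rows[[length(rows) + 1L]] <- list(name = "Carbamidomethyl", pos = p)
  }
  for (p in which(res %in% c("P", "Y", "H", "W"))) {
    u <- runif(1)
    if (u < cfg$p_ox) {
      rows[[length(rows) + 1L]] <- list(name = "Oxidation", pos = p)
    } else if (u < cfg$p_ox + cfg$p_diox) {
      rows[[length(rows) + 1L]] <- list(name = "Dioxidation", pos = p)
    }
  }
  for (p in which(res == "S")) {
    frag <- substr(peptide, p, p + 3L)
    pr <- if (frag == "SAHR") cfg$p_phospho_SAHR
          else if (frag == "SCHR") cfg$p_phospho_SCHR else 0
    if (pr > 0 && runif(1) < pr) {
      rows[[length(rows) + 1L]] <- list(name = "Phosphorylation", pos = p)
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(name = character(0), pos = integer(0),
                          delta = numeric(0)))
  }
  nm <- vapply(rows, `[[`, character(1), "name")
  ps <- vapply(rows, `[[`, numeric(1), "pos")
  tibble::tibble(name = nm, pos = as.integer(ps), delta = mod_delta(nm))
}

#' Generate one synthetic specimen
#'
#' For every marker validated in the configured species: detect with
#' probability `base_detect_p * (1 - d * class_weight)`; if detected, draw
#' a PSM count, scores from a truncated normal (mean shifted down by
#' `5 * d`), per-PSM undetermined-cleavage events with probability
#' `u0 * (1 + (u_slope/u0) * d)` (realized by trimming both termini to
#' non-tryptic positions), per-site oxidation/dioxidation and context-
#' dependent phosphoserine draws, plus carbamidomethylation of every
#' cysteine. Alpha-keratin background PSMs (non-marker decoy peptides,
#' count scaling with `1 - d`) are appended and receive the same
#' undetermined-cleavage probability.
#'
#' @param config A [generator_config()].
#' @param db A `marker_db` containing the species.
#' @param sample_id Sample identifier.
#' @return A list: `cohort` (one-sample `psm_cohort`) and `truth` (list
#'   with the realized detections and per-PSM cleavage truth).
#' @export
generate_specimen <- function(config, db, sample_id) {
  sp <- config$species
  if (!sp %in% db$species) stop("species not in database: ", sp)
  if (!is.null(config$seed)) set.seed(config$seed)
  mk <- db$markers[vapply(db$markers$species_validated,
                          function(v) sp %in% v, logical(1)), ]
  # u0 * (1 + (u_slope/u0) * d), written division-free so u0 = 0 is valid
  u_d <- config$u0 + config$u_slope * config$d
  term_of <- setNames(db$templates$tryptic_termini,
                      reporting_class(db$templates$class_id))

  # flat accumulators (one tibble at the end: cohorts can be large)
  peptide <- character(0); score <- numeric(0); prev <- character(0)
  nxt <- character(0); mods <- list(); marker_truth <- character(0)
  cleavage_truth <- character(0)
  detected <- character(0)
  for (i in seq_len(nrow(mk))) {
    w <- config$class_weights[[mk$class_id[i]]]
    p_det <- config$base_detect_p * (1 - config$d * w)
    if (runif(1) >= p_det) next
    detected <- c(detected, mk$marker_id[i])
    n_psm <- 1L + rpois(1, max(config$psm_count_mean - 1, 0))
    scores <- truncnorm1(n_psm, config$score_mean - 5 * config$d,
                         config$score_sd, config$score_floor)
    n_tryptic <- term_of[[mk$class_id[i]]] %in% c("N_only", "N_and_C")
    for (k in seq_len(n_psm)) {
      undet <- runif(1) < u_d
      if (undet) {
        tr <- trim_undetermined(mk$sequence[i])
        if (is.null(tr)) undet <- FALSE
      }
      if (undet) {
        pep <- tr$peptide; pv <- tr$prev; nx <- tr$nxt
      } else {
        pep <- mk$sequence[i]
        pv <- if (n_tryptic) "R" else "G"
        nx <- "G"
      }
      peptide <- c(peptide, pep); score <- c(score, scores[k])
      prev <- c(prev, pv); nxt <- c(nxt, nx)
      mods[[length(mods) + 1L]] <- draw_mods(pep, config)
      marker_truth <- c(marker_truth, mk$marker_id[i])
      cleavage_truth <- c(cleavage_truth,
                          if (undet) "undetermined" else "tryptic")
    }
  }
  n_bg <- rpois(1, config$bg_mean * (1 - config$d))
  if (n_bg > 0) {
    decoys <- sample(ALPHA_KERATIN_DECOYS, n_bg, replace = TRUE)
    bg_scores <- truncnorm1(n_bg, config$score_mean - 5 * config$d,
                            config$score_sd, config$score_floor)
    no_mods <- tibble::tibble(name = character(0), pos = integer(0),
                              delta = numeric(0))
    for (k in seq_len(n_bg)) {
      undet <- runif(1) < u_d
      pep <- decoys[k]
      if (undet) {
        lp <- nchar(pep)
        # decoys are built without internal K/R, so the trim is non-tryptic
        pv <- substr(pep, 1L, 1L); nx <- substr(pep, lp, lp)
        pep <- substr(pep, 2L, lp - 1L)
      } else {
        pv <- "K"; nx <- "G"
      }
      peptide <- c(peptide, pep); score <- c(score, bg_scores[k])
      prev <- c(prev, pv); nxt <- c(nxt, nx)
      mods[[length(mods) + 1L]] <- no_mods
      marker_truth <- c(marker_truth, NA_character_)
      cleavage_truth <- c(cleavage_truth,
                          if (undet) "undetermined" else "tryptic")
    }
  }
  cohort_df <- tibble::tibble(
    sample = rep(sample_id, length(peptide)), peptide = peptide,
    score = score, mods = mods, prev_residue = prev, next_residue = nxt
  )
  truth <- list(
    sample = sample_id, species = sp, d = config$d,
    detected_markers = detected,
    psms = if (length(peptide) > 0) tibble::tibble(
      sample = rep(sample_id, length(peptide)), peptide = peptide,
      marker_truth = marker_truth, cleavage_truth = cleavage_truth
    ) else NULL,
    config = config
  )
  list(cohort = new_psm_cohort(cohort_df), truth = truth)
}

#' Generate a multi-specimen cohort
#'
#' Runs [generate_specimen()] for each configuration, `n_specimens` times
#' each, with unique sample ids `<species abbrev><index>`. The first
#' config's `seed` (if any) seeds the whole generation.
#'
#' @param configs A `generator_config` or list of them.
#' @param db A `marker_db`.
#' @return A `psm_cohort` with `sample_meta` (sample, species, d) and
#'   `truth` attributes.
#' @export
generate_cohort <- function(configs, db) {
  if (inherits(configs, "generator_config")) configs <- list(configs)
  seed <- configs[[1]]$seed
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  runs <- list(); meta <- list(); truths <- list()
  counter <- 0L
  for (cfg in configs) {
    cfg$seed <- NULL  # the cohort-level seed (set above) governs all draws
    abbrev <- paste0(substr(strsplit(cfg$species, " ")[[1]], 1, 1),
                     collapse = "")
    for (j in seq_len(cfg$n_specimens)) {
      counter <- counter + 1L
      sid <- sprintf("%s%02d", toupper(abbrev), counter)
      out <- generate_specimen(cfg, db, sid)
      runs[[length(runs) + 1L]] <- tibble::as_tibble(out$cohort)
      meta[[length(meta) + 1L]] <- tibble::tibble(
        sample = sid, species = cfg$species, d = cfg$d)
      truths[[sid]] <- out$truth
    }
  }
  meta <- if (length(meta) > 0) dplyr::bind_rows(meta) else
    tibble::tibble(sample = character(0), species = character(0),
                   d = numeric(0))
  if (anyDuplicated(meta$sample)) stop("duplicate sample ids generated")
  new_psm_cohort(dplyr::bind_rows(runs), sample_meta = meta, truth = truths)
}
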