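test_that("PSM tables round-trip through read/write with mods and flanks", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "psm.tsv")
  writeLines(c(
    "sample\tpeptide\tscore\tmods\tprev\tnext",
    "s1\tQAQDSEVVIR\t41.5\t\tR\tG",
    "s1\tYGGLHGLGR\t33.2\tOxidation@4;Carbamidomethyl@2\tG\tG",
    "s2\tQCQDSEVVIR\t50.1\tPhosphorylation@5\t-\tG"
  ), f)
  coh <- read_psm_table(f)
  expect_equal(nrow(coh), 3)
  expect_equal(length(sample_runs(coh)), 2)
  expect_equal(vapply(sample_runs(coh), nrow, integer(1)),
               c(s1 = 2L, s2 = 1L))
  expect_equal(coh$mods[[2]]$name, c("Oxidation", "Carbamidomethyl"))
  expect_equal(coh$mods[[2]]$delta, c(15.99491, 57.02146))

  f2 <- file.path(dir, "psm2.tsv")
  write_psm_table(coh, f2)
  coh2 <- read_psm_table(f2)
  expect_equal(tibble::as_tibble(coh2)[order(coh2$peptide), ],
               tibble::as_tibble(coh)[order(coh$peptide), ])

  # empty file with header gives an empty cohort
  writeLines("sample\tpeptide\tscore", file.path(dir, "empty.tsv"))
  expect_equal(nrow(read_psm_table(file.path(dir, "empty.tsv"))), 0)

  # schema and modification errors are explicit
  writeLines(c("sample\tpeptide", "s1\tAAAAAA"), file.path(dir, "bad.tsv"))
  expect_error(read_psm_table(file.path(dir, "bad.tsv")), "score")
  writeLines(c("sample\tpeptide\tscore\tmods",
               "s1\tAAAAAA\t30\tOxidation-4"),
             file.path(dir, "badmod.tsv"))
  expect_error(read_psm_table(file.path(dir, "badmod.tsv")), "Oxidation-4")
  writeLines(c("sample\tpeptide\tscore\tmods",
               "s1\tAAAAAA\t30\tOxidation@9"),
             file.path(dir, "badpos.tsv"))
  expect_error(read_psm_table(file.path(dir, "badpos.tsv")), "row")
})

test_that("MAD cut-off equals median minus unscaled MAD", {
  expect_equal(mad_cutoff(c(30, 32, 35, 40, 50)), 30)
  expect_equal(mad_cutoff(rep(42.5, 7)), 42.5)
  expect_equal(mad_cutoff(25), 25)
  expect_error(mad_cutoff(numeric(0)))
  set.seed(5)
  for (i in 1:50) {
    x <- rnorm(sample(1:40, 1), mean = 40, sd = 8)
    med <- median(x)
    expect_equal(mad_cutoff(x), med - median(abs(x - med)))
    expect_lte(mad_cutoff(x), med)
  }
})

test_that("per-marker cut-offs drop sub-cut-off PSMs and flag markers without eligible PSMs", {
  db <- bundled_marker_db()
  coh <- make_cohort(
    "s1",
    peptide = c(rep("QAQDSEVVIR", 6), rep("YGGLHGLGR", 2)),
    score = c(30, 32, 35, 40, 50, 28, 31, 31),
    mods = parse_mods(c("", "", "", "", "", "Oxidation@4",
                        "Oxidation@1", "Oxidation@1"))
  )
  coh <- assign_markers(coh, db)
  res <- apply_marker_cutoffs(coh, db)
  c2 <- res$cutoffs[res$cutoffs$marker_id == "C-2", ]
  expect_equal(c2$cutoff, 30)
  expect_equal(c2$n_eligible, 5L)
  expect_false(c2$flagged)
  kept <- res$cohort$score[res$cohort$marker_id == "C-2"]
  expect_false(28 %in% kept)   # oxidized PSM below cut-off removed
  expect_true(30 %in% kept)    # eligible PSM at the cut-off retained
  # marker with no eligible PSM keeps everything, flagged
  e2c4 <- res$cutoffs[res$cutoffs$marker_id == "E2c-4", ]
  expect_true(e2c4$flagged)
  expect_equal(sum(res$cohort$marker_id == "E2c-4"), 2)

  # empty cohort in, empty tables out
  empty <- apply_marker_cutoffs(make_cohort("s", character(0), numeric(0)), db)
  expect_equal(nrow(empty$cohort), 0)
  expect_equal(nrow(empty$cutoffs), 0)
})

test_that("detection matrices count retained PSMs completely and monotonically", {
  db <- bundled_marker_db()
  coh <- make_cohort(
    c("s1", "s1", "s1", "s2"),
    peptide = c("QAQDSEVVIR", "QAQDSEVVIR", "QAQDSEVVIR", "YGGLHGLGR"),
    score = c(30, 31, 32, 45)
  )
  coh <- assign_markers(coh, db)
  m <- detection_matrix(coh, db, "count")
  expect_equal(m["C-2", "s1"], 3)
  expect_equal(m["E2c-4", "s2"], 1)
  expect_equal(sum(m), sum(!is.na(coh$marker_id)))
  # undetected markers appear as all-zero rows
  expect_true(all(m[setdiff(rownames(m), c("C-2", "E2c-4")), ] == 0))
  ms <- detection_matrix(coh, db, "max_score")
  expect_equal(ms["C-2", "s1"], 32)
  # filtering never increases a cell
  filt <- apply_marker_cutoffs(coh, db)$cohort
  m2 <- detection_matrix(filt, db, "count")
  expect_true(all(m2 <= m))
})

test_that("undetermined-cleavage percentages recover the generating probability", {
  db <- bundled_marker_db()
  # direct arithmetic: 3 undetermined of 10
  coh <- make_cohort("s1", rep("QAQDSEVVIR", 10), score = rep(30, 10))
  coh$cleavage <- rep(c("undetermined", "determined"), c(3, 7))
  expect_equal(undetermined_fraction(coh)$pct_undetermined, 30)
  expect_error(undetermined_fraction(make_cohort("s", "AAAAAA", 30)),
               "annotate")

  # binomial sampling check on a generated cohort (>= 1000 PSMs)
  panel <- synthetic_panel_db()
  cfg <- generator_config("Eretmochelys imbricata", n_specimens = 1, d = 0,
                          psm_count_mean = 10, seed = 202)
  g <- generate_cohort(cfg, panel)
  expect_gte(nrow(g), 1000)
  g <- assign_markers(g, panel)
  g <- annotate_cleavage(g, panel)
  est <- undetermined_fraction(g)$pct_undetermined
  truth <- attr(g, "truth")[[1]]$psms
  truth_pct <- 100 * mean(truth$cleavage_truth == "undetermined")
  expect_lt(abs(est - truth_pct), 3)
})
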