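test_that("template matching locates substitutions and wildcard residues", {
  # published marker vs its class template: one substitution at position 3
  r <- match_template("QCQDSEVVIR", "QCPDSEVVIX")
  expect_true(r$matched)
  expect_equal(r$mismatch_positions, 3L)
  expect_equal(r$wildcard_assignments, list(`10` = "R"))

  r <- match_template("GPGLGGSFGPGGLYGYGGR", "GXGXGGSFGXGGLYGYGGR")
  expect_true(r$matched)
  expect_length(r$mismatch_positions, 0)

  r <- match_template("AGYGGLGGYLGGYGYGGGLAGSGVSAHR",
                      "XGYGGLGGYXGGYGYGXGLXGSGVSXHR")
  expect_true(r$matched)
  expect_length(r$mismatch_positions, 0)
  expect_equal(r$wildcard_assignments,
               list(`1` = "A", `10` = "L", `17` = "G", `20` = "A", `26` = "A"))

  # saturating every wildcard with any residue matches with 0 mismatches
  tpl <- "PXPXXGSXNXPXVR"
  expect_true(match_template(gsub("X", "G", tpl), tpl)$matched)
  expect_length(match_template(gsub("X", "G", tpl), tpl)$mismatch_positions, 0)

  # length mismatch is an immediate non-match
  expect_false(match_template("QCQDSEVVIRA", "QCPDSEVVIX")$matched)
  expect_error(match_template("QCQDSEVV1R", "QCPDSEVVIX"), "illegal")
})

test_that("I/L equivalence is symmetric and switchable", {
  set.seed(7)
  tpl <- "YGGLYGYGGXGGYGGR"
  for (i in 1:20) {
    pep <- gsub("X", sample(cbpid:::AA20, 1), tpl)
    swapped <- chartr("LI", "IL", pep)
    a <- match_template(pep, tpl, il_equivalent = TRUE, max_mismatch = 16)
    b <- match_template(swapped, tpl, il_equivalent = TRUE, max_mismatch = 16)
    expect_equal(a$mismatch_positions, b$mismatch_positions)
  }
  expect_false(match_template("IGGFGGLAR", "LGGFGGLXR",
                              il_equivalent = FALSE)$mismatch_positions |>
                 length() == 0)
  expect_length(match_template("IGGFGGLAR", "LGGFGGLXR",
                               il_equivalent = TRUE)$mismatch_positions, 0)
})

test_that("peptide classification assigns published markers to their classes", {
  db <- bundled_marker_db()
  a <- classify_peptide("QAQDSEVVIR", db)
  expect_equal(a$class_id, "C")
  expect_equal(a$mismatch_count, 2L)
  expect_equal(classify_peptide("QCQDSEVVIR", db)$mismatch_count, 1L)
  expect_equal(classify_peptide("GPGLGGSFGPGGLYGYGGR", db)$class_id, "E1")
  b <- classify_peptide("AGYGGLGGYLGGYGYGGGLAGSGVSAHR", db)
  expect_equal(b$class_id, "E4a")
  expect_equal(b$mismatch_count, 0L)
  # no length-compatible template within budget
  expect_true(is.na(classify_peptide(strrep("G", 50), db)$class_id))
  # saturated templates classify back to their own class when unique at
  # that length
  for (cl in c("A", "C", "E1", "E2b", "E4b")) {
    tpl <- db$templates$template[db$templates$class_id == cl]
    got <- classify_peptide(gsub("X", "A", tpl), db)
    expect_equal(got$class_id, cl)
    expect_equal(got$mismatch_count, 0L)
  }
  # the curated-exception peptide: template inference prefers E2d
  e2c4 <- classify_peptide("YGGLHGLGR", db)
  expect_equal(e2c4$class_id, "E2d")
  expect_equal(e2c4$mismatch_count, 1L)
})

test_that("digestion enumerates tryptic peptides and matches the brute-force oracle", {
  d <- digest("MKGYRAAGR", mode = "specific", missed_cleavages = 1,
              min_len = 2, max_len = 45)
  expect_setequal(d$sequence, c("MK", "GYR", "AAGR", "MKGYR", "GYRAAGR"))
  # no K/R: whole protein only
  d2 <- digest("GGGAGGG", mode = "specific", min_len = 2)
  expect_equal(d2$sequence, "GGGAGGG")
  # semispecific is a superset of specific
  set.seed(11)
  for (i in 1:12) {
    prot <- random_protein(sample(10:60, 1))
    ml <- sample(2:6, 1); mc <- sample(0:2, 1); bp <- sample(c(TRUE, FALSE), 1)
    for (mode in c("specific", "semispecific")) {
      got <- digest(prot, mode = mode, missed_cleavages = mc, min_len = ml,
                    max_len = 45, cleave_before_proline = bp)
      want <- oracle_digest(prot, mode, mc, ml, 45, bp)
      got <- got[order(got$start, got$end), ]
      expect_equal(got$sequence, want$sequence)
      expect_equal(got$n_missed, want$n_missed)
      expect_equal(got$specificity, want$specificity)
    }
    spec <- digest(prot, "specific", 1, 6, 45)
    semi <- digest(prot, "semispecific", 1, 6, 45)
    expect_true(all(spec$sequence %in% semi$sequence))
    expect_gte(nrow(semi), nrow(spec))
  }
})

test_that("cleavage status distinguishes determined, semi and undetermined peptides", {
  mseq <- "QAQDSEVVIR"
  expect_equal(cleavage_status(mseq, mseq, "N_and_C"), "determined")
  # two N-terminal residues lost, no flanks: one boundary left
  expect_equal(cleavage_status("QDSEVVIR", mseq, "N_and_C"), "semi")
  # offset at both ends
  expect_equal(cleavage_status("QDSEVVI", mseq, "N_and_C"), "undetermined")
  # flanks can rescue an interior N-terminus
  expect_equal(cleavage_status("QDSEVVIR", mseq, "N_and_C",
                               prev_residue = "R"), "determined")
  # unalignable peptide warns and is undetermined
  expect_warning(s <- cleavage_status("WWWWWW", mseq, "N_and_C"),
                 "alignable")
  expect_equal(s, "undetermined")
  # C_only class: full marker without N-side flank evidence is semi,
  # and a tryptic prev residue upgrades it to determined
  e1 <- "GPGLGGSFGPGGLYGYGGR"
  expect_equal(cleavage_status(e1, e1, "C_only"), "semi")
  expect_equal(cleavage_status(e1, e1, "C_only", prev_residue = "R"),
               "determined")
})

test_that("peptide masses are monoisotopic and additive", {
  expect_equal(peptide_mass("GG"), 132.0535, tolerance = 1e-6)
  expect_error(peptide_mass(""), "empty")
  m0 <- peptide_mass("QCQDSEVVIR")
  m1 <- peptide_mass("QCQDSEVVIR",
                     data.frame(pos = 2, delta = 57.02146))
  expect_equal(m1 - m0, 57.02146, tolerance = 1e-9)
  expect_error(peptide_mass("GG", data.frame(pos = 3, delta = 1)),
               "out of range")
  # concatenation loses one water
  set.seed(3)
  for (i in 1:10) {
    s1 <- random_protein(sample(2:12, 1)); s2 <- random_protein(sample(2:12, 1))
    expect_equal(peptide_mass(paste0(s1, s2)),
                 peptide_mass(s1) + peptide_mass(s2) - 18.010565,
                 tolerance = 1e-9)
  }
})
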