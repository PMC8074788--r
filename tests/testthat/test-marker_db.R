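test_that("bundled templates carry the declared lengths, termini and content", {
  db <- bundled_marker_db()
  tl <- db$templates
  expect_equal(nrow(tl), 14)
  declared <- cbpid:::TEMPLATE_LENGTHS
  expect_equal(nchar(tl$template), unname(declared[tl$class_id]))
  row_c <- tl[tl$class_id == "C", ]
  expect_equal(row_c$template, "QCPDSEVVIX")
  expect_equal(row_c$tryptic_termini, "N_and_C")
  expect_equal(nchar(row_c$template), 10)
  # E4a ships as two length forms under one reporting class
  expect_setequal(nchar(tl$template[grepl("^E4a", tl$class_id)]), c(25, 28))
  expect_equal(tl$tryptic_termini[tl$class_id == "D"], "N_only")
  expect_equal(tl$tryptic_termini[tl$class_id == "E1"], "C_only")
})

test_that("bundled markers and genus map match the published content", {
  db <- bundled_marker_db()
  mk <- db$markers
  e4a <- mk[mk$marker_id == "E4a-19.1", ]
  expect_equal(e4a$sequence, "AGYGGLGGYLGGYGYGGGLAGSGVSAHR")
  expect_equal(e4a$species_validated[[1]], "Eretmochelys imbricata")
  for (id in c("C-2", "C-8", "E2c-4")) {
    expect_equal(mk$species_validated[mk$marker_id == id][[1]],
                 "Eretmochelys imbricata")
  }
  expect_equal(mk$sequence[mk$marker_id == "C-2"], "QAQDSEVVIR")
  expect_equal(mk$sequence[mk$marker_id == "E1-7"], "GPGLGGSFGPGGLYGYGGR")
  gm <- db$genus_map
  expect_equal(unname(gm["Lepidochelys olivacea"]),
               unname(gm["Lepidochelys kempii"]))
  expect_equal(length(unique(unname(gm[db$species]))), 4)
})

test_that("database FASTA/TSV round trip is lossless", {
  db <- synthetic_panel_db()
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_marker_db(db, fa, tsv)
  db2 <- load_marker_db(fa, tsv)
  expect_equal(db2$markers$marker_id, db$markers$marker_id)
  expect_equal(db2$markers$sequence, db$markers$sequence)
  expect_equal(db2$markers$class_id, db$markers$class_id)
  expect_equal(lapply(db2$markers$species_validated, sort),
               lapply(db$markers$species_validated, sort))
  expect_equal(db2$species, db$species)
})

test_that("loader flags malformed input and uppercases lowercase records", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "m.fasta"); tsv <- file.path(dir, "m.tsv")
  writeLines(c(">M-1|C", "qcpdsevvir", ">M-2|C", "QCPDSEVVIK"), fa)
  meta <- data.frame(marker_id = c("M-1", "M-2"), class_id = c("C", "C"),
                     sequence = c("QCPDSEVVIR", "QCPDSEVVIK"))
  meta[["Eretmochelys imbricata"]] <- c(1L, 1L)
  readr::write_tsv(meta, tsv)
  expect_message(db <- load_marker_db(fa, tsv), "lowercase")
  expect_equal(db$markers$sequence[1], "QCPDSEVVIR")

  # unknown class id fails validation naming the marker
  meta_bad <- meta; meta_bad$class_id <- c("Z", "C")
  readr::write_tsv(meta_bad, tsv)
  writeLines(c(">M-1|Z", "QCPDSEVVIR", ">M-2|C", "QCPDSEVVIK"), fa)
  expect_error(load_marker_db(fa, tsv), "M-1")

  # sequence length inconsistent with the class template
  meta_len <- meta; meta_len$sequence[2] <- "QCPDSEVVIKA"
  readr::write_tsv(meta_len, tsv)
  writeLines(c(">M-1|C", "QCPDSEVVIR", ">M-2|C", "QCPDSEVVIKA"), fa)
  expect_error(load_marker_db(fa, tsv), "M-2")
})

test_that("supplementary import is identity on empty input and replaces duplicates", {
  db <- bundled_marker_db()
  empty <- data.frame(marker_id = character(0), class_id = character(0),
                      sequence = character(0))
  expect_identical(import_supplementary_markers(empty, db), db)

  dup <- data.frame(marker_id = "C-2", class_id = "C",
                    sequence = "QAQDSEVVIR")
  for (sp in db$species) dup[[sp]] <- as.integer(sp == "Eretmochelys imbricata")
  expect_message(db2 <- import_supplementary_markers(dup, db), "replacing")
  expect_equal(nrow(db2$markers), nrow(db$markers))
  expect_setequal(db2$markers$marker_id, db$markers$marker_id)
  expect_equal(sort(db2$markers$sequence), sort(db$markers$sequence))

  bad <- dup; bad$sequence <- "QAQDSEVVIRGG"
  expect_error(import_supplementary_markers(bad, db), "length")
})

test_that("synthetic panel yields disjoint unique sets and valid databases", {
  db <- synthetic_panel_db()
  expect_equal(nrow(db$markers), 187)
  u <- unique_markers(db, "species")
  all_u <- unlist(u)
  expect_equal(anyDuplicated(all_u), 0L)
  expect_lte(length(all_u), nrow(db$markers))
  # sequences unique, validation invariants hold
  expect_equal(anyDuplicated(db$markers$sequence), 0L)
  expect_silent(validate_marker_db(db))
  # deterministic: two constructions are identical
  expect_identical(synthetic_reference_panel(), synthetic_reference_panel())
})
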