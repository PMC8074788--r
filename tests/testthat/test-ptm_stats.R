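test_that("potential sites count P/Y/H/W residues", {
  expect_equal(potential_sites("QCQDSEVVIR"), 0L)
  expect_equal(potential_sites("QAQDSEVVIR"), 0L)
  expect_equal(potential_sites("AGYGGLGGYLGGYGYGGGLAGSGVSAHR"), 5L)
  expect_equal(potential_sites(c("PYHW", "GGGG")), c(4L, 0L))
})

test_that("oxidation percentages follow the sites-times-PSMs bookkeeping", {
  db <- toy_db()
  # T-1 = YGGAAGYR: 2 potential sites (Y1, Y7); 5 PSMs; 2 oxidized
  # observations -> 2 / (2*5) = 20%
  coh <- make_cohort(
    "s1", rep("YGGAAGYR", 5), score = rep(40, 5),
    mods = parse_mods(c("Oxidation@1", "Oxidation@7", "", "", ""))
  )
  coh <- assign_markers(coh, db)
  rep1 <- oxidation_percentages(coh, db, classes = "E4b",
                                group_by = "sample")
  expect_equal(rep1$percent_oxidation, 20)
  expect_equal(rep1$percent_dioxidation, 0)
  expect_equal(rep1$potential_sites, 10L)
  expect_equal(rep1$observed_ox_sites, 2L)

  # 4-site arithmetic: marker with 4 sites, 5 PSMs, 3 site observations
  coh2 <- make_cohort(
    "s1", rep("YGGLYGYGGAGGYGGR", 5), score = rep(40, 5),
    mods = parse_mods(c("Oxidation@1;Oxidation@5", "Oxidation@7",
                        "", "", ""))
  )
  db2 <- suppressMessages(import_supplementary_markers({
    extra <- data.frame(marker_id = "T-3", class_id = "E2b",
                        sequence = "YGGLYGYGGAGGYGGR", check.names = FALSE)
    for (sp in db$species) extra[[sp]] <- 1L
    extra
  }, db))
  coh2 <- assign_markers(coh2, db2)
  r2 <- oxidation_percentages(coh2, db2, classes = "E2b", group_by = "sample")
  # marker has 4 Y sites -> 4 x 5 = 20 opportunities; 3 oxidized -> 15%
  expect_equal(r2$percent_oxidation, 15)
  expect_equal(r2$percent_dioxidation, 0)

  # oxidation on non-P/Y/H/W residues is excluded but logged
  coh3 <- make_cohort("s1", "YGGAAGYR", 40,
                      mods = parse_mods("Oxidation@4"))
  coh3 <- assign_markers(coh3, db)
  r3 <- oxidation_percentages(coh3, db, classes = "E4b", group_by = "sample")
  expect_equal(r3$observed_ox_sites, 0L)
  expect_equal(r3$n_ox_other, 1L)

  # no oxidative mods at all -> 0% / 0%
  coh4 <- make_cohort("s1", "YGGAAGYR", 40)
  coh4 <- assign_markers(coh4, db)
  r4 <- oxidation_percentages(coh4, db, classes = "E4b", group_by = "sample")
  expect_equal(r4$percent_oxidation, 0)
  expect_equal(r4$percent_dioxidation, 0)
})

test_that("restricting classes never increases the potential-site denominator", {
  panel <- synthetic_panel_db()
  cfg <- generator_config("Caretta caretta", n_specimens = 1, d = 0,
                          seed = 31)
  g <- generate_cohort(cfg, panel)
  g <- assign_markers(g, panel)
  full <- oxidation_percentages(g, panel,
                                classes = c("A", "B", "E4a", "E4b", "E2b"),
                                group_by = "sample")
  sub <- oxidation_percentages(g, panel, classes = c("A", "B"),
                               group_by = "sample")
  expect_lte(sub$potential_sites, full$potential_sites)
})

test_that("generated cohorts reproduce the configured oxidation rates and motif rules", {
  panel <- synthetic_panel_db()
  cfg <- generator_config("Eretmochelys imbricata", n_specimens = 3, d = 0,
                          psm_count_mean = 6, u0 = 0, seed = 99)
  g <- generate_cohort(cfg, panel)
  g <- assign_markers(g, panel)
  rep_g <- oxidation_percentages(g, panel, group_by = "genus")
  n <- rep_g$potential_sites
  expect_gte(n, 2000)
  p_hat <- rep_g$percent_oxidation / 100
  ci <- 1.96 * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(p_hat - 0.05), ci + 1e-12)
  # dioxidation configured at half the oxidation rate
  expect_lt(abs(rep_g$percent_dioxidation / 100 - 0.025),
            1.96 * sqrt(0.025 * 0.975 / n) + 1e-12)

  pm <- phospho_motif_summary(g)
  schr <- pm$by_context[pm$by_context$context == "SCHR", ]
  expect_equal(schr$n_phospho, 0L)  # SCHR never phosphorylated by design
  sahr <- pm$by_context[pm$by_context$context == "SAHR", ]
  if (sahr$n_serine > 50) {
    expect_gt(sahr$n_phospho / sahr$n_serine, 0.3)
    expect_lt(sahr$n_phospho / sahr$n_serine, 0.7)
  }
  # direct bucketing: phospho on the S of a SAHR suffix
  coh <- make_cohort("s1", "AGYGGLGGYLGGYGYGGGLAGSGVSAHR", 40,
                     mods = parse_mods("Phosphorylation@25"))
  pm2 <- phospho_motif_summary(coh)
  expect_equal(pm2$by_context$n_phospho[pm2$by_context$context == "SAHR"], 1L)
  expect_equal(pm2$by_next_residue$next_residue, "A")
  # no phospho PSMs -> all-zero table
  pm3 <- phospho_motif_summary(make_cohort("s1", "GGGGGG", 30))
  expect_true(all(pm3$by_context$n_phospho == 0))
})
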