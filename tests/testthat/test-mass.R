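test_that("residue mass tables are sane", {
  mono <- residue_masses("mono")
  avg <- residue_masses("avg")
  expect_equal(unname(mono["G"]), 57.02146)
  expect_true(all(mono < avg))
  expect_setequal(names(mono), amino_acids())
})

test_that("single-residue and worked peptide masses are correct", {
  expect_equal(peptide_mass("G")$neutral_mono, 57.02146 + 18.01056,
               tolerance = 1e-9)
  # the synthetic assay peptide: isotope-averaged neutral mass 1059.22 Da
  pm <- peptide_mass("AVIGRKFGDP")
  expect_equal(pm$neutral_avg, 1059.22, tolerance = 0.05)
  expect_equal(pm$mh_mono, pm$neutral_mono + 1.00728, tolerance = 1e-12)
  expect_error(peptide_mass("AXA"), "illegal residue")
})

test_that("modifications add their deltas per resolved site", {
  base <- peptide_mass("AVIGRKFGDP")
  dm <- peptide_mass("AVIGRKFGDP", mods = list("dimethyl"))
  # one lysine side chain + the peptide N-terminus = two sites
  expect_equal(nrow(dm$mods), 2L)
  expect_equal(dm$neutral_mono - base$neutral_mono, 2 * 28.0313,
               tolerance = 1e-4)

  cam <- peptide_mass("ACDC", mods = list("carbamidomethyl"))
  expect_equal(cam$neutral_mono - peptide_mass("ACDC")$neutral_mono,
               2 * 57.02146, tolerance = 1e-9)

  # order of the mod list does not matter
  a <- peptide_mass("ACKM", mods = list("dimethyl", "oxidation"))
  b <- peptide_mass("ACKM", mods = list("oxidation", "dimethyl"))
  expect_equal(a$neutral_mono, b$neutral_mono, tolerance = 1e-12)

  expect_error(peptide_mass("AAA", mods = list("nosuchmod")),
               "unknown modification")
})

test_that("mh_ion is the +1.00728 protonation", {
  expect_error(mh_ion(0))
  avigr <- peptide_mass("AVIGR")
  expect_equal(avigr$neutral_mono, 514.3227, tolerance = 1e-3)
  # the nonprime MALDI product peak reported at 515.30 Da
  expect_equal(mh_ion(avigr$neutral_mono), 515.30, tolerance = 0.05)
  x <- 731.2
  expect_equal(mh_ion(mh_ion(x) - 1.00728), mh_ion(x), tolerance = 1e-12)
})

test_that("cleavage products obey the hydrolysis mass balance", {
  pr <- predict_cleavage_products("AVIGRKFGDP", cut_index = 5)
  expect_equal(pr$nterm$sequence, "AVIGR")
  expect_equal(pr$cterm$sequence, "KFGDP")

  parent <- peptide_mass("AVIGRKFGDP")
  expect_equal(pr$nterm$neutral_mono + pr$cterm$neutral_mono,
               parent$neutral_mono + 18.01056, tolerance = 1e-6)
  expect_equal(pr$nterm$neutral_avg + pr$cterm$neutral_avg,
               parent$neutral_avg + 18.0153, tolerance = 1e-6)
  # every cut index of a random peptide balances to parent + one water
  withr::local_seed(55)
  pep <- random_protein_sequence(14)
  parent <- peptide_mass(pep)
  for (ci in 1:13) {
    pr <- predict_cleavage_products(pep, ci)
    expect_equal(pr$nterm$neutral_mono + pr$cterm$neutral_mono,
                 parent$neutral_mono + 18.01056, tolerance = 1e-6)
    expect_equal(pr$nterm$neutral_avg + pr$cterm$neutral_avg,
                 parent$neutral_avg + 18.0153, tolerance = 1e-6)
  }
  expect_error(predict_cleavage_products("AVIGR", 0))
  expect_error(predict_cleavage_products("AVIGR", 5))
})

test_that("modification sites are re-resolved on fragments", {
  # dimethylated parent: N-terminal site stays on the N fragment, the K
  # site travels with the C fragment, the neo-N-terminus stays free
  pr <- predict_cleavage_products("AVIGRKFGDP", 5, mods = list("dimethyl"))
  expect_equal(nrow(pr$nterm$mods), 1L)    # N-terminus only
  expect_equal(nrow(pr$cterm$mods), 1L)    # lysine side chain only
  expect_equal(pr$nterm$neutral_mono,
               peptide_mass("AVIGR")$neutral_mono + 28.0313, tolerance = 1e-4)
  # matches the dimethylated product peak reported at 543.30 Da
  expect_equal(mh_ion(pr$nterm$neutral_mono), 543.30, tolerance = 0.1)

  relabel <- predict_cleavage_products("AVIGRKFGDP", 5,
                                       mods = list("dimethyl"),
                                       modify_new_nterm = TRUE)
  expect_equal(nrow(relabel$cterm$mods), 2L)
})

test_that("peak matching is greedy, one-to-one and tolerance-bounded", {
  m <- match_peaks(c(515.31), data.frame(label = "AVIGR", mz = 515.33),
                   tolerance = 0.1)
  expect_equal(nrow(m$assignments), 1L)
  expect_equal(m$assignments$delta, -0.02, tolerance = 1e-9)

  expect_equal(nrow(match_peaks(numeric(0),
                                data.frame(label = "a", mz = 100))$assignments),
               0L)

  # nearer theoretical peak wins; exact tie broken by lower m/z
  theo <- data.frame(label = c("lo", "hi"), mz = c(499.95, 500.06))
  near <- match_peaks(500.00, theo, tolerance = 0.1)
  expect_equal(near$assignments$label, "lo")
  tie <- match_peaks(500.00, data.frame(label = c("lo", "hi"),
                                        mz = c(499.95, 500.05)),
                     tolerance = 0.1)
  expect_equal(tie$assignments$label, "lo")

  # one-to-one: two observed, one theoretical -> one assignment
  two <- match_peaks(c(500.00, 500.01), data.frame(label = "t", mz = 500.0),
                     tolerance = 0.1)
  expect_equal(nrow(two$assignments), 1L)
  expect_equal(two$unassigned, 500.01)

  # out of tolerance stays unassigned
  far <- match_peaks(501, data.frame(label = "t", mz = 500), tolerance = 0.1)
  expect_equal(far$unassigned, 501)
})

test_that("full MALDI assay interpretation recovers the cleavage site", {
  # parent peptide cleaved between R and K; observed peaks are the parent
  # and the nonprime product as reported for the matriptase-2 assay
  products <- predict_cleavage_products("AVIGRKFGDP", 5)
  theo <- data.frame(
    label = c("parent", "AVIGR", "KFGDP"),
    mz = c(peptide_mass("AVIGRKFGDP")$mh_mono,
           mh_ion(products$nterm$neutral_mono),
           mh_ion(products$cterm$neutral_mono)))
  m <- match_peaks(c(1059.52, 515.31), theo, tolerance = 0.1)
  expect_setequal(m$assignments$label, c("parent", "AVIGR"))
  expect_equal(length(m$unassigned), 0L)
})
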