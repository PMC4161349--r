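test_that("positional counts obey the column-sum conservation law", {
  m <- count_matrix(c("MAVIGRKFGDPL", "MAVIGRKFGDPL"))
  expect_equal(m$counts["R", "P1"], 2L)
  expect_equal(m$counts["K", "P1'"], 2L)
  expect_equal(m$n_sites, 2L)

  mx <- count_matrix(c("XAVIGRKFGDPL", "MAVIGRKFGDPL"))
  expect_equal(unname(mx$x_counts["P6"]), 1L)
  expect_equal(sum(mx$counts[, "P6"]), 1L)

  withr::local_seed(21)
  win <- replicate(50, paste(sample(amino_acids(TRUE), 12, replace = TRUE,
                                    prob = c(rep(1, 20), 3)), collapse = ""))
  m2 <- count_matrix(win)
  expect_equal(unname(colSums(m2$counts) + m2$x_counts), rep(50L, 12L))

  expect_error(count_matrix(c("SHORT")), "exactly 12")
  expect_error(
    count_matrix(data.frame(protease = c("a", "b"),
                            window = c("MAVIGRKFGDPL", "MAVIGRKFGDPL"))),
    "mix proteases")
})

test_that("occurrence percentages exclude masked observations", {
  m <- count_matrix(c("RAVIGRKFGDPL", "XAVIGRKFGDPL",
                      "XAVIGRKFGDPL", "KAVIGRKFGDPL"))
  pct <- occurrence_percent(m)
  expect_equal(pct["R", "P6"], 50)    # 1 of 2 unmasked
  expect_equal(pct["R", "P1"], 100)
  expect_equal(sum(pct[, "P6"]), 100)

  allx <- count_matrix(c("XAVIGRKFGDPL", "XAVIGRKFGDPL"))
  expect_true(all(is.na(occurrence_percent(allx)[, "P6"])))

  withr::local_seed(3)
  win <- replicate(40, paste(sample(amino_acids(), 12, TRUE), collapse = ""))
  p2 <- occurrence_percent(count_matrix(win))
  expect_equal(unname(colSums(p2)), rep(100, 12), tolerance = 1e-9)
})

test_that("enrichment folds and calls match a direct binomial computation", {
  # 100 sites, all arginine at P1, background 5% -> fold 20, p << 0.01
  win <- rep("AAAAARKAAAAA", 100)
  bg <- structure(rep(0.05, 20), names = amino_acids(),
                  class = "aa_background")
  prof <- enrichment_profile(count_matrix(win), bg, alpha = 0.01)
  r_p1 <- prof[prof$position == "P1" & prof$residue == "R", ]
  expect_equal(r_p1$fold, 20)
  expect_equal(r_p1$p_value, binom.test(100, 100, 0.05)$p.value)
  expect_lt(r_p1$p_value, 1e-100)
  expect_equal(r_p1$call, "over")

  # a residue never seen with expected count >= 5 is called absent
  g_p1 <- prof[prof$position == "P1" & prof$residue == "G", ]
  expect_equal(g_p1$call, "absent")
  expect_equal(g_p1$count, 0L)

  # uniform observation over uniform background: folds 1, all ns
  uwin <- vapply(0:19, function(k) {
    paste(rep(amino_acids()[k + 1], 12), collapse = "")
  }, character(1))
  uprof <- enrichment_profile(count_matrix(uwin), bg, alpha = 0.01)
  expect_true(all(uprof$fold == 1))
  expect_true(all(uprof$call == "ns"))
})

test_that("X-masked sites drop out of the enrichment denominator", {
  win <- c(rep("XAAAARKAAAAA", 3), rep("RAAAARKAAAAA", 1))
  bg <- structure(rep(0.05, 20), names = amino_acids(),
                  class = "aa_background")
  prof <- enrichment_profile(count_matrix(win), bg)
  r_p6 <- prof[prof$position == "P6" & prof$residue == "R", ]
  expect_equal(r_p6$n_eff, 1L)
  expect_equal(r_p6$observed, 1)
})

test_that("PWM entries match the direct log-odds formula", {
  sim <- small_simulation(seed = 19L, n_proteins = 30L, n_events = 200L)
  bg <- background_composition(sim$proteome)
  res <- reconstruct_all(sim$assay$ids, proteome_index(sim$proteome))
  prof <- enrichment_profile(count_matrix(res$windows), bg)
  pwm <- pwm_from_profile(prof, pseudocount = 0.5)
  # independent recomputation straight from the profile rows
  for (i in sample(nrow(prof), 100)) {
    pos <- as.character(prof$position[i]); a <- prof$residue[i]
    want <- log2(((prof$count[i] + 0.5) / (prof$n_eff[i] + 10)) /
                   prof$background[i])
    expect_equal(pwm[a, pos], want, tolerance = 1e-12)
  }
  expect_true(all(is.finite(pwm)))
})

test_that("PWM ranks the planted consensus above alternatives", {
  win <- rep("AAAAARKAAAAA", 100)
  bg <- structure(rep(0.05, 20), names = amino_acids(),
                  class = "aa_background")
  prof <- enrichment_profile(count_matrix(win), bg)
  pwm <- pwm_from_profile(prof)
  expect_equal(unname(which.max(pwm[, "P1"])), which(amino_acids() == "R"))

  # CDCP1 window (P4-P4' known, X-padded) scores above its P1-swapped twin
  cdcp1 <- "XXKQSRKFVPXX"
  swapped <- "XXKQSDKFVPXX"
  expect_gt(score_window(pwm, cdcp1), score_window(pwm, swapped))
})

test_that("window scores are additive over positions and zero for X", {
  sim <- small_simulation(seed = 23L, n_proteins = 20L, n_events = 150L)
  bg <- background_composition(sim$proteome)
  res <- reconstruct_all(sim$assay$ids, proteome_index(sim$proteome))
  pwm <- pwm_from_profile(enrichment_profile(count_matrix(res$windows), bg))

  withr::local_seed(77)
  for (i in 1:10) {
    w <- paste(sample(amino_acids(TRUE), 12, TRUE), collapse = "")
    chars <- strsplit(w, "")[[1]]
    per_pos <- vapply(seq_len(12), function(j) {
      if (chars[j] == "X") 0 else pwm[chars[j], subsite_labels()[j]]
    }, numeric(1))
    expect_equal(score_window(pwm, w), sum(per_pos), tolerance = 1e-12)
  }
  expect_equal(score_window(structure(matrix(0, 20, 12,
                 dimnames = list(amino_acids(), subsite_labels())),
                 class = c("subsite_pwm", "matrix")), "XXXXXXXXXXXX"), 0)
  expect_error(score_window(pwm, "ACDEFG"), "12")
})
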