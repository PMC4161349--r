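test_that("simulated proteomes are reproducible and isoform-aware", {
  cfg <- simulation_config(n_proteins = 40L, mean_length = 200L, seed = 99L)
  a <- simulate_proteome(cfg)
  b <- simulate_proteome(cfg)
  expect_identical(a$proteome$sequence, b$proteome$sequence)
  fa1 <- withr::local_tempfile(fileext = ".fasta")
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  write_proteome_fasta(a$proteome, fa1)
  write_proteome_fasta(b$proteome, fa2)
  expect_identical(readLines(fa1), readLines(fa2))

  # isoform_rate 0 -> singleton groups
  solo <- simulate_proteome(simulation_config(n_proteins = 30L,
                                              mean_length = 150L,
                                              isoform_rate = 0, seed = 5L))
  expect_equal(anyDuplicated(solo$proteome$isoform_group), 0L)

  # isoform copies differ from their base exactly at the recorded positions
  iso <- a$truth[!is.na(a$truth$isoform_of) & nzchar(a$truth$sub_positions), ]
  for (i in seq_len(nrow(iso))) {
    base <- a$proteome$sequence[a$proteome$accession == iso$isoform_of[i]]
    copy <- a$proteome$sequence[a$proteome$accession == iso$accession[i]]
    subs <- as.integer(strsplit(iso$sub_positions[i], ";")[[1]]) + 1L
    diffs <- which(strsplit(base, "")[[1]] != strsplit(copy, "")[[1]])
    expect_equal(diffs, subs)
  }
})

test_that("degenerate simulator configs are rejected", {
  expect_error(simulation_config(composition = rep(0, 20)), "composition")
  expect_error(simulation_config(contamination_rate = 1.5))
})

test_that("planted subsite preferences shape the emitted products", {
  sim <- small_simulation(seed = 41L, n_proteins = 300L, mean_length = 450L,
                          n_events = 1000L)
  truth <- sim$assay$truth
  expect_lte(nrow(truth), 1000L)
  expect_gte(nrow(truth), 400L)
  # model plants R at P1 (window char 6) and K at P1' (char 7); expected
  # fractions under the default weights are f*w/(1 + f*(w-1)): ~0.95 for
  # arginine (w = 320) and ~0.86 for lysine (w = 100)
  p1 <- substr(truth$window, 6, 6)
  p1p <- substr(truth$window, 7, 7)
  expect_gte(mean(p1 == "R"), 0.9)
  expect_gte(mean(p1p == "K"), 0.8)
  # emitted peptide is the prime-side product: starts at the P1' residue
  expect_true(all(substr(truth$peptide, 1, 1) == p1p))
})

test_that("a neutral model cleaves uniformly across eligible bonds", {
  cfg <- simulation_config(n_proteins = 100L, mean_length = 400L,
                           n_cleavage_events = 10000L,
                           contamination_rate = 0, isoform_rate = 0,
                           seed = 8L)
  sim <- simulate_proteome(cfg)
  lib <- digest_proteome(sim$proteome, digest_rule("gluc"))
  neutral <- specificity_model(baseline = 0.05, label = "neutral")
  assay <- simulate_protease_assay(lib, sim$proteome, neutral, cfg)
  expect_gt(nrow(assay$truth), 2000)
  # under a neutral model every eligible bond fires with the same
  # probability, so product lengths follow the eligibility profile:
  # a peptide of length plen contributes one bond per product length
  # L in 8..plen-1
  plen <- nchar(lib$sequence)
  lens <- nchar(assay$truth$peptide)
  ls <- 8:max(lens)
  expected <- vapply(ls, function(L) sum(plen >= L + 1), numeric(1))
  observed <- as.vector(table(factor(lens, levels = ls)))
  # collapse the sparse tail so all expected cell counts are >= 5
  p_exp <- expected / sum(expected)
  keep <- which(p_exp * length(lens) >= 5)
  if (length(keep) < length(ls)) {
    obs2 <- c(observed[keep], sum(observed[-keep]))
    p2 <- c(p_exp[keep], 1 - sum(p_exp[keep]))
  } else {
    obs2 <- observed
    p2 <- p_exp
  }
  cs <- suppressWarnings(chisq.test(obs2, p = p2))
  expect_gt(cs$p.value, 0.01)
})

test_that("n_cleavage_events caps and zero yields empty output", {
  cfg0 <- simulation_config(n_proteins = 20L, mean_length = 150L,
                            n_cleavage_events = 0L, seed = 2L)
  sim <- simulate_proteome(cfg0)
  lib <- digest_proteome(sim$proteome, digest_rule("gluc"))
  assay <- simulate_protease_assay(lib, sim$proteome, ttsp_like_model(), cfg0)
  expect_equal(nrow(assay$ids), 0L)
  expect_equal(nrow(assay$truth), 0L)
})

test_that("contamination plants the configured decoy fraction", {
  sim <- small_simulation(seed = 47L, n_proteins = 300L, mean_length = 450L,
                          n_events = 1000L, contamination = 0.05)
  truth <- sim$assay$truth
  n <- nrow(truth)
  frac <- mean(truth$is_decoy)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(frac - 0.05), 3 * se + 1e-9)
  # decoys remain mappable: they are substrings of library peptides
  idx <- proteome_index(sim$proteome)
  for (pep in head(truth$peptide[truth$is_decoy], 10)) {
    expect_gt(nrow(locate_peptide(idx, pep)), 0)
  }
})

test_that("ground-truth TSV round-trips with stable columns", {
  sim <- small_simulation(seed = 53L, n_proteins = 30L, n_events = 100L,
                          contamination = 0.1)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_ground_truth(sim$assay$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back, sim$assay$truth)
  # same config, fresh run -> byte-identical file
  sim2 <- small_simulation(seed = 53L, n_proteins = 30L, n_events = 100L,
                           contamination = 0.1)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  export_ground_truth(sim2$assay$truth, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("simulator does not disturb the caller's RNG stream", {
  set.seed(1)
  before <- .Random.seed
  invisible(simulate_proteome(simulation_config(n_proteins = 5L,
                                                mean_length = 100L,
                                                seed = 77L)))
  expect_identical(.Random.seed, before)
})
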