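# Fixture builders and independent oracles shared across the suite.

# independent regex-based digestion oracle: insert a split marker after
# every cleavage residue (unless blocked), split, then enumerate joins
brute_digest <- function(sequence, cleave_after, blocked_before = character(0),
                         max_missed = 0L, length_range = c(1L, 10000L)) {
  ca <- paste(cleave_after, collapse = "")
  pat <- if (length(blocked_before)) {
    sprintf("([%s])(?![%s])", ca, paste(blocked_before, collapse = ""))
  } else {
    sprintf("([%s])", ca)
  }
  marked <- gsub(pat, "\\1\u0001", sequence, perl = TRUE)
  frags <- strsplit(marked, "\u0001", fixed = TRUE)[[1L]]
  frags <- frags[nzchar(frags)]
  ends <- cumsum(nchar(frags))
  starts <- c(0L, ends[-length(ends)])
  out <- list()
  for (m in 0:max_missed) {
    for (i in seq_len(max(0L, length(frags) - m))) {
      s <- starts[i]; e <- ends[i + m]
      if (e - s >= length_range[1L] && e - s <= length_range[2L]) {
        out[[length(out) + 1L]] <- data.frame(
          start = s, end = e,
          sequence = substr(sequence, s + 1L, e),
          n_missed = m, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      sequence = character(0), n_missed = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$n_missed), , drop = FALSE]
}

random_protein_sequence <- function(n, prob = NULL) {
  paste(sample(amino_acids(), n, replace = TRUE, prob = prob), collapse = "")
}

# canonical string form of a digest result for set comparison
digest_key <- function(df) {
  sort(paste(df$start, df$end, df$sequence, df$n_missed, sep = ":"))
}

# small deterministic proteome + assay used by several files
small_simulation <- function(seed = 11L, n_proteins = 60L,
                             n_events = 300L, contamination = 0,
                             isoform_rate = 0, mean_length = 300L) {
  cfg <- simulation_config(n_proteins = n_proteins, mean_length = mean_length,
                           n_cleavage_events = n_events,
                           contamination_rate = contamination,
                           isoform_rate = isoform_rate, seed = seed)
  sim <- simulate_proteome(cfg)
  lib <- digest_proteome(sim$proteome, digest_rule("gluc"))
  assay <- simulate_protease_assay(lib, sim$proteome, ttsp_like_model(), cfg)
  list(config = cfg, proteome = sim$proteome, proteome_truth = sim$truth,
       library = lib, assay = assay)
}

# windows cut uniformly at random from a proteome (composition-neutral
# null: every residue position is equally likely to flank the cut)
null_windows <- function(proteome, n_sites) {
  seqs <- proteome$sequence
  lens <- nchar(seqs)
  pi <- sample(length(seqs), n_sites, replace = TRUE, prob = lens)
  cut <- vapply(pi, function(i) sample(seq(6L, lens[i] - 6L), 1L), numeric(1))
  substring(seqs[pi], cut - 5L, cut + 6L)
}
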