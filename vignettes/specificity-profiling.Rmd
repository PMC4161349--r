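---
title: "Profiling protease cleavage-site specificity with proteome-derived peptide libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling protease cleavage-site specificity with proteome-derived peptide libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picsr)
```

## The method

Proteomic identification of cleavage sites (PICS) determines the subsite
specificity of a protease from a single experiment. A whole proteome is
digested with a *library protease* of known, narrow specificity — GluC
(after E), chymotrypsin (after F/W/Y/L/M, not before P) or trypsin (after
K/R) — to produce a peptide library of tens of thousands of sequences whose
termini carry the library protease's signature, not the test protease's.
The *test protease* is then incubated with this library. Wherever it cleaves
a library peptide internally, it creates a product with a new N-terminus:
the **prime-side** product, running from P1' outward. These products are
isolated and identified by mass spectrometry.

Each identified prime-side product fixes only half of the cleavage site. The
**non-prime** half (P6…P1) is reconstructed bioinformatically: the product
sequence is located in the source proteome, and the six residues preceding
the match are read off the protein sequence. Joining both halves yields a
12-residue **cleavage window** P6–P6', and the set of windows for a protease
is summarised into positional specificity profiles.

`picsr` implements this workflow end to end: proteome I/O and composition
(`read_proteome_fasta`, `background_composition`), in-silico library
digestion (`digest_rule`, `digest_proteome`), window reconstruction
(`proteome_index`, `reconstruct_all`), profiling (`count_matrix`,
`enrichment_profile`, `pwm_from_profile`), modification-aware mass
bookkeeping for validation assays (`peptide_mass`,
`predict_cleavage_products`, `match_peaks`), a ground-truth simulator
(`simulate_proteome`, `simulate_protease_assay`), and a one-call pipeline
(`run_profile`).

## Conventions and assumptions

**Coordinates.** All intervals are 0-based and half-open; `cut_pos` is the
0-based index of the P1' residue. Zero-missed-cleavage fragments therefore
concatenate exactly back to the protein — an invariant the test suite
enforces.

**X-masking.** Windows are always 12 characters over a 21-letter alphabet.
`X` marks positions that are *uninformative*: outside the protein (a cut
near a terminus), disagreeing between equally valid mapping locations
(isoforms or repeated sequence), or a nonstandard input residue (U/B/Z/J/O
are masked on import with a warning). Masked positions are excluded from
column denominators in occurrence percentages, contribute zero to PWM
scores, and are reported per window as the subsite labels they affect, so
ambiguity is visible rather than silently resolved.

**Isoforms.** Accessions of the form `ACC-2` group with their base `ACC`.
By default a peptide mapping to several members of one isoform group is kept
with disagreeing positions masked; `same_group_only` optionally drops
cross-group multi-mappers entirely.

## Statistics

`enrichment_profile` compares each residue × subsite cell against the
proteome's background composition with a **two-sided exact binomial test**
at `alpha = 0.01`, calling cells `over`, `under` or `ns`. A residue never
observed at a position is called `absent` only when its expected count under
background is at least 5; below that, absence carries no evidence. A
z-test on proportions (`test = "ztest"`) is available as a lighter
alternative, but the exact test is the default because it is valid at the
small per-cell counts typical of a few hundred sites; it is mildly
conservative (achieved size ≈ 0.009 at nominal 0.01 for 1,000 sites), which
we prefer to anti-conservative calls.

A caveat worth knowing: the *library itself* is compositionally biased.
GluC library peptides contain no internal E (except at missed cleavages), so
positions far from the cut inherit an E-depleted background. Profiles should
therefore be read relative to an appropriate background
(`background_source` in the pipeline), and claims about weak depletion at
outer subsites treated with care. For null calibration we use
composition-neutral windows cut uniformly from the proteome, precisely
because digested-library nulls carry this real composition signal.

The PWM is `log2(((count + c) / (n_eff + 20c)) / background)` with
pseudocount `c = 0.5`; `score_window` sums non-X positions, so X-padded
partial windows (e.g. a P4–P4' literature site padded to 12) score on the
evidence they contain.

## The simulator as ground truth

`simulate_proteome` draws a multi-protein proteome from a vertebrate-like
composition, optionally with isoform copies carrying recorded point
substitutions. `simulate_protease_assay` digests it, then cleaves library
peptides under a multiplicative subsite model: each eligible bond fires with
probability `p = min(1, baseline × Π weights)` over its 12-residue window,
with `X` neutral. Under this model the expected fraction of a residue with
background frequency `f` and weight `w` at its subsite is
`f·w / (1 + f·(w − 1))` — a closed form we use to set defaults and test
bounds *before* running anything.

`ttsp_like_model()` plants an Arg-P1 / Lys-P1' preference (weights 320 and
100, baseline 3e-5), chosen so the realized P1-arginine enrichment is
roughly 17-fold — the effect size reported for trypsin-like
transmembrane serine proteases — with ~95% of events preceded by R and ~86%
starting with K. Default study conditions (300 proteins, mean length 450,
500–600 events, `min_product_length = 8`, 5% decoy contamination available)
are sized like one real per-protease dataset and run in seconds. The
simulator exports full ground truth (cut positions, true windows, decoy
flags) so reconstruction can be checked for *exact* window equality, and it
restores the caller's RNG state.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_proteins = 300, mean_length = 450,
                         n_cleavage_events = 600, seed = 42)
sim <- simulate_proteome(cfg)
lib <- digest_proteome(sim$proteome, digest_rule("gluc"))
assay <- simulate_protease_assay(lib, sim$proteome, ttsp_like_model(), cfg)

idx <- proteome_index(sim$proteome)
rec <- reconstruct_all(assay$ids, idx)
prof <- enrichment_profile(count_matrix(rec$windows),
                           background_composition(sim$proteome))
summary(prof)           # top residues per subsite; R at P1, K at P1'
pwm <- pwm_from_profile(prof)
score_window(pwm, "XXKQSRKFVPXX")   # candidate substrate window

# mass bookkeeping for a MALDI validation assay
peptide_mass("AVIGRKFGDP")                     # avg 1059.22 Da
predict_cleavage_products("AVIGRKFGDP", 5)     # AVIGR / KFGDP
```

Or, from files, via the pipeline: `run_profile(pipeline_config(...))` or
`read_pipeline_config("run.yaml")`, which writes per-group windows, heat
map, enrichment and PWM TSVs plus a `summary.json` stamped with a config
hash, and a run log. A command-line front end ships in
`system.file("cli", "pics.R", package = "picsr")`.

## Limitations

- Reconstruction assumes the product maps to the searched proteome; sites in
  sequence absent from the database are lost, and decoy identifications
  (simulated via `contamination_rate`) appear as noise windows.
- Only prime-side products are modelled, as in the underlying assay;
  non-prime evidence comes solely from the database.
- The multiplicative cleavage model treats subsites independently; real
  proteases show subsite cooperativity the simulator does not plant.
- The mass module covers a fixed set of common modifications
  (carbamidomethyl, dimethyl, oxidation, N-terminal thioacylation) with
  simple site rules; it is a bookkeeping aid, not a search engine.
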