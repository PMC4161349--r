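# Residue (amino-acid minus water) masses in Da.
# Monoisotopic values from the most-abundant-isotope elemental masses;
# average values from IUPAC 2021 standard atomic weights.
AA_MONO <- c(
  A = 71.03711, C = 103.00919, D = 115.02694, E = 129.04259, F = 147.06841,
  G = 57.02146, H = 137.05891, I = 113.08406, K = 128.09496, L = 113.08406,
  M = 131.04049, N = 114.04293, P = 97.05276, Q = 128.05858, R = 156.10111,
  S = 87.03203, T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333
)
AA_AVG <- c(
  A = 71.0779, C = 103.1429, D = 115.0874, E = 129.1155, F = 147.1739,
  G = 57.0513, H = 137.1393, I = 113.1576, K = 128.1723, L = 113.1576,
  M = 131.1961, N = 114.1026, P = 97.1152, Q = 128.1292, R = 156.1857,
  S = 87.0773, T = 101.1039, V = 99.1311, W = 186.2099, Y = 163.1733
)
WATER_MONO <- 18.01056
WATER_AVG <- 18.0153
PROTON <- 1.00728

#' Residue mass tables
#'
#' @param scale `"mono"` (monoisotopic) or `"avg"` (isotope-averaged).
#' @return Named numeric vector of the 20 residue masses in Da
#'   (peptide-bond residues, i.e. amino acid minus water).
#' @export
#' @examples
#' residue_masses("mono")[["G"]]  # glycine, 57.02146
residue_masses <- function(scale = c("mono", "avg")) {
  switch(match.arg(scale), mono = AA_MONO, avg = AA_AVG)
}

#' Define a peptide modification
#'
#' Built-in presets cover the chemistry of proteome-derived peptide
#' library preparation and its mass-spectrometric readout:
#'
#' * `"carbamidomethyl"`: +57.02146 Da (mono) on cysteine, fixed
#'   (iodoacetamide alkylation).
#' * `"dimethyl"`: +28.03130 Da (mono) per site on lysine side chains and
#'   the peptide N-terminus, fixed (reductive dimethylation protecting
#'   primary amines).
#' * `"oxidation"`: +15.99491 Da (mono) on methionine, variable.
#' * `"thioacyl"`: +87.99827 Da (mono) on the peptide N-terminus,
#'   variable (the thioacylation tag marking prime-side neo-N-termini).
#'
#' @param name Preset name, or a label for a custom modification.
#' @param delta_mono,delta_avg Mass shifts in Da (required for custom
#'   modifications).
#' @param targets Character vector of residue letters and/or `"nterm"`.
#' @param fixed Logical; `TRUE` for fixed modifications. Metadata only:
#'   [peptide_mass()] applies every modification it is given.
#' @return List of class `modification`.
#' @export
#' @examples
#' modification("dimethyl")
modification <- function(name, delta_mono = NULL, delta_avg = NULL,
                         targets = NULL, fixed = NULL) {
  presets <- list(
    carbamidomethyl = list(delta_mono = 57.02146, delta_avg = 57.0513,
                           targets = "C", fixed = TRUE),
    dimethyl = list(delta_mono = 28.03130, delta_avg = 28.0532,
                    targets = c("K", "nterm"), fixed = TRUE),
    oxidation = list(delta_mono = 15.99491, delta_avg = 15.9994,
                     targets = "M", fixed = FALSE),
    thioacyl = list(delta_mono = 87.99827, delta_avg = 88.1241,
                    targets = "nterm", fixed = FALSE)
  )
  key <- tolower(name)
  if (key %in% names(presets)) {
    p <- presets[[key]]
    if (is.null(delta_mono)) delta_mono <- p$delta_mono
    if (is.null(delta_avg)) delta_avg <- p$delta_avg
    if (is.null(targets)) targets <- p$targets
    if (is.null(fixed)) fixed <- p$fixed
  }
  if (is.null(delta_mono) || is.null(delta_avg) || is.null(targets)) {
    stop("unknown modification '", name,
         "': supply delta_mono, delta_avg and targets", call. = FALSE)
  }
  if (is.null(fixed)) fixed <- TRUE
  stopifnot(is.finite(delta_mono), is.finite(delta_avg), length(targets) >= 1L)
  targets <- ifelse(targets == "nterm", "nterm", toupper(targets))
  stopifnot(all(targets %in% c(AA20, "nterm")))
  structure(
    list(name = name, delta_mono = delta_mono, delta_avg = delta_avg,
         targets = targets, fixed = fixed),
    class = "modification"
  )
}

# resolve modification sites on a sequence; returns data.frame(site, kind)
# where site is "nterm" or a 1-based residue position
resolve_mod_sites <- function(sequence, mod) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  sites <- character(0)
  if ("nterm" %in% mod$targets) sites <- "nterm"
  res_targets <- setdiff(mod$targets, "nterm")
  if (length(res_targets)) {
    sites <- c(sites, as.character(which(chars %in% res_targets)))
  }
  sites
}

#' Modification-aware peptide mass
#'
#' Neutral mass = sum of residue masses + one water + the mass shift of
#' every applicable modification site, on both the monoisotopic and the
#' isotope-averaged scale. `[M+H]+` values add one proton (1.00728 Da).
#'
#' @param sequence Peptide over the 20-letter alphabet (`X` has no
#'   defined mass and is rejected).
#' @param mods List of [modification()] objects (or preset names); each
#'   is applied at every matching site.
#' @return List of class `peptide_mass`: `sequence`, `mods` (applied
#'   name/site pairs), `neutral_mono`, `neutral_avg`, `mh_mono`,
#'   `mh_avg`.
#' @export
#' @examples
#' peptide_mass("AVIGRKFGDP")$neutral_avg        # 1059.22
#' peptide_mass("AVIGRKFGDP", mods = list("dimethyl"))$neutral_mono
peptide_mass <- function(sequence, mods = list()) {
  check_sequence(sequence, what = "peptide", allow_x = FALSE)
  if (inherits(mods, "modification")) mods <- list(mods)
  mods <- lapply(mods, function(m) {
    if (is.character(m)) modification(m) else m
  })
  stopifnot(all(vapply(mods, inherits, logical(1), "modification")))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  mono <- sum(AA_MONO[chars]) + WATER_MONO
  avg <- sum(AA_AVG[chars]) + WATER_AVG
  applied <- list()
  for (m in mods) {
    sites <- resolve_mod_sites(sequence, m)
    if (length(sites)) {
      mono <- mono + length(sites) * m$delta_mono
      avg <- avg + length(sites) * m$delta_avg
      applied[[length(applied) + 1L]] <- data.frame(
        name = m$name, site = sites, stringsAsFactors = FALSE)
    }
  }
  applied <- if (length(applied)) do.call(rbind, applied)
             else data.frame(name = character(0), site = character(0))
  structure(
    list(sequence = sequence, mods = applied,
         neutral_mono = unname(mono), neutral_avg = unname(avg),
         mh_mono = unname(mono + PROTON), mh_avg = unname(avg + PROTON)),
    class = "peptide_mass"
  )
}

#' @export
print.peptide_mass <- function(x, ...) {
  cat(sprintf("peptide %s%s\n", x$sequence,
              if (nrow(x$mods)) paste0(" (+", nrow(x$mods), " mod site(s))") else ""))
  cat(sprintf("  neutral: %.4f Da (mono)  %.4f Da (avg)\n",
              x$neutral_mono, x$neutral_avg))
  cat(sprintf("  [M+H]+ : %.4f Da (mono)  %.4f Da (avg)\n",
              x$mh_mono, x$mh_avg))
  invisible(x)
}

#' Protonated-ion m/z from a neutral mass
#'
#' @param neutral Neutral mass in Da (> 0).
#' @return `neutral + 1.00728` (singly protonated, z = 1).
#' @export
mh_ion <- function(neutral) {
  stopifnot(is.numeric(neutral), all(neutral > 0))
  neutral + PROTON
}

#' Theoretical products of cleaving a peptide at one bond
#'
#' Splits `peptide` before the residue at `cut_index` (the 0-based index
#' of the P1' residue) and masses both fragments. Modifications given for
#' the parent are re-resolved on each fragment: residue-targeted sites
#' travel with their residue, parent N-terminal modifications stay on the
#' N-terminal fragment, and the C-terminal fragment's newly exposed
#' N-terminus is unmodified by default (the assay modifies the intact
#' peptide before cleavage); set `modify_new_nterm = TRUE` when labelling
#' happens after cleavage.
#'
#' @param peptide Parent peptide sequence.
#' @param cut_index 0-based index of the first residue of the C-terminal
#'   fragment; must satisfy `1 <= cut_index <= nchar(peptide) - 1`.
#' @param mods Modifications applied to the parent (as in
#'   [peptide_mass()]).
#' @param modify_new_nterm Whether N-terminus-targeted modifications also
#'   apply to the C-terminal fragment's neo-N-terminus (default `FALSE`).
#' @return List with elements `nterm` and `cterm`, each a `peptide_mass`.
#' @export
#' @examples
#' pr <- predict_cleavage_products("AVIGRKFGDP", cut_index = 5)
#' pr$nterm$sequence  # "AVIGR"
#' mh_ion(pr$nterm$neutral_mono)
predict_cleavage_products <- function(peptide, cut_index, mods = list(),
                                      modify_new_nterm = FALSE) {
  check_sequence(peptide, what = "peptide", allow_x = FALSE)
  n <- nchar(peptide)
  if (!(cut_index >= 1L && cut_index <= n - 1L)) {
    stop("cut_index must lie strictly inside the peptide (1..", n - 1L, ")",
         call. = FALSE)
  }
  if (inherits(mods, "modification")) mods <- list(mods)
  mods <- lapply(mods, function(m) if (is.character(m)) modification(m) else m)
  nseq <- substr(peptide, 1L, cut_index)
  cseq <- substr(peptide, cut_index + 1L, n)
  strip_nterm <- function(m) {
    t2 <- setdiff(m$targets, "nterm")
    if (length(t2) == 0L) return(NULL)
    modification(m$name, m$delta_mono, m$delta_avg, t2, m$fixed)
  }
  cmods <- if (modify_new_nterm) mods else
    Filter(Negate(is.null), lapply(mods, strip_nterm))
  list(
    nterm = peptide_mass(nseq, mods),
    cterm = peptide_mass(cseq, cmods)
  )
}

#' Assign observed peaks to theoretical masses
#'
#' One-to-one greedy assignment: candidate (observed, theoretical) pairs
#' within `tolerance` are ranked by ascending mass error (ties broken by
#' lower theoretical m/z) and accepted while both peaks are still free.
#'
#' @param observed Numeric vector of observed m/z values.
#' @param theoretical `data.frame` with columns `label` and `mz`, or a
#'   named numeric vector.
#' @param tolerance Maximum |observed - theoretical| in Da (default 0.1,
#'   MALDI reflectron scale).
#' @return List with `assignments` (`data.frame`: `observed`, `label`,
#'   `theoretical`, `delta`) and `unassigned` (observed peaks with no
#'   match).
#' @export
#' @examples
#' match_peaks(c(515.31), data.frame(label = "AVIGR", mz = 515.33))
match_peaks <- function(observed, theoretical, tolerance = 0.1) {
  stopifnot(tolerance > 0)
  if (is.numeric(theoretical) && !is.null(names(theoretical))) {
    theoretical <- data.frame(label = names(theoretical),
                              mz = as.numeric(theoretical))
  }
  stopifnot(is.data.frame(theoretical),
            all(c("label", "mz") %in% names(theoretical)))
  empty <- data.frame(observed = numeric(0), label = character(0),
                      theoretical = numeric(0), delta = numeric(0))
  if (length(observed) == 0L || nrow(theoretical) == 0L) {
    return(list(assignments = empty, unassigned = observed))
  }
  cand <- expand.grid(i = seq_along(observed), j = seq_len(nrow(theoretical)))
  cand$delta <- abs(observed[cand$i] - theoretical$mz[cand$j])
  cand <- cand[cand$delta <= tolerance, , drop = FALSE]
  cand <- cand[order(cand$delta, theoretical$mz[cand$j]), , drop = FALSE]
  used_obs <- logical(length(observed))
  used_theo <- logical(nrow(theoretical))
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used_obs[i] || used_theo[j]) next
    used_obs[i] <- TRUE
    used_theo[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      observed = observed[i], label = theoretical$label[j],
      theoretical = theoretical$mz[j],
      delta = observed[i] - theoretical$mz[j])
  }
  list(
    assignments = if (length(rows)) do.call(rbind, rows) else empty,
    unassigned = observed[!used_obs]
  )
}
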