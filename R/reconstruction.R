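#' Build an exact-substring index over a proteome
#'
#' Supports exact lookup of identified peptides anywhere in the proteome,
#' returning every match location. Matching is backed by
#' [Biostrings::vmatchPattern()] over an `AAStringSet`.
#'
#' @param proteome A `proteome` table.
#' @return An object of class `proteome_index`.
#' @export
proteome_index <- function(proteome) {
  stopifnot(inherits(proteome, "proteome"), nrow(proteome) >= 1L)
  subject <- Biostrings::AAStringSet(proteome$sequence)
  names(subject) <- proteome$accession
  structure(
    list(subject = subject,
         accession = proteome$accession,
         isoform_group = proteome$isoform_group,
         sequence = proteome$sequence,
         length = nchar(proteome$sequence)),
    class = "proteome_index"
  )
}

#' Locate a peptide in an indexed proteome
#'
#' @param index A [proteome_index()].
#' @param peptide Peptide sequence (20-letter alphabet).
#' @return `data.frame` with columns `accession`, `isoform_group` and
#'   `start` (0-based position of the peptide's first residue); zero rows
#'   when the peptide is absent. Overlapping matches within one protein
#'   are all reported.
#' @export
#' @examples
#' idx <- proteome_index(proteome("P1", "MAVIGRKFGDPL"))
#' locate_peptide(idx, "KFGDPL")
locate_peptide <- function(index, peptide) {
  stopifnot(inherits(index, "proteome_index"))
  check_sequence(peptide, what = "peptide", allow_x = FALSE)
  hits <- Biostrings::vmatchPattern(peptide, index$subject)
  ir <- unlist(hits, use.names = FALSE)
  n_per <- S4Vectors::elementNROWS(hits)
  which_prot <- rep(seq_along(n_per), n_per)
  data.frame(
    accession = index$accession[which_prot],
    isoform_group = index$isoform_group[which_prot],
    start = if (length(ir)) BiocGenerics::start(ir) - 1L else integer(0),
    stringsAsFactors = FALSE
  )
}

#' Reconstruct a P6-P6' cleavage window from a prime-side peptide
#'
#' An identified prime-side cleavage product determines the residues
#' C-terminal of the scissile bond directly (P1'-P6' are its first six
#' residues, X-padded when shorter). The non-prime residues P6-P1 are
#' recovered from the proteome: they are the six residues preceding each
#' match location, X-padded at protein N-termini. When the peptide maps
#' to several locations (typically protein isoforms), a per-position
#' consensus is taken and any position where the locations disagree is
#' masked to `X` and recorded in `ambiguous_positions`.
#'
#' @param peptide The identified peptide sequence.
#' @param index A [proteome_index()].
#' @param n_nonprime,n_prime Number of non-prime/prime subsites (default
#'   6 and 6, the standard P6-P6' window).
#' @param same_group_only If `TRUE`, restrict consensus to match
#'   locations within the isoform group of the first match; matches in
#'   other groups are dropped before masking.
#' @return A list of class `cleavage_window` with elements `aligned`
#'   (12-character string), `support` (`data.frame` of `accession`,
#'   `cut_pos`, the 0-based index of the P1' residue),
#'   `ambiguous_positions` (character vector of subsite labels) and
#'   `cross_group` (logical: matches span more than one isoform group) —
#'   or `NULL` when the peptide does not map.
#' @export
#' @examples
#' idx <- proteome_index(proteome("P1", "MAVIGRKFGDPL"))
#' reconstruct_window("KFGDPL", idx)$aligned
reconstruct_window <- function(peptide, index, n_nonprime = 6L, n_prime = 6L,
                               same_group_only = FALSE) {
  hits <- locate_peptide(index, peptide)
  if (nrow(hits) == 0L) return(NULL)
  if (same_group_only && length(unique(hits$isoform_group)) > 1L) {
    hits <- hits[hits$isoform_group == hits$isoform_group[1L], , drop = FALSE]
  }
  labels <- window_labels(n_nonprime, n_prime)

  # prime side comes from the peptide itself, X-padded if short
  prime <- substring(peptide, seq_len(n_prime), seq_len(n_prime))
  prime[prime == ""] <- "X"

  # one candidate non-prime context per match location
  seq_by_acc <- stats::setNames(index$sequence, index$accession)
  contexts <- t(vapply(seq_len(nrow(hits)), function(i) {
    s <- seq_by_acc[[hits$accession[i]]]
    pos <- hits$start[i] - seq(n_nonprime, 1L)  # 0-based residue indices
    ch <- rep("X", n_nonprime)
    ok <- pos >= 0L
    ch[ok] <- substring(s, pos[ok] + 1L, pos[ok] + 1L)
    ch
  }, character(n_nonprime)))

  consensus <- contexts[1L, ]
  disagree <- logical(n_nonprime)
  if (nrow(contexts) > 1L) {
    for (j in seq_len(n_nonprime)) {
      u <- unique(contexts[, j])
      if (length(u) > 1L) {
        consensus[j] <- "X"
        disagree[j] <- TRUE
      }
    }
  }
  aligned <- paste(c(consensus, prime), collapse = "")
  structure(
    list(aligned = aligned,
         support = data.frame(accession = hits$accession,
                              cut_pos = hits$start,
                              stringsAsFactors = FALSE),
         ambiguous_positions = labels[seq_len(n_nonprime)][disagree],
         cross_group = length(unique(hits$isoform_group)) > 1L),
    class = "cleavage_window"
  )
}

window_labels <- function(n_nonprime = 6L, n_prime = 6L) {
  c(paste0("P", n_nonprime:1), paste0("P", seq_len(n_prime), "'"))
}

#' Reconstruct cleavage windows for a set of identifications
#'
#' Applies [reconstruct_window()] to every identified prime-side peptide,
#' drops unmappable and too-short identifications, optionally collapses
#' duplicate (protease, window) pairs, and optionally removes windows
#' whose P1 residue is masked (`X`), since P1 anchors the specificity
#' analysis.
#'
#' @param ids `data.frame` with columns `protease`, `library`, `peptide`
#'   and optionally `score` (see [read_identifications_tsv()]).
#' @param index A [proteome_index()].
#' @param dedupe Collapse identical (protease, aligned window) pairs,
#'   merging their support (default `TRUE`).
#' @param require_p1 Drop windows with `X` at P1 (default `TRUE`).
#' @param min_peptide_length Identifications shorter than this are
#'   rejected as too promiscuous to map (default 4).
#' @param same_group_only Passed to [reconstruct_window()].
#' @param n_nonprime,n_prime Window geometry.
#' @return List with `windows` (a `data.frame` of class `window_set`:
#'   `protease`, `library`, `window`, `n_support`, `accessions`
#'   (semicolon-joined), `cut_positions` (semicolon-joined),
#'   `ambiguous_positions`, `cross_group`, `n_obs`) and `report` (counts:
#'   `n_input`, `n_too_short`, `n_unmapped`, `n_mapped`, `n_ambiguous`,
#'   `n_dropped_no_p1`, `n_cross_group`, `n_windows`).
#' @export
reconstruct_all <- function(ids, index, dedupe = TRUE, require_p1 = TRUE,
                            min_peptide_length = 4L, same_group_only = FALSE,
                            n_nonprime = 6L, n_prime = 6L) {
  stopifnot(is.data.frame(ids), all(c("protease", "peptide") %in% names(ids)))
  if (is.null(ids$library)) ids$library <- ""
  n_input <- nrow(ids)
  too_short <- nchar(ids$peptide) < min_peptide_length
  ids <- ids[!too_short, , drop = FALSE]

  rows <- vector("list", nrow(ids))
  n_unmapped <- 0L
  for (i in seq_len(nrow(ids))) {
    w <- reconstruct_window(ids$peptide[i], index,
                            n_nonprime = n_nonprime, n_prime = n_prime,
                            same_group_only = same_group_only)
    if (is.null(w)) {
      n_unmapped <- n_unmapped + 1L
      next
    }
    rows[[i]] <- data.frame(
      protease = ids$protease[i],
      library = ids$library[i],
      window = w$aligned,
      n_support = nrow(w$support),
      accessions = paste(w$support$accession, collapse = ";"),
      cut_positions = paste(w$support$cut_pos, collapse = ";"),
      ambiguous_positions = paste(w$ambiguous_positions, collapse = ";"),
      cross_group = w$cross_group,
      n_obs = 1L,
      stringsAsFactors = FALSE
    )
  }
  windows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(windows)) {
    windows <- data.frame(protease = character(0), library = character(0),
                          window = character(0), n_support = integer(0),
                          accessions = character(0), cut_positions = character(0),
                          ambiguous_positions = character(0),
                          cross_group = logical(0), n_obs = integer(0))
  }
  n_mapped <- nrow(windows)
  n_ambiguous <- sum(nzchar(windows$ambiguous_positions))
  n_cross_group <- sum(windows$cross_group)

  if (dedupe && nrow(windows) > 0L) {
    key <- paste(windows$protease, windows$library, windows$window, sep = "\r")
    grp <- split(seq_len(nrow(windows)), key)
    merged <- lapply(grp, function(ii) {
      first <- windows[ii[1L], , drop = FALSE]
      accs <- unlist(strsplit(windows$accessions[ii], ";", fixed = TRUE))
      cuts <- unlist(strsplit(windows$cut_positions[ii], ";", fixed = TRUE))
      uniq <- !duplicated(paste(accs, cuts))
      first$accessions <- paste(accs[uniq], collapse = ";")
      first$cut_positions <- paste(cuts[uniq], collapse = ";")
      first$n_support <- sum(uniq)
      first$n_obs <- length(ii)
      first
    })
    windows <- do.call(rbind, merged[order(vapply(grp, min, integer(1)))])
    rownames(windows) <- NULL
  }

  n_dropped_no_p1 <- 0L
  if (require_p1 && nrow(windows) > 0L) {
    p1 <- substring(windows$window, n_nonprime, n_nonprime)
    n_dropped_no_p1 <- sum(p1 == "X")
    windows <- windows[p1 != "X", , drop = FALSE]
    rownames(windows) <- NULL
  }
  class(windows) <- c("window_set", "data.frame")
  list(
    windows = windows,
    report = list(n_input = n_input,
                  n_too_short = sum(too_short),
                  n_unmapped = n_unmapped,
                  n_mapped = n_mapped,
                  n_ambiguous = n_ambiguous,
                  n_dropped_no_p1 = n_dropped_no_p1,
                  n_cross_group = n_cross_group,
                  n_windows = nrow(windows))
  )
}

#' Read identified prime-side peptides from TSV
#'
#' Expects a header with columns `protease`, `library`, `peptide` and
#' optionally `score` (a confidence in \[0, 1\]).
#'
#' @param path File path.
#' @return `data.frame` with those columns.
#' @export
read_identifications_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("protease", "library", "peptide")
  if (!all(need %in% names(df))) {
    stop("identifications TSV must have header columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_identifications_tsv
#' @param x Identifications `data.frame`.
#' @export
write_identifications_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write/read reconstructed cleavage windows as TSV
#'
#' The window is stored as a single 12-character string over the
#' 21-letter alphabet; support accessions and cut positions are
#' semicolon-joined. This is the interchange format between
#' reconstruction and profiling.
#'
#' @param x A `window_set`.
#' @param path File path.
#' @export
write_windows_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows_tsv
#' @export
read_windows_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(accessions = "character",
                                          cut_positions = "character",
                                          ambiguous_positions = "character"))
  out$ambiguous_positions[is.na(out$ambiguous_positions)] <- ""
  class(out) <- c("window_set", "data.frame")
  out
}
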