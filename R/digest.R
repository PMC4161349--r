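#' Define an endoproteinase digestion rule
#'
#' A rule names the residues after which the library-generating protease
#' cleaves (`cleave_after`), residues that block cleavage when they follow
#' the cut site (`blocked_before`, classically proline), and the maximum
#' number of missed cleavages to enumerate. Three named presets cover the
#' library chemistries used for specificity profiling:
#'
#' * `"gluc"` - endoproteinase GluC in bicarbonate buffer: cleaves after
#'   glutamate only, giving libraries with negatively charged C-termini.
#'   Set `include_d = TRUE` for the phosphate-buffer specificity that also
#'   cleaves after aspartate.
#' * `"chymotrypsin"` - cleaves after F/W/Y/L/M unless proline follows,
#'   giving aromatic/hydrophobic C-termini. Set `broad = FALSE` to
#'   restrict to the aromatic residues F/W/Y.
#' * `"trypsin"` - cleaves after K/R; tryptic libraries therefore carry no
#'   internal basic residues, which is why GluC and chymotryptic libraries
#'   are preferred when profiling trypsin-like proteases.
#'
#' `X` (unknown residue) never triggers cleavage and never blocks it.
#'
#' @param name Preset name (`"gluc"`, `"chymotrypsin"`, `"trypsin"`) or a
#'   label for a custom rule.
#' @param cleave_after Character vector of P1 residues (overrides preset).
#' @param blocked_before Character vector of P1' residues that block
#'   cleavage (overrides preset).
#' @param max_missed Maximum missed cleavages enumerated per peptide.
#' @param include_d GluC preset only: also cleave after D.
#' @param broad Chymotrypsin preset only: include L and M (default) or not.
#' @return A list of class `digest_rule`.
#' @export
#' @examples
#' digest_rule("gluc")
#' digest_rule("chymotrypsin", max_missed = 0)
digest_rule <- function(name, cleave_after = NULL, blocked_before = NULL,
                        max_missed = 1L, include_d = FALSE, broad = TRUE) {
  presets <- list(
    gluc = list(cleave_after = if (include_d) c("E", "D") else "E",
                blocked_before = character(0)),
    chymotrypsin = list(cleave_after = if (broad) c("F", "W", "Y", "L", "M")
                                       else c("F", "W", "Y"),
                        blocked_before = "P"),
    trypsin = list(cleave_after = c("K", "R"),
                   blocked_before = character(0))
  )
  key <- tolower(name)
  if (is.null(cleave_after) && key %in% names(presets)) {
    cleave_after <- presets[[key]]$cleave_after
  }
  if (is.null(blocked_before)) {
    blocked_before <- if (key %in% names(presets)) presets[[key]]$blocked_before
                      else character(0)
  }
  if (is.null(cleave_after) || length(cleave_after) == 0L) {
    stop("cleave_after must name at least one residue", call. = FALSE)
  }
  stopifnot(all(cleave_after %in% AA20), all(blocked_before %in% AA20),
            max_missed >= 0L)
  structure(
    list(name = name,
         cleave_after = unique(toupper(cleave_after)),
         blocked_before = unique(toupper(blocked_before)),
         max_missed = as.integer(max_missed)),
    class = "digest_rule"
  )
}

#' @export
print.digest_rule <- function(x, ...) {
  cat(sprintf("digest_rule '%s': cleave after [%s]%s, max %d missed\n",
              x$name, paste(x$cleave_after, collapse = ""),
              if (length(x$blocked_before))
                paste0(" unless before [", paste(x$blocked_before, collapse = ""), "]")
              else "",
              x$max_missed))
  invisible(x)
}

# 1-based positions i such that the bond between residue i and i+1 is cut
cleavage_positions <- function(sequence, rule) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  i <- which(chars[-n] %in% rule$cleave_after)
  if (length(rule$blocked_before)) {
    i <- i[!chars[i + 1L] %in% rule$blocked_before]
  }
  i
}

#' Digest one protein in silico
#'
#' Cleaves after every `cleave_after` residue (unless the next residue is
#' in `blocked_before`), then enumerates all products carrying 0 to
#' `rule$max_missed` missed cleavages and keeps those whose length falls
#' in `length_range`. Coordinates are 0-based half-open in the parent
#' sequence, so `substr(parent, start + 1, end)` reproduces the peptide.
#'
#' @param protein A single-row `proteome` table, or a list/row with
#'   `accession` and `sequence`.
#' @param rule A [digest_rule()].
#' @param length_range Integer pair `c(min, max)` of retained peptide
#'   lengths; the default 6-40 reflects the range routinely identifiable
#'   by LC-MS/MS.
#' @return `data.frame` with columns `accession`, `start`, `end`,
#'   `sequence`, `n_missed`, ordered by `start` then `n_missed`.
#' @export
#' @examples
#' p <- proteome("P1", "MALEGKPED")
#' digest(p, digest_rule("gluc", max_missed = 0), length_range = c(1, 50))
digest <- function(protein, rule, length_range = c(6L, 40L)) {
  stopifnot(inherits(rule, "digest_rule"),
            length(length_range) == 2L, length_range[1L] >= 1L,
            length_range[1L] <= length_range[2L])
  if (inherits(protein, "proteome")) {
    stopifnot(nrow(protein) == 1L)
    acc <- protein$accession[1L]
    seq <- protein$sequence[1L]
  } else {
    acc <- protein$accession
    seq <- protein$sequence
  }
  check_sequence(seq, what = paste0("protein '", acc, "'"))
  n <- nchar(seq)
  cuts <- cleavage_positions(seq, rule)
  # fragment boundaries as 0-based half-open [starts, ends)
  bounds <- c(0L, cuts, n)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  k <- length(starts)
  res <- vector("list", rule$max_missed + 1L)
  for (m in 0:rule$max_missed) {
    if (m + 1L > k) break
    i <- seq_len(k - m)
    res[[m + 1L]] <- data.frame(
      accession = acc,
      start = starts[i],
      end = ends[i + m],
      n_missed = m,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  out$sequence <- substring(seq, out$start + 1L, out$end)
  len <- out$end - out$start
  out <- out[len >= length_range[1L] & len <= length_range[2L], , drop = FALSE]
  out <- out[order(out$start, out$n_missed), c("accession", "start", "end",
                                               "sequence", "n_missed")]
  rownames(out) <- NULL
  out
}

#' Digest every protein of a proteome
#'
#' @param proteome A `proteome` table.
#' @inheritParams digest
#' @return Row-bound [digest()] output across all records, class
#'   `peptide_library`.
#' @export
digest_proteome <- function(proteome, rule, length_range = c(6L, 40L)) {
  stopifnot(inherits(proteome, "proteome"))
  parts <- lapply(seq_len(nrow(proteome)), function(i) {
    digest(list(accession = proteome$accession[i],
                sequence = proteome$sequence[i]),
           rule, length_range)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("peptide_library", "data.frame")
  out
}

#' Sanity-check a peptide library's termini
#'
#' Reports the fraction of peptides whose C-terminal residue matches the
#' digestion specificity (peptides ending at a protein C-terminus are
#' exempt) and the fraction containing internal lysine or arginine.
#' Libraries intended for trypsin-like test proteases must display
#' internal K/R, which is why GluC and chymotryptic libraries are used.
#'
#' @param peptides A `peptide_library` (from [digest_proteome()]) or
#'   [digest()] output.
#' @param proteome The source `proteome`, used to identify protein
#'   C-termini.
#' @param rule The [digest_rule()] that produced the library.
#' @return List with `n_peptides`, `frac_cterm_specific` (among peptides
#'   not at a protein C-terminus) and `frac_internal_kr`.
#' @export
library_c_terminus_check <- function(peptides, proteome, rule) {
  stopifnot(is.data.frame(peptides), inherits(rule, "digest_rule"))
  prot_len <- stats::setNames(nchar(proteome$sequence), proteome$accession)
  at_cterm <- peptides$end == prot_len[peptides$accession]
  last <- substring(peptides$sequence, nchar(peptides$sequence))
  internal <- substring(peptides$sequence, 2L, nchar(peptides$sequence) - 1L)
  list(
    n_peptides = nrow(peptides),
    frac_cterm_specific = if (all(at_cterm)) NA_real_ else
      mean(last[!at_cterm] %in% rule$cleave_after),
    frac_internal_kr = mean(grepl("[KR]", internal))
  )
}

#' Write/read a peptide library as TSV
#'
#' Columns: `accession`, `start`, `end`, `sequence`, `n_missed`
#' (0-based half-open coordinates).
#'
#' @param x A peptide library `data.frame`.
#' @param path File path.
#' @export
write_library_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_library_tsv
#' @export
read_library_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "integer"))
  class(out) <- c("peptide_library", "data.frame")
  out
}
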