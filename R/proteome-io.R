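#' Read a proteome from FASTA
#'
#' Parses a (possibly multi-line) amino-acid FASTA file into a proteome
#' table. The accession is taken from the header: UniProt-style
#' `db|ACC|NAME` headers yield `ACC`, otherwise the first
#' whitespace-delimited token is used. Isoforms are grouped by the
#' accession root before the first dash, so `Q9Y5Y6` and `Q9Y5Y6-2`
#' share the isoform group `Q9Y5Y6`. Non-standard residue codes
#' (B, Z, U, J, O) are mapped to `X` with a warning; any other character
#' is an error naming the record and position.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` of class `proteome` with columns `accession`,
#'   `isoform_group`, `description` and `sequence`, one row per entry, in
#'   file order.
#' @seealso [write_proteome_fasta()], [background_composition()]
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|Q9Y5Y6|ST14_HUMAN matriptase", "MAVIGR",
#'              ">sp|Q9Y5Y6-2|ST14_HUMAN isoform 2", "MAVIGK"), fa)
#' p <- read_proteome_fasta(fa)
#' p$isoform_group
read_proteome_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path, call. = FALSE)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("FASTA file contains no sequences: ", path, call. = FALSE)
  headers <- names(aas)
  acc <- vapply(headers, parse_accession, character(1), USE.NAMES = FALSE)
  desc <- vapply(headers, function(h) {
    tok <- sub("^\\S+\\s*", "", h)
    if (identical(tok, h)) "" else tok
  }, character(1), USE.NAMES = FALSE)
  seqs <- toupper(as.character(aas))
  names(seqs) <- NULL
  proteome(accession = acc, sequence = seqs, description = desc)
}

# UniProt "db|ACC|NAME ..." -> ACC; otherwise first whitespace token
parse_accession <- function(header) {
  first <- strsplit(header, "\\s+")[[1L]][1L]
  parts <- strsplit(first, "|", fixed = TRUE)[[1L]]
  if (length(parts) >= 3L && nzchar(parts[2L])) parts[2L] else first
}

#' Construct a proteome table
#'
#' Validates sequences against the 21-letter alphabet (20 standard
#' residues plus `X`), maps the ambiguity codes B, Z, U, J, O to `X` with
#' a warning, derives `isoform_group` from the accession root before the
#' first dash, and checks accession uniqueness.
#'
#' @param accession Character vector of unique record identifiers.
#' @param sequence Character vector of amino-acid sequences.
#' @param description Optional character vector of free-text descriptions.
#' @return A `data.frame` of class `proteome`.
#' @export
proteome <- function(accession, sequence, description = "") {
  stopifnot(is.character(accession), is.character(sequence),
            length(accession) == length(sequence), length(accession) >= 1L)
  description <- rep_len(as.character(description), length(accession))
  if (anyDuplicated(accession)) {
    stop("duplicate accessions: ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "),
         call. = FALSE)
  }
  sequence <- toupper(sequence)
  # tolerate common ambiguity codes by masking to X
  has_amb <- grepl("[BZUJO]", sequence)
  if (any(has_amb)) {
    warning(sum(has_amb), " record(s) contain non-standard residues ",
            "(B/Z/U/J/O); masked to X", call. = FALSE)
    sequence <- chartr("BZUJO", "XXXXX", sequence)
  }
  for (i in seq_along(sequence)) {
    ok <- try(check_sequence(sequence[i], what = paste0("record '", accession[i], "'")),
              silent = TRUE)
    if (inherits(ok, "try-error")) stop(attr(ok, "condition")$message, call. = FALSE)
  }
  out <- data.frame(
    accession = accession,
    isoform_group = sub("-.*$", "", accession),
    description = description,
    sequence = sequence,
    stringsAsFactors = FALSE
  )
  class(out) <- c("proteome", "data.frame")
  out
}

#' Write a proteome to FASTA
#'
#' @param x A `proteome` table.
#' @param path Output path.
#' @param width Line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(x, path, width = 60L) {
  stopifnot(inherits(x, "proteome"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    hdr <- if (nzchar(x$description[i])) {
      paste(x$accession[i], x$description[i])
    } else {
      x$accession[i]
    }
    writeLines(paste0(">", hdr), con)
    s <- x$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Natural amino-acid abundance of a proteome
#'
#' Counts every non-X residue across all sequences and returns the
#' relative frequency of each of the 20 standard amino acids. This is the
#' background against which positional occurrences at cleavage sites are
#' normalised: a residue enriched at a subsite is one observed more often
#' than its natural abundance predicts. `X` residues are excluded from
#' both numerator and denominator.
#'
#' @param x A `proteome` table.
#' @return Named numeric vector of length 20 summing to 1, class
#'   `aa_background`.
#' @export
#' @examples
#' p <- proteome("P1", "AAAAG")
#' background_composition(p)[c("A", "G")]
background_composition <- function(x) {
  stopifnot(inherits(x, "proteome"), nrow(x) >= 1L)
  all_chars <- strsplit(paste(x$sequence, collapse = ""), "", fixed = TRUE)[[1L]]
  counts <- table(factor(all_chars, levels = AA20))
  total <- sum(counts)
  if (total == 0L) stop("proteome has no standard (non-X) residues", call. = FALSE)
  freq <- as.numeric(counts) / total
  names(freq) <- AA20
  class(freq) <- "aa_background"
  freq
}

#' Write/read an amino-acid composition as TSV
#'
#' Two columns: `residue`, `frequency`.
#'
#' @param x An `aa_background` vector.
#' @param path File path.
#' @return `path` (write) or an `aa_background` vector (read).
#' @export
write_composition_tsv <- function(x, path) {
  stopifnot(inherits(x, "aa_background"))
  utils::write.table(
    data.frame(residue = names(x), frequency = as.numeric(x)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_composition_tsv
#' @export
read_composition_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric"))
  stopifnot(setequal(df$residue, AA20))
  freq <- df$frequency[match(AA20, df$residue)]
  names(freq) <- AA20
  if (abs(sum(freq) - 1) > 1e-6) stop("composition does not sum to 1", call. = FALSE)
  class(freq) <- "aa_background"
  freq
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("proteome: %d record(s), %d isoform group(s), %s residues\n",
              nrow(x), length(unique(x$isoform_group)),
              format(sum(nchar(x$sequence)), big.mark = ",")))
  utils::head(as.data.frame(x)[, c("accession", "isoform_group")], 6L) |> print()
  invisible(x)
}
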