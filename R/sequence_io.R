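#' Construct a set of upstream sequence records
#'
#' An `upstream_set` holds one or more 5' upstream nucleotide sequences with
#' their provenance. Sequences are normalized to uppercase DNA over
#' \{A,C,G,T,N\} (U is folded to T). Record order is preserved through all
#' downstream stages.
#'
#' @param id character vector of unique record identifiers (FASTA header
#'   tokens).
#' @param sequence character vector of nucleotide sequences (same length as
#'   `id`).
#' @param description optional character vector of free-text descriptions.
#' @param organism optional character vector of organism names.
#' @param source_accession optional character vector of source accessions.
#' @param mode `"prokaryote"` or `"eukaryote"`; controls Shine-Dalgarno
#'   scanning downstream.
#' @param label free-text label for the set.
#' @return An object of class `upstream_set`.
#' @examples
#' upstream_set(c("s1", "s2"), c("atgAAAtaa", "AUGUAA"))
#' @export
upstream_set <- function(id, sequence, description = NULL, organism = NULL,
                         source_accession = NULL,
                         mode = c("prokaryote", "eukaryote"), label = "") {
  mode <- match.arg(mode)
  id <- as.character(id)
  n <- length(id)
  if (n == 0L) stop("no sequences")
  if (length(sequence) != n) stop("'id' and 'sequence' lengths differ")
  if (anyDuplicated(id)) {
    stop("duplicate record id: ", id[duplicated(id)][1L])
  }
  sequence <- vapply(seq_len(n), function(i) {
    normalize_sequence(sequence[[i]], id[[i]])
  }, character(1))
  recycle <- function(x) {
    if (is.null(x)) rep(NA_character_, n) else {
      x <- as.character(x)
      if (length(x) == 1L) rep(x, n) else x
    }
  }
  description <- if (is.null(description)) rep("", n) else recycle(description)
  structure(
    list(id = id, description = description, sequence = sequence,
         organism = recycle(organism), source_accession = recycle(source_accession),
         mode = mode, label = label),
    class = "upstream_set")
}

#' Normalize a nucleotide sequence
#'
#' Uppercases, folds U to T, and validates that only A, C, G, T, N remain.
#' Normalization is idempotent.
#'
#' @param x a single nucleotide string.
#' @param id record identifier used in error messages.
#' @return The normalized sequence string.
#' @export
normalize_sequence <- function(x, id = "sequence") {
  x <- toupper(gsub("[ \t\r\n]", "", as.character(x)))
  x <- chartr("U", "T", x)
  if (nchar(x) == 0L) stop("record '", id, "': empty sequence")
  bad <- regmatches(x, regexpr("[^ACGTN]", x))
  if (length(bad) && nzchar(bad)) {
    stop("record '", id, "': invalid character '", bad, "' (only A/C/G/T/N/U allowed)")
  }
  x
}

#' @export
length.upstream_set <- function(x) length(x$id)

#' @export
`[.upstream_set` <- function(x, i) {
  structure(
    list(id = x$id[i], description = x$description[i], sequence = x$sequence[i],
         organism = x$organism[i], source_accession = x$source_accession[i],
         mode = x$mode, label = x$label),
    class = "upstream_set")
}

#' @export
print.upstream_set <- function(x, ...) {
  cat("upstream_set of", length(x), "record(s), mode:", x$mode, "\n")
  n <- min(length(x), 10L)
  for (i in seq_len(n)) {
    cat(sprintf("  %-20s %6d nt  %s\n", x$id[i], nchar(x$sequence[i]),
                substr(x$sequence[i], 1, 30)))
  }
  if (length(x) > n) cat("  ...", length(x) - n, "more\n")
  invisible(x)
}

#' Read a FASTA file of upstream sequences
#'
#' Reads a (possibly multi-line, mixed-case) nucleotide FASTA file. Sequences
#' are normalized (uppercase, U folded to T); duplicate ids and non-nucleotide
#' characters are rejected with informative errors.
#'
#' @param path path to a FASTA file.
#' @param mode `"prokaryote"` or `"eukaryote"`.
#' @param label optional label for the set; defaults to the file name.
#' @return An [upstream_set()].
#' @export
read_fasta <- function(path, mode = c("prokaryote", "eukaryote"), label = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("cannot parse FASTA '", path, "': ",
                                            conditionMessage(e)))
  if (length(seqs) == 0L) stop("no sequences in '", path, "'")
  headers <- names(seqs)
  ids <- sub("[ \t].*$", "", headers)
  desc <- ifelse(grepl("[ \t]", headers), sub("^[^ \t]+[ \t]+", "", headers), "")
  upstream_set(id = ids, sequence = as.character(seqs), description = desc,
               mode = mode, label = if (is.null(label)) basename(path) else label)
}

#' Write an upstream set to FASTA
#'
#' Output wraps sequence lines at 60 columns. Round-trips losslessly through
#' [read_fasta()] for id, description, and sequence.
#'
#' @param x an [upstream_set()]; must be non-empty.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "upstream_set"))
  if (length(x) == 0L) stop("cannot write an empty record set")
  headers <- ifelse(nzchar(x$description), paste(x$id, x$description), x$id)
  s <- Biostrings::BStringSet(x$sequence)
  names(s) <- headers
  Biostrings::writeXStringSet(s, filepath = path, width = 60L)
  invisible(path)
}
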