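#' Center-star multiple sequence alignment
#'
#' Progressive MSA: the center is the input sequence maximizing its summed
#' pairwise alignment score to all others; every other sequence is globally
#' aligned to the center and the pairwise alignments are merged under
#' "once a gap, always a gap". Row order follows input order. For the short
#' sequences this package aligns (uORFs, typically under ~100 codons) the
#' center-star approximation is adequate and keeps the toolchain
#' self-contained and deterministic.
#'
#' @param seqs named character vector (or named list) of at least two
#'   non-empty sequences; names are record ids.
#' @param scheme a [scoring_scheme()]; its `level` sets the alignment
#'   alphabet.
#' @return An object of class `uorf_alignment` with elements `ids`, `rows`
#'   (gapped strings, all of length `n_cols`), `alphabet` (`"amino"` or
#'   `"nucleotide"`), and `n_cols`.
#' @examples
#' center_star_msa(c(a = "MKF", b = "MKF", c = "MK"))
#' @export
center_star_msa <- function(seqs, scheme = scoring_scheme()) {
  seqs <- unlist(seqs)
  if (length(seqs) < 2L) stop("need at least 2 sequences to align")
  if (any(!nzchar(seqs))) stop("empty sequence")
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  n <- length(seqs)

  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    sc <- pairwise_score_vec(seqs[i:n], seqs[[i]], scheme)
    S[i, i:n] <- sc; S[i:n, i] <- sc
  }
  center <- which.max(rowSums(S) - diag(S))   # first index on ties

  rows <- as.list(seqs)                        # gapped rows, built progressively
  master <- seqs[[center]]                     # gapped center row
  done <- center                               # rows already in master coords
  for (k in seq_len(n)) {
    if (k == center) next
    aln <- pairwise_align(seqs[[k]], seqs[[center]], scheme)
    m <- merge_onto_master(master, aln$subject)
    if (length(m$ins_master)) {
      for (j in done) rows[[j]] <- insert_gaps(rows[[j]], m$ins_master)
      master <- insert_gaps(master, m$ins_master)
    }
    rows[[k]] <- insert_gaps(aln$pattern, m$ins_pair)
    done <- c(done, k)
  }
  n_cols <- nchar(master)
  structure(list(ids = unname(ids), rows = unname(unlist(rows)),
                 alphabet = if (scheme$level == "peptide") "amino" else "nucleotide",
                 n_cols = n_cols),
            class = "uorf_alignment")
}

# global alignment returning gapped strings
pairwise_align <- function(pattern, subject, scheme) {
  if (scheme$level == "peptide") {
    p <- Biostrings::AAString(pattern); s <- Biostrings::AAString(subject)
  } else {
    p <- Biostrings::DNAString(pattern); s <- Biostrings::DNAString(subject)
  }
  aln <- Biostrings::pairwiseAlignment(
    p, s, type = "global",
    substitutionMatrix = scheme$substitution_matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  list(pattern = as.character(Biostrings::alignedPattern(aln)),
       subject = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

# walk two gapped versions of the same center sequence; return the column
# positions (in merged coordinates) where gaps must be inserted on each side
merge_onto_master <- function(master, pair_center) {
  a <- strsplit(master, "", fixed = TRUE)[[1]]
  b <- strsplit(pair_center, "", fixed = TRUE)[[1]]
  i <- 1L; j <- 1L; col <- 0L
  ins_master <- integer(0); ins_pair <- integer(0)
  while (i <= length(a) || j <= length(b)) {
    ca <- if (i <= length(a)) a[i] else ""
    cb <- if (j <= length(b)) b[j] else ""
    col <- col + 1L
    if (ca == "-" && cb == "-") { i <- i + 1L; j <- j + 1L }
    else if (ca == "-") { ins_pair <- c(ins_pair, col); i <- i + 1L }
    else if (cb == "-") { ins_master <- c(ins_master, col); j <- j + 1L }
    else if (ca == "" ) { ins_master <- c(ins_master, col); j <- j + 1L }
    else if (cb == "" ) { ins_pair <- c(ins_pair, col); i <- i + 1L }
    else { i <- i + 1L; j <- j + 1L }
  }
  list(ins_master = ins_master, ins_pair = ins_pair)
}

# insert "-" at the given (post-insertion) column positions
insert_gaps <- function(s, cols) {
  if (!length(cols)) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- character(nchar(s) + length(cols))
  out[cols] <- "-"
  out[setdiff(seq_along(out), cols)] <- ch
  paste(out, collapse = "")
}

#' @export
print.uorf_alignment <- function(x, ...) {
  cat("uorf_alignment:", length(x$ids), "rows x", x$n_cols, "columns (",
      x$alphabet, ")\n")
  for (i in seq_along(x$ids)) {
    cat(sprintf("  %-20s %s\n", x$ids[i], x$rows[i]))
  }
  invisible(x)
}

#' Write an alignment as aligned FASTA
#' @param aln a `uorf_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  s <- Biostrings::BStringSet(aln$rows)
  names(s) <- aln$ids
  Biostrings::writeXStringSet(s, filepath = path, width = 60L)
  invisible(path)
}

AMINO_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
NT_ALPHABET <- c("A", "C", "G", "T")

#' Per-column sequence-logo statistics of an alignment
#'
#' For each column: relative frequencies over non-gap symbols of the
#' alignment's alphabet, Shannon information content in bits
#' (`log2(alphabet size) - entropy`), and the consensus symbol (per-column
#' argmax, ties resolved alphabetically, `"-"` for all-gap columns).
#' Ambiguity symbols (X, N) are excluded from the counts like gaps. No
#' small-sample correction is applied. Columns with more than 50% gaps are
#' flagged but still reported.
#'
#' @param aln a `uorf_alignment` from [center_star_msa()].
#' @return An object of class `logo_matrix` with elements `freq` (alphabet x
#'   columns matrix), `info` (bits per column), `consensus` (string),
#'   `gap_frac`, `gappy` (logical, gap fraction > 0.5), and `alphabet`.
#' @export
logo_stats <- function(aln) {
  stopifnot(inherits(aln, "uorf_alignment"))
  ab <- if (aln$alphabet == "amino") AMINO_ALPHABET else NT_ALPHABET
  mat <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  nc <- ncol(mat)
  freq <- matrix(0, length(ab), nc, dimnames = list(ab, NULL))
  info <- numeric(nc)
  cons <- character(nc)
  gap_frac <- numeric(nc)
  for (j in seq_len(nc)) {
    colj <- mat[, j]
    gap_frac[j] <- mean(colj == "-")
    obs <- colj[colj %in% ab]
    if (!length(obs)) {
      cons[j] <- "-"
      next
    }
    f <- table(factor(obs, levels = ab)) / length(obs)
    freq[, j] <- as.numeric(f)
    p <- freq[freq[, j] > 0, j]
    h <- -sum(p * log2(p))
    info[j] <- min(max(log2(length(ab)) - h, 0), log2(length(ab)))
    cons[j] <- ab[which.max(freq[, j])]     # alphabetical on ties
  }
  structure(list(freq = freq, info = info, consensus = paste(cons, collapse = ""),
                 gap_frac = gap_frac, gappy = gap_frac > 0.5, alphabet = ab),
            class = "logo_matrix")
}

#' Write logo statistics as a tab-separated table
#'
#' Columns: `column` (1-based), `symbol`, `freq`, `info_bits`. Only symbols
#' with non-zero frequency are written.
#'
#' @param logo a `logo_matrix` from [logo_stats()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_logo_tsv <- function(logo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("column\tsymbol\tfreq\tinfo_bits", con)
  for (j in seq_len(ncol(logo$freq))) {
    nz <- which(logo$freq[, j] > 0)
    for (i in nz) {
      writeLines(sprintf("%d\t%s\t%.6f\t%.6f", j, rownames(logo$freq)[i],
                         logo$freq[i, j], logo$info[j]), con)
    }
  }
  invisible(path)
}
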