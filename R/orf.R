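#' ORF-calling parameters
#'
#' @param start_codons character vector of 3-mers recognized as start codons.
#'   Default `"ATG"`; add `"GTG"`/`"TTG"` for alternative bacterial starts.
#' @param stop_codons character vector of stop codons.
#' @param min_orf_length minimum ORF length in nucleotides, stop codon
#'   included; must be at least 6 and divisible by 3. The default of 9 nt
#'   means three codons: start, one internal codon, stop.
#' @param sd_window width (nt) of the Shine-Dalgarno search window upstream
#'   of each start codon; default 20.
#' @param sd_threshold hybridization free-energy threshold (kcal/mol) at or
#'   below which an SD annotation is called; default -3.0.
#' @param asd_probe anti-Shine-Dalgarno probe, 5'->3' RNA. The default
#'   `"CCUCCU"` is the reverse complement of the AGGAGG core recognized by
#'   the 16S rRNA 3' tail.
#' @param genetic_code translation table; only `"standard"` is supported.
#' @return An object of class `orf_params`.
#' @export
orf_params <- function(start_codons = "ATG",
                       stop_codons = c("TAA", "TAG", "TGA"),
                       min_orf_length = 9L,
                       sd_window = 20L,
                       sd_threshold = -3.0,
                       asd_probe = "CCUCCU",
                       genetic_code = "standard") {
  start_codons <- toupper(start_codons); stop_codons <- toupper(stop_codons)
  stopifnot(all(nchar(start_codons) == 3L), all(nchar(stop_codons) == 3L))
  min_orf_length <- as.integer(min_orf_length)
  if (min_orf_length < 6L || min_orf_length %% 3L != 0L) {
    stop("min_orf_length must be >= 6 and divisible by 3")
  }
  sd_window <- as.integer(sd_window)
  asd_probe <- toupper(asd_probe)
  if (sd_window < nchar(asd_probe)) {
    stop("sd_window must be at least the length of the aSD probe")
  }
  if (!identical(genetic_code, "standard")) {
    stop("only the standard genetic code is supported")
  }
  structure(list(start_codons = start_codons, stop_codons = stop_codons,
                 min_orf_length = min_orf_length, sd_window = sd_window,
                 sd_threshold = sd_threshold, asd_probe = asd_probe,
                 genetic_code = genetic_code),
            class = "orf_params")
}

new_orf <- function(record_id, start, end, strand, start_codon, nt_seq,
                    peptide, sd = NULL) {
  structure(list(record_id = record_id, start = as.integer(start),
                 end = as.integer(end), strand = strand,
                 frame = as.integer(start %% 3L), start_codon = start_codon,
                 nt_seq = nt_seq, peptide = peptide,
                 length_nt = as.integer(end - start), sd = sd),
            class = "uorf")
}

#' @export
print.uorf <- function(x, ...) {
  cat(sprintf("uORF %s:%d-%d(%s) frame %d  %s  %s%s\n",
              x$record_id, x$start, x$end, x$strand, x$frame, x$start_codon,
              x$peptide,
              if (!is.null(x$sd)) sprintf("  SD dG=%.1f", x$sd$delta_g) else ""))
  invisible(x)
}

#' Enumerate candidate ORFs
#'
#' Every position where a configured start codon begins is paired with the
#' nearest downstream in-frame configured stop codon. ORFs with no in-frame
#' stop before the sequence end are discarded (no open-ended ORFs), as are
#' ORFs shorter than `min_orf_length` (stop codon included). Multiple starts
#' sharing one stop are all reported; the conservation stage selects among
#' them. Codons containing N are never starts or stops.
#'
#' @param x an [upstream_set()] (scanned record by record) or a single
#'   nucleotide sequence string.
#' @param params an [orf_params()] object.
#' @param record_id identifier attached to ORFs when `x` is a bare string.
#' @return For an `upstream_set`, a named list (one element per record, in
#'   record order) of lists of `uorf` objects; for a string, a list of
#'   `uorf` objects sorted by start coordinate.
#' @examples
#' find_orfs("ATGAAATAA")
#' @export
find_orfs <- function(x, params = orf_params(), record_id = "seq") {
  if (inherits(x, "upstream_set")) {
    out <- lapply(seq_len(length(x)), function(i) {
      find_orfs_seq(x$sequence[i], params, x$id[i])
    })
    names(out) <- x$id
    return(out)
  }
  find_orfs_seq(normalize_sequence(x, record_id), params, record_id)
}

find_orfs_seq <- function(seq, params, record_id, strand = "+") {
  L <- nchar(seq)
  if (L < 6L) return(list())
  pos <- seq_len(L - 2L)
  codons <- substring(seq, pos, pos + 2L)
  starts <- pos[codons %in% params$start_codons]     # 1-based
  if (!length(starts)) return(list())
  stops <- pos[codons %in% params$stop_codons]
  if (!length(stops)) return(list())
  orfs <- list()
  for (f in 0:2) {
    st_f <- starts[(starts - 1L) %% 3L == f]
    sp_f <- stops[(stops - 1L) %% 3L == f]
    if (!length(st_f) || !length(sp_f)) next
    sp_f <- sort(sp_f)
    # nearest in-frame stop strictly downstream of the start codon
    idx <- findInterval(st_f + 2L, sp_f) + 1L
    keep <- idx <= length(sp_f)
    st_f <- st_f[keep]; idx <- idx[keep]
    if (!length(st_f)) next
    t_f <- sp_f[idx]
    len <- t_f + 3L - st_f
    keep <- len >= params$min_orf_length
    st_f <- st_f[keep]; t_f <- t_f[keep]
    for (k in seq_along(st_f)) {
      s <- st_f[k]; e <- t_f[k] + 2L
      nt <- substr(seq, s, e)
      orfs[[length(orfs) + 1L]] <-
        new_orf(record_id, start = s - 1L, end = e, strand = strand,
                start_codon = substr(seq, s, s + 2L), nt_seq = nt,
                peptide = orf_peptide(nt, params))
    }
  }
  if (!length(orfs)) return(list())
  st <- vapply(orfs, function(o) o$start, integer(1))
  ln <- vapply(orfs, function(o) o$length_nt, integer(1))
  orfs[order(st, -ln)]
}

# initiator codon is translated as M (fMet) whatever its identity
orf_peptide <- function(nt_seq, params) {
  aa <- translate_nt(nt_seq, params$genetic_code)
  aa <- sub("\\*$", "", aa)
  paste0("M", substr(aa, 2L, nchar(aa)))
}

#' Translate a nucleotide sequence with the standard genetic code
#'
#' Stop codons are rendered as `"*"`; any codon containing N translates to
#' `"X"`.
#'
#' @param nt_seq DNA string whose length is divisible by 3.
#' @param code translation table; only `"standard"`.
#' @return The amino-acid string (stops included as `*`).
#' @examples
#' translate_nt("ATGAAATAA")  # "MK*"
#' @export
translate_nt <- function(nt_seq, code = "standard") {
  nt_seq <- toupper(chartr("U", "T", nt_seq))
  L <- nchar(nt_seq)
  if (L %% 3L != 0L) stop("sequence length not divisible by 3")
  if (L == 0L) return("")
  at <- seq(1L, L, by = 3L)
  codons <- substring(nt_seq, at, at + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa[grepl("N", codons, fixed = TRUE)] <- "X"
  paste(aa, collapse = "")
}

#' Reverse complement of a DNA string
#' @param x DNA string over A/C/G/T/N.
#' @return The reverse complement string.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}
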