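# default planted uORF: 45 nt = start + 13 codons + stop, leader-peptide-like
DEFAULT_PLANTED_NT <-
  "ATGGGTATTTTCAGCATCTTTGTTATCTCAACTGTTCACCGTTAA"

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random decoy ORF: ATG + (n_codons) non-stop codons + random stop
random_orf <- function(n_internal_codons,
                       stop_codons = c("TAA", "TAG", "TGA")) {
  bases <- c("A", "C", "G", "T")
  internal <- character(n_internal_codons)
  for (i in seq_len(n_internal_codons)) {
    repeat {
      cod <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      if (!(cod %in% stop_codons)) break
    }
    internal[i] <- cod
  }
  paste0("ATG", paste(internal, collapse = ""), sample(stop_codons, 1))
}

# substitute bases at `rate` per site outside start/stop codons; internal
# codons that become stops are re-randomized at their mutated positions
mutate_orf <- function(nt, rate, stop_codons = c("TAA", "TAG", "TGA")) {
  L <- nchar(nt)
  ch <- strsplit(nt, "", fixed = TRUE)[[1]]
  mutable <- setdiff(seq_len(L), c(1:3, (L - 2):L))
  hit <- mutable[stats::runif(length(mutable)) < rate]
  bases <- c("A", "C", "G", "T")
  for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1)
  repeat {
    codon_starts <- seq(4L, L - 5L, by = 3L)
    if (!length(codon_starts)) break
    bad <- codon_starts[vapply(codon_starts, function(s) {
      paste(ch[s:(s + 2)], collapse = "") %in% stop_codons
    }, logical(1))]
    if (!length(bad)) break
    for (s in bad) {
      pos <- intersect(s:(s + 2), hit)
      if (!length(pos)) pos <- s:(s + 2)  # cannot happen for a valid input
      for (i in pos) ch[i] <- sample(setdiff(bases, ch[i]), 1)
    }
  }
  paste(ch, collapse = "")
}

# pick a placement interval [start0, start0+len) avoiding occupied intervals
place_interval <- function(len, total, occupied, tries = 200L) {
  for (k in seq_len(tries)) {
    s <- sample.int(total - len + 1L, 1L) - 1L
    e <- s + len
    clash <- any(vapply(occupied, function(iv) s < iv[2] && iv[1] < e,
                        logical(1)))
    if (!clash) return(c(s, e))
  }
  NULL
}

#' Generate a synthetic upstream-sequence set with a planted conserved uORF
#'
#' Each record is a random background sequence (uniform A/C/G/T by default,
#' GC content adjustable) into which one copy of the planted uORF is
#' inserted at a random position, plus `n_decoys` random unrelated ORFs in
#' non-overlapping positions. Planted copies diverge by per-site
#' substitutions at `mutation_rate`; start and stop codons are never mutated
#' and substitutions creating an internal in-frame stop are resampled, so
#' the planted ORF remains a valid candidate at any rate — divergence
#' stresses the conservation search, not ORF calling. Fully reproducible
#' from `seed`.
#'
#' @param n_records number of records (default 8).
#' @param record_length length of each record in nt (default 500).
#' @param planted_nt the planted uORF (valid ORF under default
#'   [orf_params()]: ATG start, terminal stop, no internal stop); default a
#'   built-in 45-nt uORF.
#' @param mutation_rate per-site substitution rate in `[0, 0.5)` applied to
#'   planted copies (default 0.05).
#' @param n_decoys unrelated decoy ORFs per record (default 3).
#' @param seed integer RNG seed.
#' @param gc background GC content (default 0.5).
#' @param mode record mode for the generated set.
#' @return A list with `records` (an [upstream_set()]) and `truth` (class
#'   `synthetic_truth`: planted peptide, per-record coordinates, rates,
#'   sizes, seed).
#' @export
generate_dataset <- function(n_records = 8L, record_length = 500L,
                             planted_nt = DEFAULT_PLANTED_NT,
                             mutation_rate = 0.05, n_decoys = 3L, seed = 1L,
                             gc = 0.5, mode = "prokaryote") {
  planted_nt <- normalize_sequence(planted_nt, "planted_nt")
  if (mutation_rate < 0 || mutation_rate >= 0.5) {
    stop("mutation_rate must be in [0, 0.5)")
  }
  po <- find_orfs(planted_nt)
  ok <- any(vapply(po, function(o) {
    o$start == 0L && o$end == nchar(planted_nt)
  }, logical(1)))
  if (!ok) stop("planted_nt is not a valid ORF under default parameters")
  plen <- nchar(planted_nt)
  if (record_length < plen + 30L) stop("record_length too short for the planted ORF")

  with_seed(seed, {
    ids <- sprintf("synth_%02d", seq_len(n_records))
    seqs <- character(n_records)
    coords <- data.frame(record_id = ids, start = 0L, end = 0L,
                         stringsAsFactors = FALSE)
    for (r in seq_len(n_records)) {
      bg <- strsplit(random_dna(record_length, gc), "", fixed = TRUE)[[1]]
      occupied <- list()
      iv <- place_interval(plen, record_length, occupied)
      copy <- mutate_orf(planted_nt, mutation_rate)
      bg[(iv[1] + 1L):iv[2]] <- strsplit(copy, "", fixed = TRUE)[[1]]
      occupied[[1]] <- iv
      coords$start[r] <- iv[1]; coords$end[r] <- iv[2]
      placed <- 0L
      while (placed < n_decoys) {
        dec <- random_orf(sample(2:13, 1))
        div <- place_interval(nchar(dec), record_length, occupied)
        if (is.null(div)) break
        bg[(div[1] + 1L):div[2]] <- strsplit(dec, "", fixed = TRUE)[[1]]
        occupied[[length(occupied) + 1L]] <- div
        placed <- placed + 1L
      }
      seqs[r] <- paste(bg, collapse = "")
    }
    records <- upstream_set(ids, seqs, mode = mode,
                            label = sprintf("synthetic planted-uORF set (seed %d)",
                                            seed))
    truth <- structure(
      list(planted_peptide = sub("\\*$", "", translate_nt(planted_nt)),
           planted_nt = planted_nt, coords = coords,
           mutation_rate = mutation_rate, seed = as.integer(seed),
           n_records = as.integer(n_records),
           record_length = as.integer(record_length),
           n_decoys_per_record = as.integer(n_decoys)),
      class = "synthetic_truth")
    list(records = records, truth = truth)
  })
}

#' Score recovery of the planted uORF
#'
#' A record counts as recovered when the top-ranked conserved path contains
#' an ORF whose start and end both match the planted coordinates within
#' `tolerance_nt`.
#'
#' @param paths list of `conserved_path` objects from [greedy_search()]
#'   (ranked; the first is the top path). May be empty.
#' @param truth a `synthetic_truth` from [generate_dataset()].
#' @param tolerance_nt coordinate tolerance in nt (default 0: exact).
#' @return A list of class `recovery_report` with `per_record` (data frame:
#'   record_id, hit) and `recall`.
#' @export
score_recovery <- function(paths, truth, tolerance_nt = 0L) {
  stopifnot(inherits(truth, "synthetic_truth"), tolerance_nt >= 0)
  hits <- logical(nrow(truth$coords))
  if (length(paths)) {
    top <- paths[[1L]]
    for (r in seq_len(nrow(truth$coords))) {
      o <- top$members[[truth$coords$record_id[r]]]
      if (!is.null(o) &&
          abs(o$start - truth$coords$start[r]) <= tolerance_nt &&
          abs(o$end - truth$coords$end[r]) <= tolerance_nt) {
        hits[r] <- TRUE
      }
    }
  }
  structure(list(per_record = data.frame(record_id = truth$coords$record_id,
                                         hit = hits, stringsAsFactors = FALSE),
                 recall = mean(hits)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("planted-uORF recovery: %d/%d records, recall %.2f\n",
              sum(x$per_record$hit), nrow(x$per_record), x$recall))
  invisible(x)
}

#' Write the synthetic truth table
#'
#' Tab-separated columns: record_id, start, end, peptide.
#'
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  df <- truth$coords
  df$peptide <- truth$planted_peptide
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
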