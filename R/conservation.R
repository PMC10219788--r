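#' Alignment scoring scheme
#'
#' Controls how candidate ORFs are compared: globally (end-to-end) aligned
#' with affine gap penalties at the peptide level (default, BLOSUM62) or the
#' nucleotide level (match +2 / mismatch -3). Leader peptides are conserved
#' at the amino-acid level, hence the peptide default; nucleotide mode suits
#' very short ORFs.
#'
#' @param level `"peptide"` or `"nucleotide"`.
#' @param substitution_matrix optional square scoring matrix with dimnames;
#'   defaults to BLOSUM62 (peptide) or match +2 / mismatch -3 (nucleotide).
#' @param gap_open gap opening penalty (positive, default 10).
#' @param gap_extend gap extension penalty (positive, default 1); a gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(level = c("peptide", "nucleotide"),
                           substitution_matrix = NULL,
                           gap_open = 10, gap_extend = 1) {
  level <- match.arg(level)
  if (!(gap_open >= gap_extend && gap_extend > 0)) {
    stop("gap_open >= gap_extend > 0 required")
  }
  if (is.null(substitution_matrix)) {
    substitution_matrix <- if (level == "peptide") {
      blosum62_matrix()
    } else {
      nt_matrix(match = 2, mismatch = -3)
    }
  }
  structure(list(level = level, substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

nt_matrix <- function(match = 2, mismatch = -3) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- mismatch; m[, "N"] <- mismatch   # N never matches
  m
}

orf_level_seq <- function(orf, level) {
  if (identical(level, "peptide")) orf$peptide else orf$nt_seq
}

align_score <- function(s1, s2, scheme) {
  pairwise_score_vec(s1, s2, scheme)[1L]
}

# vectorized: scores of each element of `patterns` against one `subject`
pairwise_score_vec <- function(patterns, subject, scheme) {
  if (scheme$level == "peptide") {
    p <- Biostrings::AAStringSet(patterns)
    s <- Biostrings::AAString(subject)
  } else {
    p <- Biostrings::DNAStringSet(patterns)
    s <- Biostrings::DNAString(subject)
  }
  Biostrings::pairwiseAlignment(
    p, s, type = "global",
    substitutionMatrix = scheme$substitution_matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    scoreOnly = TRUE)
}

#' Global alignment score between two candidate ORFs
#'
#' End-to-end (global) affine-gap alignment score of the two ORFs at the
#' scheme's level (peptides by default). Symmetric in its arguments.
#'
#' @param a,b `uorf` objects (or bare sequence strings at the chosen level).
#' @param scheme a [scoring_scheme()].
#' @return The alignment score (numeric scalar).
#' @export
pairwise_score <- function(a, b, scheme = scoring_scheme()) {
  s1 <- if (inherits(a, "uorf")) orf_level_seq(a, scheme$level) else a
  s2 <- if (inherits(b, "uorf")) orf_level_seq(b, scheme$level) else b
  if (!nzchar(s1) || !nzchar(s2)) stop("empty sequence in pairwise_score")
  align_score(s1, s2, scheme)
}

# full score matrix over a set of sequences (unique-collapsed internally)
score_matrix <- function(seqs, scheme) {
  us <- unique(seqs)
  n <- length(us)
  S <- matrix(0, n, n, dimnames = list(us, us))
  for (i in seq_len(n)) {
    sc <- pairwise_score_vec(us[i:n], us[i], scheme)
    S[i, i:n] <- sc
    S[i:n, i] <- sc
  }
  S
}

member_key <- function(orf) paste(orf$record_id, orf$start, orf$end, orf$strand)

new_conserved_path <- function(members, total_score, coverage, seed) {
  structure(list(members = members, total_score = total_score,
                 coverage = coverage, seed = seed),
            class = "conserved_path")
}

#' @export
print.conserved_path <- function(x, ...) {
  cat(sprintf("conserved_path: %d member(s), coverage %.2f, total score %.1f\n",
              length(x$members), x$coverage, x$total_score))
  for (o in x$members) {
    cat(sprintf("  %-20s %5d-%5d (%s)  %s\n", o$record_id, o$start, o$end,
                o$strand, o$peptide))
  }
  invisible(x)
}

#' Conservation-search parameters
#'
#' @param min_coverage minimum fraction of records a reported path must
#'   cover (default 0.67).
#' @param accept_ratio a candidate joins a path only if its mean pairwise
#'   score against current members is at least `accept_ratio` times the mean
#'   self-score of those members (default 0.5). Normalizing by self-score
#'   makes one threshold serve both 3-codon and 60-codon uORFs.
#' @param max_paths maximum number of paths reported (default 10).
#' @return An object of class `conservation_params`.
#' @export
conservation_params <- function(min_coverage = 0.67, accept_ratio = 0.5,
                                max_paths = 10L) {
  stopifnot(min_coverage > 0, min_coverage <= 1,
            accept_ratio > 0, accept_ratio <= 1, max_paths >= 1)
  structure(list(min_coverage = min_coverage, accept_ratio = accept_ratio,
                 max_paths = as.integer(max_paths)),
            class = "conservation_params")
}

#' Greedy search for conserved ORFs across records
#'
#' Selects, across the record set, sets of mutually similar candidate ORFs
#' (at most one per record) by greedily maximizing the sum of pairwise
#' alignment scores. Every candidate of every record serves once as a seed;
#' for each seed the remaining records are visited in record order and from
#' each record the candidate maximizing the summed score to current members
#' joins, provided it passes the `accept_ratio` gate (records may be
#' skipped). Ties break toward higher score, then smaller start coordinate,
#' then longer ORF. Resulting paths are filtered to `min_coverage`,
#' deduplicated (paths sharing more than half their members collapse to the
#' higher-scoring one), sorted by total score, and truncated to `max_paths`.
#'
#' @param candidates named list mapping record id to a list of `uorf`
#'   candidates, in record order (e.g. from [find_orfs()]); records with no
#'   candidates may be present as empty lists.
#' @param scheme a [scoring_scheme()].
#' @param params a [conservation_params()].
#' @return List of `conserved_path` objects sorted by decreasing
#'   `total_score` (possibly empty).
#' @export
greedy_search <- function(candidates, scheme = scoring_scheme(),
                          params = conservation_params()) {
  stopifnot(is.list(candidates), !is.null(names(candidates)))
  record_ids <- names(candidates)
  n_records <- length(record_ids)
  nonempty <- record_ids[vapply(candidates, length, integer(1)) > 0L]
  if (length(nonempty) < 2L) stop("nothing to compare")

  # flatten candidates; cache all pairwise scores over unique sequences
  flat <- list()
  for (rid in record_ids) {
    for (o in candidates[[rid]]) {
      flat[[length(flat) + 1L]] <- list(rid = rid, orf = o,
                                        seq = orf_level_seq(o, scheme$level))
    }
  }
  seqs <- vapply(flat, `[[`, character(1), "seq")
  if (any(!nzchar(seqs))) stop("empty sequence among candidates")
  S <- score_matrix(seqs, scheme)
  sc <- function(s1, s2) S[s1, s2]
  by_record <- split(seq_along(flat), vapply(flat, `[[`, character(1), "rid"))

  paths <- list()
  for (seed_i in seq_along(flat)) {
    seed <- flat[[seed_i]]
    mem_idx <- seed_i
    mem_rid <- seed$rid
    for (rid in setdiff(record_ids, seed$rid)) {
      ci <- by_record[[rid]]
      if (is.null(ci) || !length(ci)) next
      ssum <- vapply(ci, function(j) {
        sum(S[seqs[j], seqs[mem_idx]])
      }, numeric(1))
      starts <- vapply(ci, function(j) flat[[j]]$orf$start, integer(1))
      lens <- vapply(ci, function(j) flat[[j]]$orf$length_nt, integer(1))
      best <- order(-ssum, starts, -lens)[1L]
      mean_self <- mean(vapply(mem_idx, function(j) S[seqs[j], seqs[j]],
                               numeric(1)))
      if (ssum[best] / length(mem_idx) >= params$accept_ratio * mean_self) {
        mem_idx <- c(mem_idx, ci[best])
        mem_rid <- c(mem_rid, rid)
      }
    }
    total <- 0
    if (length(mem_idx) > 1L) {
      for (a in seq_len(length(mem_idx) - 1L)) {
        for (b in (a + 1L):length(mem_idx)) {
          total <- total + S[seqs[mem_idx[a]], seqs[mem_idx[b]]]
        }
      }
    }
    ord <- match(record_ids, mem_rid)
    ord <- ord[!is.na(ord)]                    # members in record order
    members <- stats::setNames(lapply(mem_idx[ord], function(j) flat[[j]]$orf),
                               mem_rid[ord])
    paths[[length(paths) + 1L]] <-
      new_conserved_path(members, total, length(members) / n_records,
                         seed = list(record_id = seed$rid, orf = seed$orf))
  }

  paths <- Filter(function(p) p$coverage >= params$min_coverage, paths)
  if (!length(paths)) return(list())
  totals <- vapply(paths, `[[`, numeric(1), "total_score")
  paths <- paths[order(-totals, seq_along(paths))]   # stable: seed order on ties

  kept <- list()
  kept_keys <- list()
  for (p in paths) {
    keys <- vapply(p$members, member_key, character(1))
    dup <- any(vapply(kept_keys, function(k) {
      length(intersect(k, keys)) / min(length(k), length(keys)) > 0.5
    }, logical(1)))
    if (!dup) {
      kept[[length(kept) + 1L]] <- p
      kept_keys[[length(kept_keys) + 1L]] <- keys
    }
    if (length(kept) >= params$max_paths) break
  }
  kept
}

#' Recompute a conserved path's total score from scratch
#'
#' Integrity check: sums [pairwise_score()] over all unordered member pairs.
#' The result must equal the stored `total_score` (within 1e-9 in tests).
#'
#' @param path a `conserved_path` with at least two members.
#' @param scheme the [scoring_scheme()] used to build the path.
#' @return The recomputed total score.
#' @export
recompute_score <- function(path, scheme = scoring_scheme()) {
  m <- path$members
  if (length(m) < 2L) stop("path must have at least 2 members")
  total <- 0
  for (a in seq_len(length(m) - 1L)) {
    for (b in (a + 1L):length(m)) {
      total <- total + pairwise_score(m[[a]], m[[b]], scheme)
    }
  }
  total
}
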