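# Shared fixtures and independent oracles, all built in code.

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# independent ORF oracle: plain triple loop over positions and codon walks
brute_force_orfs <- function(seq, params = orf_params()) {
  L <- nchar(seq)
  out <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_len(max(L - 2, 0))) {
    if (!(substr(seq, i, i + 2) %in% params$start_codons)) next
    t <- i + 3
    while (t + 2 <= L) {
      if (substr(seq, t, t + 2) %in% params$stop_codons) {
        if (t + 3 - i >= params$min_orf_length) {
          out <- rbind(out, data.frame(start = i - 1L, end = t + 2L))
        }
        break
      }
      t <- t + 3
    }
  }
  out[order(out$start, out$start - out$end), , drop = FALSE]
}

orf_coord_df <- function(orfs) {
  if (!length(orfs)) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = vapply(orfs, `[[`, integer(1), "start"),
             end = vapply(orfs, `[[`, integer(1), "end"))
}

# independent duplex-energy oracle: reads the shipped table directly and
# hand-sums stacks over a window known to pair end to end
indep_perfect_duplex <- function(probe) {
  tab <- read.delim(system.file("extdata", "rna_stack_energies.tsv",
                                package = "uorfscout"),
                    comment.char = "#", stringsAsFactors = FALSE)
  dg <- setNames(tab$dG_kcal_mol, tab$stack)
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  p <- strsplit(probe, "")[[1]]
  mate <- unname(comp[p])
  total <- dg[["initiation"]]
  for (i in seq_len(length(p) - 1)) {
    total <- total + dg[[paste0(p[i], p[i + 1], "/", mate[i], mate[i + 1])]]
  }
  total
}

# target (5'->3') that pairs perfectly and antiparallel with an RNA probe
perfect_target_dna <- function(probe) {
  comp <- c(A = "T", U = "A", G = "C", C = "G")
  paste(rev(unname(comp[strsplit(probe, "")[[1]]])), collapse = "")
}

# construct a candidate uorf directly (conservation-stage fixtures)
make_orf <- function(record_id, peptide, start = 0L) {
  codon <- c(M = "ATG", K = "AAA", L = "CTG", F = "TTT", A = "GCT",
             G = "GGT", S = "TCT", T = "ACT", V = "GTT", I = "ATT",
             R = "CGT", E = "GAA", D = "GAT", P = "CCT", W = "TGG",
             Y = "TAT", H = "CAT", Q = "CAA", N = "AAT", C = "TGT")
  nt <- paste0(paste(codon[strsplit(peptide, "")[[1]]], collapse = ""), "TAA")
  end <- start + nchar(nt)
  uorfscout:::new_orf(record_id, start, end, "+", substr(nt, 1, 3), nt, peptide)
}

# exhaustive oracle for the conservation search: enumerate every
# one-candidate-or-skip selection per record and maximize the summed
# pairwise score subject to the coverage floor; all pairwise scores are
# precomputed once so enumeration is pure table lookup
exhaustive_best_path <- function(candidates, scheme = scoring_scheme(),
                                 min_coverage = 0.67) {
  rids <- names(candidates)
  n <- length(rids)
  flat <- list(); rec_of <- integer(0); idx_of <- integer(0)
  for (r in seq_len(n)) {
    for (k in seq_along(candidates[[r]])) {
      flat[[length(flat) + 1]] <- candidates[[r]][[k]]
      rec_of <- c(rec_of, r); idx_of <- c(idx_of, k)
    }
  }
  m <- length(flat)
  S <- matrix(0, m, m)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (a < b) S[a, b] <- S[b, a] <- pairwise_score(flat[[a]], flat[[b]],
                                                      scheme)
    }
  }
  flat_id <- function(r, k) which(rec_of == r & idx_of == k)
  grid <- expand.grid(lapply(candidates, function(x) 0:length(x)),
                      KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    pick <- as.integer(grid[g, ])
    used <- which(pick > 0)
    if (length(used) < 2 || length(used) / n < min_coverage) next
    ii <- vapply(used, function(r) flat_id(r, pick[r]), integer(1))
    total <- sum(S[ii, ii]) / 2
    if (is.null(best) || total > best$total) {
      best <- list(total = total,
                   keys = sort(unname(vapply(flat[ii], uorfscout:::member_key,
                                             character(1)))))
    }
  }
  best
}

path_member_keys <- function(path) {
  sort(unname(vapply(path$members, uorfscout:::member_key, character(1))))
}

# mock NCBI transport: dispatches canned responses on URL patterns and
# records every URL it is asked for
mock_transport <- function(responses, log = new.env()) {
  log$urls <- character(0)
  f <- function(url) {
    log$urls <- c(log$urls, url)
    for (pat in names(responses)) {
      if (grepl(pat, url, fixed = TRUE)) {
        r <- responses[[pat]]
        if (inherits(r, "condition")) stop(r)
        return(r)
      }
    }
    stop("mock transport: unexpected url ", url)
  }
  attr(f, "log") <- log
  f
}

ipg_table_lines <- function(nuc = "NZ_TEST01", start = 1201, stop = 1935,
                            strand = "+") {
  c(paste("Id", "Source", "Nucleotide Accession", "Start", "Stop", "Strand",
          "Protein", "Protein Name", sep = "\t"),
    paste("1", "RefSeq", nuc, start, stop, strand, "WP_X", "test", sep = "\t"))
}
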