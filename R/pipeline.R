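#' Scan upstream sequences for conserved uORFs
#'
#' The main entry point. Runs the offline workflow on a set of 5' upstream
#' sequences: ORF annotation in every record (with Shine-Dalgarno
#' free-energy scanning in prokaryote mode), greedy conserved-ORF search
#' maximizing the sum of pairwise alignment scores, then a center-star MSA
#' and sequence-logo statistics for every reported path.
#'
#' @param x an [upstream_set()] or a path to a nucleotide FASTA file.
#' @param config a [load_config()] / `uorf_config` object.
#' @return An object of class `uorf_scan` with components `records`,
#'   `candidates` (per-record ORF lists), `paths` (ranked
#'   `conserved_path`s), `alignments`, `logos`, and `config`. Absence of any
#'   conserved path is a valid result (empty `paths`, with a warning), not
#'   an error.
#' @seealso [run_pipeline()] to also write reports and figures.
#' @examples
#' d <- generate_dataset(n_records = 4, record_length = 300, seed = 7)
#' fit <- uorf_scan(d$records)
#' fit
#' @export
uorf_scan <- function(x, config = load_config()) {
  stopifnot(inherits(config, "uorf_config"))
  records <- if (inherits(x, "upstream_set")) x else {
    read_fasta(x, mode = config$mode)
  }
  if (!identical(records$mode, config$mode)) records$mode <- config$mode
  if (length(records) < 2L) stop("nothing to compare (need at least 2 sequences)")

  params <- orf_params_from_config(config)
  scheme <- scoring_scheme_from_config(config)
  cpar <- conservation_params_from_config(config)

  candidates <- find_orfs(records, params)
  if (isTRUE(config$scan_reverse)) {
    for (i in seq_len(length(records))) {
      rc <- find_orfs_seq(revcomp(records$sequence[i]), params,
                          records$id[i], strand = "-")
      candidates[[records$id[i]]] <- c(candidates[[records$id[i]]], rc)
    }
  }
  if (identical(config$mode, "prokaryote")) {
    candidates <- annotate_sd(records, candidates, params)
  }

  n_with <- sum(vapply(candidates, length, integer(1)) > 0L)
  paths <- list()
  if (n_with >= 2L) {
    paths <- greedy_search(candidates, scheme, cpar)
  }
  if (!length(paths)) {
    warning("no conserved uORFs found at min_coverage ",
            format(cpar$min_coverage), call. = FALSE)
  }

  alignments <- list(); logos <- list()
  for (i in seq_along(paths)) {
    seqs <- vapply(paths[[i]]$members, orf_level_seq, character(1),
                   level = config$level)
    if (length(seqs) >= 2L) {
      aln <- center_star_msa(seqs, scheme)
      alignments[[i]] <- aln
      logos[[i]] <- logo_stats(aln)
    }
  }

  structure(list(records = records, candidates = candidates, paths = paths,
                 alignments = alignments, logos = logos, config = config),
            class = "uorf_scan")
}

#' @export
print.uorf_scan <- function(x, ...) {
  cat("uorfscout scan\n")
  cat(sprintf("  records:    %d (%s mode)\n", length(x$records), x$records$mode))
  cat(sprintf("  candidates: %d ORFs\n", sum(lengths(x$candidates))))
  cat(sprintf("  conserved paths: %d\n", length(x$paths)))
  if (length(x$paths)) {
    p <- x$paths[[1L]]
    cat(sprintf("  top path: %d member(s), coverage %.2f, total score %.1f\n",
                length(p$members), p$coverage, p$total_score))
    if (length(x$logos)) {
      cat("  top path consensus:", x$logos[[1L]]$consensus, "\n")
    }
  }
  invisible(x)
}

#' @export
summary.uorf_scan <- function(object, ...) {
  tab <- path_summary_table(object)
  structure(list(n_records = length(object$records),
                 n_candidates = sum(lengths(object$candidates)),
                 paths = tab,
                 top_members = if (length(object$paths)) {
                   path_table(object$paths[[1L]])
                 } else NULL),
            class = "summary.uorf_scan")
}

#' @export
print.summary.uorf_scan <- function(x, ...) {
  cat(sprintf("uorfscout scan: %d records, %d candidate ORFs, %d path(s)\n\n",
              x$n_records, x$n_candidates, nrow(x$paths)))
  if (nrow(x$paths)) {
    print(x$paths, row.names = FALSE)
    cat("\ntop path members:\n")
    print(x$top_members, row.names = FALSE)
  } else {
    cat("no conserved uORFs found\n")
  }
  invisible(x)
}

#' Plot method: locus annotation sketch with base graphics
#'
#' Draws one track per record with candidate ORFs (grey outline), conserved
#' path members (filled), and SD marks; an on-screen counterpart of
#' [render_annotation_plot()].
#'
#' @param x a `uorf_scan` object.
#' @param ... ignored.
#' @export
plot.uorf_scan <- function(x, ...) {
  n <- length(x$records)
  maxlen <- max(nchar(x$records$sequence))
  conserved <- list()
  for (pi in seq_along(x$paths)) {
    for (o in x$paths[[pi]]$members) conserved[[member_key(o)]] <- pi
  }
  graphics::plot(NULL, xlim = c(-0.28 * maxlen, maxlen * 1.03),
                 ylim = c(n + 0.5, 0.5), xlab = "position (nt)", ylab = "",
                 yaxt = "n", bty = "n", main = "upstream regions")
  for (i in seq_len(n)) {
    rid <- x$records$id[i]
    slen <- nchar(x$records$sequence[i])
    graphics::segments(0, i, slen, i, col = "grey40")
    graphics::text(-0.02 * maxlen, i, rid, adj = 1, cex = 0.7)
    for (o in x$candidates[[rid]]) {
      pi <- conserved[[member_key(o)]]
      if (is.null(pi)) {
        graphics::rect(o$start, i - 0.12, o$end, i + 0.12, border = "grey60")
      } else {
        col <- PATH_PALETTE[(pi - 1) %% length(PATH_PALETTE) + 1]
        graphics::rect(o$start, i - 0.18, o$end, i + 0.18, col = col,
                       border = "black")
      }
      if (!is.null(o$sd)) {
        sx <- o$sd$window_start + o$sd$match_offset
        graphics::segments(sx, i - 0.3, sx, i - 0.18, col = "red", lwd = 2)
      }
    }
  }
  invisible(x)
}

path_table <- function(path) {
  data.frame(
    record_id = names(path$members),
    start = vapply(path$members, `[[`, integer(1), "start"),
    end = vapply(path$members, `[[`, integer(1), "end"),
    strand = vapply(path$members, `[[`, character(1), "strand"),
    start_codon = vapply(path$members, `[[`, character(1), "start_codon"),
    peptide = vapply(path$members, `[[`, character(1), "peptide"),
    sd_delta_g = vapply(path$members, function(o) {
      if (is.null(o$sd)) NA_real_ else o$sd$delta_g
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

path_summary_table <- function(res) {
  if (!length(res$paths)) {
    return(data.frame(rank = integer(0), total_score = numeric(0),
                      coverage = numeric(0), n_members = integer(0),
                      consensus = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    rank = seq_along(res$paths),
    total_score = vapply(res$paths, `[[`, numeric(1), "total_score"),
    coverage = vapply(res$paths, `[[`, numeric(1), "coverage"),
    n_members = vapply(res$paths, function(p) length(p$members), integer(1)),
    consensus = vapply(seq_along(res$paths), function(i) {
      if (i <= length(res$logos) && !is.null(res$logos[[i]])) {
        res$logos[[i]]$consensus
      } else ""
    }, character(1)),
    stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline and write all outputs
#'
#' Runs [uorf_scan()] and writes, into `config$output_dir`: the upstream
#' FASTA (intermediate output), a ranked path summary table, one
#' tab-separated results table + aligned FASTA + logo table per conserved
#' path, the SVG annotation plot, per-path SVG logos and MSA panels, and a
#' run log echoing every effective parameter (a run is reconstructible from
#' its log). Finding no conserved uORF is a valid result: the run completes
#' with a warning and an empty summary table.
#'
#' @param config a `uorf_config` from [load_config()].
#' @param input FASTA path or [upstream_set()].
#' @return The `uorf_scan` object, invisibly; outputs under
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config, input) {
  res <- withCallingHandlers(
    uorf_scan(input, config),
    warning = function(w) {
      message("uorfscout: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)

  write_fasta(res$records, out("upstream_sequences.fa"))
  write_tsv(path_summary_table(res), out("path_summary.tsv"))
  for (i in seq_along(res$paths)) {
    write_tsv(path_table(res$paths[[i]]), out(sprintf("uorf_path_%02d.tsv", i)))
    if (i <= length(res$alignments) && !is.null(res$alignments[[i]])) {
      write_alignment_fasta(res$alignments[[i]], out(sprintf("msa_%02d.fa", i)))
      write_logo_tsv(res$logos[[i]], out(sprintf("logo_%02d.tsv", i)))
      render_logo(res$logos[[i]], out(sprintf("logo_%02d.svg", i)))
      render_msa(res$alignments[[i]], out(sprintf("msa_%02d.svg", i)))
    }
  }
  if (length(res$paths) || sum(lengths(res$candidates))) {
    render_annotation_plot(res$records, res$paths, res$candidates,
                           out("annotation_plot.svg"))
  }
  log_lines <- c("uorfscout run log",
                 paste0("n_records: ", length(res$records)),
                 paste0("n_candidates: ", sum(lengths(res$candidates))),
                 paste0("n_paths: ", length(res$paths)),
                 "config:",
                 vapply(names(res$config), function(k) {
                   sprintf("  %s: %s", k, paste(res$config[[k]], collapse = " "))
                 }, character(1)))
  writeLines(log_lines, out("run.log"))
  invisible(res)
}
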