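#' Load the RNA:RNA duplex energy model
#'
#' The model is an additive nearest-neighbor stack table: the free energy of
#' an ungapped duplex is the sum of stack terms over adjacent base pairs plus
#' a duplex initiation penalty. Allowed pairs are A:U, U:A, G:C, C:G and the
#' G:U/U:G wobble. Watson-Crick stack values follow Freier-style RNA duplex
#' parameters; wobble-containing stacks carry coarse uniform values (see the
#' packaged table's header for provenance). Loops and bulges are not modeled:
#' only contiguous ungapped duplexes are scored.
#'
#' @param path path to a tab-separated table with columns `stack` (e.g.
#'   `"GC/CG"`, probe 5'->3' over target 3'->5') and `dG_kcal_mol`; a row
#'   named `initiation` holds the initiation penalty. Defaults to the table
#'   shipped with the package.
#' @return An object of class `energy_model` with elements `stacks` (named
#'   numeric), `initiation`, and `allowed_pairs`.
#' @export
energy_model <- function(path = system.file("extdata", "rna_stack_energies.tsv",
                                            package = "uorfscout")) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("stack", "dG_kcal_mol") %in% names(tab)))
  init <- tab$dG_kcal_mol[tab$stack == "initiation"]
  if (length(init) != 1L) stop("energy table must contain one 'initiation' row")
  tab <- tab[tab$stack != "initiation", , drop = FALSE]
  stacks <- stats::setNames(tab$dG_kcal_mol, tab$stack)
  structure(list(stacks = stacks, initiation = init,
                 allowed_pairs = c("AU", "UA", "GC", "CG", "GU", "UG")),
            class = "energy_model")
}

#' Hybridization free energy of an ungapped RNA duplex
#'
#' The probe and target (both 5'->3', equal length) are paired antiparallel:
#' probe position i pairs with target position L+1-i. The energy is the sum
#' of nearest-neighbor stack terms over the longest contiguous run of allowed
#' pairs, plus the initiation penalty. If fewer than two contiguous pairs
#' form, no stable duplex exists and 0 is returned.
#'
#' @param probe RNA string (T is folded to U).
#' @param target RNA string of the same length.
#' @param model an [energy_model()].
#' @return Free energy in kcal/mol (more negative = stronger duplex).
#' @examples
#' duplex_energy("CCUCCU", "AGGAGG")
#' @export
duplex_energy <- function(probe, target, model = energy_model()) {
  probe <- toupper(chartr("T", "U", probe))
  target <- toupper(chartr("T", "U", target))
  L <- nchar(probe)
  if (nchar(target) != L) stop("probe and target must have equal length")
  if (L < 2L) return(0)
  p <- strsplit(probe, "", fixed = TRUE)[[1]]
  t <- strsplit(target, "", fixed = TRUE)[[1]]
  mate <- rev(t)                            # mate[i] pairs with p[i]
  ok <- paste0(p, mate) %in% model$allowed_pairs
  r <- rle(ok)
  if (!any(r$values & r$lengths >= 2L)) return(0)
  ends <- cumsum(r$lengths)
  runs <- which(r$values & r$lengths >= 2L)
  best <- runs[which.max(r$lengths[runs])]  # longest run, leftmost on ties
  i1 <- ends[best] - r$lengths[best] + 1L
  i2 <- ends[best]
  idx <- i1:(i2 - 1L)
  keys <- paste0(p[idx], p[idx + 1L], "/", mate[idx], mate[idx + 1L])
  dg <- model$stacks[keys]
  if (anyNA(dg)) stop("missing stack parameter: ", keys[which(is.na(dg))[1L]])
  model$initiation + sum(dg)
}

#' Scan for a Shine-Dalgarno element upstream of an ORF start
#'
#' Slides the anti-SD probe ungapped across the window
#' `[max(0, start - sd_window), start)` immediately upstream of the ORF's
#' start codon and computes [duplex_energy()] at every offset. An annotation
#' is returned iff the minimum free energy is at or below
#' `params$sd_threshold`; ties in energy resolve toward the offset closest to
#' the start codon. The window is truncated at the sequence start without
#' error. In eukaryote mode no annotation is ever produced.
#'
#' @param x the [upstream_set()] the ORF belongs to, or a bare nucleotide
#'   sequence string.
#' @param orf a `uorf` from [find_orfs()].
#' @param params an [orf_params()] (supplies `sd_window`, `sd_threshold`,
#'   `asd_probe`).
#' @param model an [energy_model()].
#' @param mode overrides the mode when `x` is a bare string.
#' @return A list of class `sd_annotation` with `delta_g`, `window_start`,
#'   `match_offset`, `asd_used`, or `NULL` when no SD element is called.
#' @export
scan_sd <- function(x, orf, params = orf_params(), model = energy_model(),
                    mode = "prokaryote") {
  if (inherits(x, "upstream_set")) {
    mode <- x$mode
    i <- match(orf$record_id, x$id)
    if (is.na(i)) stop("ORF record_id '", orf$record_id, "' not in set")
    seq <- x$sequence[i]
  } else {
    seq <- toupper(chartr("U", "T", x))
  }
  if (identical(mode, "eukaryote")) return(NULL)
  win_start <- max(0L, orf$start - params$sd_window)
  if (orf$start - win_start < 1L) return(NULL)
  window <- substr(seq, win_start + 1L, orf$start)   # 0-based [win_start, start)
  probe <- params$asd_probe
  plen <- nchar(probe)
  wlen <- nchar(window)
  if (wlen < plen) return(NULL)
  offsets <- 0:(wlen - plen)
  e <- vapply(offsets, function(o) {
    duplex_energy(probe, substr(window, o + 1L, o + plen), model)
  }, numeric(1))
  best <- min(e)
  if (best > params$sd_threshold) return(NULL)
  off <- max(offsets[e == best])   # closest to the start codon on ties
  structure(list(delta_g = best, window_start = win_start,
                 match_offset = as.integer(off), asd_used = probe),
            class = "sd_annotation")
}

#' Annotate Shine-Dalgarno elements on all candidate ORFs of a set
#'
#' @param x an [upstream_set()] in prokaryote mode (eukaryote sets are
#'   returned unchanged).
#' @param candidates named list of ORF lists, as returned by [find_orfs()].
#' @param params an [orf_params()].
#' @param model an [energy_model()].
#' @return `candidates` with the `sd` field filled where an SD element is
#'   called.
#' @export
annotate_sd <- function(x, candidates, params = orf_params(),
                        model = energy_model()) {
  stopifnot(inherits(x, "upstream_set"))
  if (identical(x$mode, "eukaryote")) return(candidates)
  for (rid in names(candidates)) {
    candidates[[rid]] <- lapply(candidates[[rid]], function(o) {
      if (identical(o$strand, "+")) o$sd <- scan_sd(x, o, params, model)
      o
    })
  }
  candidates
}
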