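# Network acquisition of upstream sequences, kept behind a pluggable
# transport so the rest of the pipeline never touches the network. A
# transport is a function(url) returning the response as a character vector
# of lines; tests substitute a mock. Deleting this file leaves the
# FASTA-input pipeline fully functional.

EUTILS_BASE <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"

#' Default NCBI transport (live network)
#'
#' @return A function of one argument (a URL) returning the response lines.
#' @export
ncbi_transport <- function() {
  function(url) {
    con <- base::url(url)
    on.exit(close(con))
    readLines(con, warn = FALSE)
  }
}

# first mapping row of an NCBI Identical Protein Groups table:
# nucleotide accession, CDS start, CDS stop, strand
parse_ipg <- function(lines, accession) {
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Nucleotide Accession", "Start", "Stop", "Strand")
  if (!all(need %in% names(tab)) || nrow(tab) == 0L) {
    stop("no genomic mapping for ", accession)
  }
  tab <- tab[!is.na(tab$Start) & nzchar(tab[["Nucleotide Accession"]]), ,
             drop = FALSE]
  if (nrow(tab) == 0L) stop("no genomic mapping for ", accession)
  if (nrow(tab) > 1L) {
    # WP_ non-redundant proteins map to many genomes; the adapter takes the
    # first mapping row and flags the ambiguity
    warning(accession, ": ", nrow(tab),
            " genomic placements; using the first", call. = FALSE)
  }
  list(nuc = tab[["Nucleotide Accession"]][1L], start = as.integer(tab$Start[1L]),
       stop = as.integer(tab$Stop[1L]), strand = tab$Strand[1L])
}

# FASTA text -> single sequence string
fasta_lines_seq <- function(lines) {
  body <- lines[!startsWith(lines, ">")]
  s <- paste(body, collapse = "")
  if (!nzchar(s)) stop("empty FASTA response")
  s
}

fetch_one_upstream <- function(accession, mode, upstream_length, transport) {
  if (identical(mode, "prokaryote")) {
    ipg <- parse_ipg(transport(sprintf(
      "%s/efetch.fcgi?db=protein&id=%s&rettype=ipg&retmode=text",
      EUTILS_BASE, accession)), accession)
    if (identical(ipg$strand, "+")) {
      to <- ipg$start - 1L            # region ends at the mORF start codon
      from <- max(1L, to - upstream_length + 1L)
      strand_arg <- 1L
    } else {
      from <- ipg$stop + 1L
      to <- from + upstream_length - 1L
      strand_arg <- 2L
    }
    if (to < from) stop(accession, ": no upstream region at contig edge")
    lines <- transport(sprintf(
      "%s/efetch.fcgi?db=nuccore&id=%s&seq_start=%d&seq_stop=%d&strand=%d&rettype=fasta&retmode=text",
      EUTILS_BASE, ipg$nuc, from, to, strand_arg))
    fasta_lines_seq(lines)
  } else {
    # eukaryote: linked mRNA record; 5' UTR = transcript up to the CDS start
    gb <- transport(sprintf(
      "%s/efetch.fcgi?db=nuccore&id=%s&rettype=gb_linked_mrna&retmode=text",
      EUTILS_BASE, accession))
    cds <- grep("^\\s*CDS\\s", gb, value = TRUE)
    if (!length(cds)) stop(accession, ": no linked mRNA CDS found")
    cds_start <- suppressWarnings(
      as.integer(sub("^\\s*CDS\\s+<?(\\d+).*$", "\\1", cds[1L])))
    if (is.na(cds_start) || cds_start < 2L) {
      stop(accession, ": cannot determine 5' UTR")
    }
    fa <- transport(sprintf(
      "%s/efetch.fcgi?db=nuccore&id=%s&rettype=fasta_linked_mrna&retmode=text",
      EUTILS_BASE, accession))
    substr(fasta_lines_seq(fa), 1L, cds_start - 1L)
  }
}

#' Fetch upstream regions for a list of protein accessions
#'
#' Network-dependent acquisition behind the transport interface. In
#' prokaryote mode the region is `upstream_length` nt ending at the
#' annotated mORF start codon, on the mORF strand (truncated regions near a
#' contig edge are accepted); in eukaryote mode the transcript's complete
#' 5' UTR. Results are cached as per-accession FASTA files keyed by
#' accession, mode, and length, so reruns are fully offline. An unknown
#' accession produces a per-accession warning; the run continues if at
#' least two accessions succeed.
#'
#' @param accessions character vector of protein accessions (e.g. RefSeq
#'   WP_/NP_/XP_).
#' @param mode `"prokaryote"` or `"eukaryote"`.
#' @param upstream_length upstream window in nt (prokaryote mode; default
#'   500).
#' @param cache_dir directory of cached FASTA files; created if missing.
#' @param transport a `function(url) -> character` used for every network
#'   access; defaults to [ncbi_transport()].
#' @return An [upstream_set()] carrying `source_accession`.
#' @export
fetch_upstream <- function(accessions, mode = c("prokaryote", "eukaryote"),
                           upstream_length = 500L,
                           cache_dir = file.path(tempdir(), "uorfscout_cache"),
                           transport = ncbi_transport()) {
  mode <- match.arg(mode)
  stopifnot(length(accessions) >= 1L)
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- character(0); seqs <- character(0); src <- character(0)
  for (acc in accessions) {
    cache <- file.path(cache_dir,
                       sprintf("%s_%s_%d.fa", acc, mode, upstream_length))
    seq <- tryCatch({
      if (file.exists(cache)) {
        fasta_lines_seq(readLines(cache, warn = FALSE))
      } else {
        s <- fetch_one_upstream(acc, mode, as.integer(upstream_length),
                                transport)
        writeLines(c(paste0(">", acc, " upstream"), s), cache)
        s
      }
    }, error = function(e) {
      warning("accession ", acc, " skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(seq)) {
      ids <- c(ids, paste0(acc, "_upstream"))
      seqs <- c(seqs, seq)
      src <- c(src, acc)
    }
  }
  if (length(ids) < 2L) {
    stop("fewer than 2 upstream regions retrieved; cannot continue")
  }
  upstream_set(ids, seqs, source_accession = src, mode = mode,
               label = "fetched upstream regions")
}

#' Remote homolog search (adapter)
#'
#' Thin adapter around the NCBI BLAST URL API: submits a BlastP query
#' against RefSeq proteins, polls for the request id, and returns the hit
#' accessions. Entirely network-dependent; offline tests exercise it only
#' through a mock transport. On remote failure the error instructs use of a
#' precomputed, user-curated homolog list instead.
#'
#' @param query_accession protein accession used as the query.
#' @param max_hits maximum number of hit accessions (must be positive).
#' @param transport a `function(url) -> character`; defaults to
#'   [ncbi_transport()].
#' @return Character vector of hit accessions.
#' @export
search_homologs <- function(query_accession, max_hits = 100L,
                            transport = ncbi_transport()) {
  if (max_hits <= 0L) stop("max_hits must be positive")
  tryCatch({
    put <- transport(sprintf(
      "https://blast.ncbi.nlm.nih.gov/Blast.cgi?CMD=Put&PROGRAM=blastp&DATABASE=refseq_protein&QUERY=%s&HITLIST_SIZE=%d",
      query_accession, as.integer(max_hits)))
    rid <- sub(".*RID = (\\S+).*", "\\1",
               grep("RID =", put, value = TRUE)[1L])
    if (is.na(rid) || !nzchar(rid)) stop("no request id in BLAST response")
    res <- transport(sprintf(
      "https://blast.ncbi.nlm.nih.gov/Blast.cgi?CMD=Get&RID=%s&FORMAT_TYPE=Tabular&ALIGNMENTS=%d",
      rid, as.integer(max_hits)))
    hits <- res[grepl("^\\S+\\t", res)]
    acc <- unique(vapply(strsplit(hits, "\t", fixed = TRUE), `[[`,
                         character(1), 2L))
    utils::head(acc, max_hits)
  }, error = function(e) {
    stop("remote homolog search failed (", conditionMessage(e),
         "); supply a precomputed list of homolog accessions instead",
         call. = FALSE)
  })
}
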