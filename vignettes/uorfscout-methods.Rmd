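---
title: "Methods: conserved upstream-ORF detection in uorfscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conserved upstream-ORF detection in uorfscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uorfscout)
```

## The problem

Short upstream open reading frames (uORFs) in the 5′ region of a gene often
encode regulatory leader peptides: ribosome behavior on the uORF controls
expression of the downstream main ORF (mORF), as in translational attenuation
of bacterial antibiotic-resistance genes or stress-dependent reinitiation in
eukaryotic 5′ UTRs. Individual uORFs are hard to call from one sequence
alone — they are short (usually well under 100 codons) and compositionally
unremarkable. What distinguishes a functional uORF is its *conservation*
across homologous upstream regions. `uorfscout` operationalizes that signal:
given a set of homologous 5′ upstream nucleotide sequences, it enumerates all
candidate ORFs in each, then searches for a set of mutually similar ORFs —
at most one per sequence — that maximizes the sum of pairwise alignment
scores.

## ORF annotation

An ORF is a region from a start codon to the nearest downstream in-frame
stop codon, stop included. Defaults: start codon ATG (GTG/TTG can be added;
alternative initiators translate as M in the initiator position), stops
TAA/TAG/TGA, and a minimum length of 9 nt — three codons: start, one
internal codon, stop. ORFs whose start has no in-frame stop before the
sequence end are discarded rather than reported open-ended. All nested
starts sharing a stop are kept as separate candidates; the conservation
stage, not the caller, decides which start is supported across sequences.
Coordinates are 0-based half-open on the given strand; the input is assumed
to be the mORF-coding strand read 5′→3′, with reverse-strand scanning an
opt-in flag (`scan_reverse`) for the general conserved-ORF use case. Codons
containing N are never starts or stops and translate as X.

## Shine-Dalgarno scoring

In prokaryote mode each candidate's start codon is preceded by a 20-nt
window scanned for a Shine-Dalgarno (SD) element. The anti-SD probe
(default `CCUCCU`, the reverse complement of the AGGAGG core bound by the
16S rRNA 3′ tail) slides ungapped across the window, and at each offset an
RNA:RNA hybridization free energy is computed from an additive
nearest-neighbor model: the sum of stack terms over the longest contiguous
run of allowed pairs (Watson-Crick plus G:U wobble) plus a duplex initiation
penalty of +3.4 kcal/mol. Fewer than two contiguous pairs means no stable
duplex (energy 0). Watson-Crick stack values are Freier-style RNA duplex
parameters shipped as `inst/extdata/rna_stack_energies.tsv`;
wobble-containing stacks carry coarse uniform values (−0.5 with one wobble
pair, −0.3 with two) because a full parameterization is not needed at the
precision this annotation requires. This contiguous-run model deliberately
simplifies full hybridization thermodynamics: no bulges or internal loops
are considered. An SD annotation is emitted when the minimum energy over
offsets is at or below `sd_threshold` (default −3.0 kcal/mol — permissive,
because leader-peptide SDs are often weak); ties between offsets resolve
toward the start codon. The probe, the parameter values, and the threshold
are all configurable, since different 16S tails and stringencies are
legitimate choices. Eukaryote mode never produces SD annotations.

## The conservation search

Candidates are compared by global (end-to-end) affine-gap alignment, by
default at the peptide level with BLOSUM62, gap open 10, gap extend 1
(leader peptides are conserved as amino-acid sequences; a nucleotide mode
with match +2/mismatch −3 exists for very short ORFs). The search is
greedy: every candidate of every record seeds a path; the remaining records
are visited in input order, and from each record the candidate maximizing
the summed pairwise score to the current members joins — if its mean score
against members is at least `accept_ratio` (default 0.5) times the members'
mean self-score. Normalizing the gate by self-score lets one threshold
serve 3-codon and 60-codon uORFs alike; records with no acceptable
candidate are skipped. Ties break toward higher score, then smaller start
coordinate, then longer ORF, making the search fully deterministic. Paths
are filtered to cover at least `min_coverage` of the records (default 0.67,
leaving room for genuinely patchy conservation), deduplicated — two paths
sharing more than half their members, as nested same-stop start variants
routinely do, collapse to the higher-scoring one — ranked by total score,
and truncated to `max_paths` (default 10). Seeding from *all* records
(rather than only the first) removes any dependence on which homolog the
user happens to list first; relabeling records leaves results unchanged,
only record order matters. On small instances where one candidate per
record dominates its decoys, the greedy top path provably coincides with
the exhaustive one-per-record optimum, and the test suite verifies this by
enumeration.

## MSA and sequence logos

Members of each path are aligned with a center-star progressive MSA: the
center is the sequence maximizing its summed pairwise score to the others;
every other sequence is pairwise-aligned to it and merged under "once a
gap, always a gap". Center-star is implemented internally rather than
shelling out to an external aligner: the sequences are short, the quality
loss relative to iterative methods is negligible there, and the pipeline
stays self-contained and byte-deterministic. Logo statistics per column:
relative frequencies over non-gap alphabet symbols (X/N excluded like
gaps), information content `log2(|alphabet|) − H` in bits, consensus by
argmax with alphabetical tie-break. No small-sample correction is applied —
these alignments typically have far fewer than 50 rows, and the uncorrected
values are the familiar logo heights; columns with more than half gaps are
flagged but rendered.

## Figures

Three deterministic SVG 1.1 outputs mirror the standard presentation of a
uORF locus: an annotation plot (one track per record; conserved members
filled per-path, other candidates grey outlines, SD positions ticked, the
mORF 5′ end marked at the right edge of the upstream window), a sequence
logo (letter heights proportional to `freq × info`), and an MSA panel.
Numbers in the SVG are printed with fixed formatting and fonts are
referenced by name, so identical inputs give byte-identical files — a
property the tests assert rather than assume.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` builds the study conditions used throughout testing:
by default 8 records of 500 nt (the default prokaryotic upstream window),
uniform-composition background with a GC knob, one planted 45-nt uORF per
record at a random position, per-site substitution divergence at rate 0.05,
and 3 random decoy ORFs per record placed without overlap. Start and stop
codons are never mutated and substitutions that would create an internal
in-frame stop are resampled, so the planted ORF is always a valid candidate
— divergence stresses the conservation search, not the ORF caller. The
generator does *not* emulate phylogenetic (tree-structured) divergence,
indels, codon bias, or real intergenic composition; recovery rates on it
therefore measure the search machinery under controlled noise, not expected
sensitivity on real homolog sets, where divergence is correlated and
conservation patchy. Problem sizes in the tests (8 × 500 nt, 100
replicates; 200 random sequences up to 2 kb for the caller oracle) were
chosen as the smallest sets that exercise every code path with stable
statistics.

## Numerical and design choices

* Tie-breaks are specified everywhere (alignment-score ties by position and
  length; SD-offset ties toward the start codon; consensus ties
  alphabetical; center ties by input order), which is what makes
  end-to-end byte determinism possible.
* `total_score` stored on a path is recomputable from members
  (`recompute_score()`, equal within 1e-9); tests treat this as an
  integrity invariant.
* Degenerate inputs: a single record errors with "nothing to compare"; a
  run finding no conserved path warns and writes an empty summary — absence
  of conservation is a scientific result, not a failure.
* The network layer (`fetch_upstream()`, `search_homologs()`) sits behind a
  transport function so the offline pipeline never references it; cached
  FASTA responses make reruns network-free. WP_ accessions can map to many
  genomes; the adapter takes the first placement and warns about the
  ambiguity.

## A worked example

```{r example}
d <- generate_dataset(n_records = 5, record_length = 400,
                      mutation_rate = 0.05, seed = 42)
fit <- uorf_scan(d$records)
fit
score_recovery(fit$paths, d$truth)
```

## Known limitations

Substitution-only synthetic divergence; ungapped SD duplex model; no
statistical significance (E-values) attached to conservation scores; no
exhaustive optimal selection for large record sets (the greedy search is a
heuristic, matched against the optimum only at small scale); the eukaryote
retrieval path depends on how transcript records annotate their CDS and is
exercised only through mocks offline.
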