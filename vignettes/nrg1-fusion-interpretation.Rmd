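---
title: "Targeted detection and interpretation of NRG1 fusions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted detection and interpretation of NRG1 fusions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrgfusion)
```

## The problem

NRG1 encodes ligands of the ERBB2–ERBB3 receptor heterodimer. Gene fusions
that place another gene's promoter and 5' exons upstream of NRG1's
EGF-like, receptor-binding exon can create an autocrine loop and are
candidate drug targets; but NRG1 is also recurrently *inactivated* in breast
cancer, and many genomic rearrangements of the locus are out of frame, lose
the receptor-binding exon, retain only the gene's 5' end, or are too complex
to interpret from DNA alone. Distinguishing activating fusions from
inactivating or indeterminate rearrangements therefore needs integrated
DNA + RNA evidence and explicit interpretation rules, which is what this
package implements:

1. a targeted split-read search of raw RNA reads for splice-boundary
   anchors of the genes of interest (`junction_scan` functions);
2. breakend (BND) structural-variant parsing and somatic filtering
   (`sv_integration` functions);
3. DNA + RNA integration, reading-frame and domain-retention annotation,
   and activation classification (`fusion_annotation` functions);
4. windowed read-count copy number with junction concordance
   (`copy_number` functions);
5. derivative-chromosome reconstruction from junction segment graphs
   (`reconstruction` functions);
6. a seeded synthetic-data generator supplying every input the pipeline
   needs (`synthetic_*` functions), so the whole analysis runs and is tested
   without access to patient data, which for the motivating study is not
   public.

The `analysis/` directory of the source repository runs these stages as
numbered scripts over the synthetic data and writes the result tables under
`results/`.

## Gene models and exon numbering

Exons are numbered 1..n by ascending genomic start coordinate, regardless of
transcript usage or strand (`number_exons_by_genome_order()`). Under this
convention the first exon of many normal NRG1 transcripts is exon 3, the
Ig-like domain is encoded by exons 3–4, the EGF-like receptor-binding domain
by exon 9, the alpha/beta alternative exons are {10|11}, the transmembrane
exon is 12 and the cytoplasmic tail is 13–18. Transcripts terminating in
exon 11 use a genomic extension of that exon (the "β3" terminus); we model
it as an extension block of exon 11 (`beta3_extension`), not as a separate
numbered exon. Cryptic exons — unannotated, possibly antisense within
another gene's intron, like the 78-nt "int15" exon inside the partner
gene's intron 15 — are stored with their genomic coordinates and *expressed*
strand, and their splice anchors are computed on the expressed strand.

Coding phase is defined per exon as (cumulative upstream CDS length) mod 3,
computed in transcript row order. Where a gene carries mutually exclusive
exons, the stored phases are those of the annotation table including both
members; this is immaterial here because frame calls are made at the fusion
acceptor exon (exon 3, phase 0), upstream of the alternative group.

All coordinates are 1-based inclusive in every interface and report
(GTF/VCF convention, interval length = end − start + 1). Internal interval
arithmetic converts at the boundaries where needed (e.g. breakend "cut"
positions in the segment graph).

## Splice-anchor read scan

The fusion detector is a text search, not an alignment. For every exon of
the configured genes, two anchors of length `k` are extracted: the acceptor
anchor (first `k` transcribed bases) and the donor anchor (last `k`), both
read 5'→3' on the mRNA. Parameters:

* `k = 20` bases (default). The anchor must be unique across the genome
  region of interest; `build_anchor_index()` fails loudly on collisions and
  the toy-genome generator verifies uniqueness of all 86 anchors at k = 20.
  The value is a design choice — at desk scale 20-mers are unique with very
  high probability while leaving 55 bp of partner flank on a 75-bp read.
* `max_mismatches = 0` (default): a pure text search. An optional
  1-mismatch mode (per-position Hamming scan) exists for error-tolerant
  scanning; the deterministic simulations use error-free reads.
* `min_flank = 12` bases: an anchor hit whose partner-side flank is shorter
  is reported as `too_short` and excluded from fraction denominators, so
  percentages are computed over classifiable split reads only.
* `dedup`: identical (orientation-normalised) read sequences can be
  collapsed before counting — the duplicate-removed cell-line mode — or kept,
  the cohort mode. The worked compositions below use `dedup = FALSE`.

Anchors are matched anywhere within the read and on both orientations; hits
found on the reverse complement are re-oriented before classification, so
junction summaries are invariant to reverse-complementing the input reads
(a tested property). Flank classification is exact suffix/prefix matching
against the complementary-side anchors of all modelled exons, including
cryptic ones; unmatched flanks are reported verbatim as `novel(...)`, which
is how a fusion spliced from an undocumented partner exon remains visible.

Counting is acceptor-anchored: a junction-spanning read containing both the
donor and the acceptor anchor is counted once, at its acceptor.

## Breakend parsing and somatic filters

`parse_breakend_vcf()` decodes the four VCF 4.2 bracket cases and collapses
MATEID pairs into junctions of two breakends with *retained sides*: "left"
means reference sequence left of the breakend position is retained in the
derivative. `filter_somatic()` applies three filters, in order: any
supporting read in the matched normal; membership in a panel of normals
(same retained-side orientation, both breakends within ±10 bp — the
tolerance is a design choice, the filter itself is standard); and any
breakend on a contig outside the allowed set (mitochondrial/unassembled
contigs are excluded by default). Filtering is order-preserving and
idempotent.

`predict_fusion_from_junction()` emits a candidate only for
orientation-consistent sense–sense geometry: one breakend inside a 5'
candidate gene retaining its promoter-proximal exons on its coding strand,
the other upstream of the 3' gene's first retained exon reading into it.
The predicted spliced-in exon is the first (lowest-numbered) acceptor exon
downstream of the breakend, skipping transcription-start exons. Two special
geometries are preserved rather than discarded: a breakend retaining only
the 3' gene's 5' portion (`five_prime_end_only`, an inactivating pattern)
and a partner breakend in no modelled gene (`novel_partner`, frame unknown).
The window for "breakpoints within the gene" is the annotated gene span with
a configurable flank, default 0 bp.

## DNA + RNA integration and classification

DNA candidates alone are provisional. `integrate_fusion_evidence()` attaches
RNA split-read support to each candidate (reads at the predicted acceptor
whose donor is the partner's donor exon; any novel donor for novel-partner
candidates) and, for cases that do carry DNA breakpoints in the gene,
creates calls from RNA junction rows that no single junction's geometry
predicted — this is how the double-fusion cell line is called: its
partner-side breakend lies in the (minus-strand) middle gene, so no single
junction reads as a sense–sense fusion, but the RNA shows the partner's
exon 12 splicing into NRG exon 3 in frame.

Frame rules (`frame_status()`): a partner contributing L coding bases is in
frame at an acceptor of phase p iff L mod 3 = p; a UTR-only partner is in
frame by construction (translation initiates at the 3' unit's own start
codon); an undocumented partner exon gives `unknown_partner_exon`. A cryptic
cassette exon of length l preserves the frame established by the junction it
interrupts iff l mod 3 = 0, adding l/3 residues (`cassette_insertion_frame()`;
the 78-nt exon adds 26 residues in frame).

Classification (`classify_rearrangement()`):

* **activating** — some call is in frame (or UTR-only partner), retains the
  EGF-like exon, and has ≥ `min_rna_support` split reads (default 1, because
  real fusions have been confirmed with only one or two split reads);
* **likely_inactivating** — every call is out of frame, retains only the
  gene's 5' end, loses the EGF-like exon, or splices in at/after the
  transmembrane exon; or a single-breakpoint case yields no candidate;
* **indeterminate** — unknown partner exon with the 3' side in frame
  (subclass `possible_activating_partner_frame_unknown`; a flag can promote
  these), multi-breakpoint cases without RNA support, and DNA candidates
  without RNA confirmation.

The cytoplasmic tail is reported per isoform but never used in
classification: tail-containing fusion isoforms exist, so tail loss cannot
be the oncogenic mechanism and must not drive the call.

Cohort percentages use round-half-away-from-zero: fusion frequency to one
decimal (4/571 → 0.7), breakpoint-case frequency to the nearest integer
(20/250 → 8).

## Copy number

`window_read_counts()` counts read starts per fixed-width window (default
1 kb; at least 100 bp) for tumour and reference and forms library-size
normalised ratios; windows with zero reference count are masked. Note that
library-size normalisation divides all ratios by the mean tumour copy
number over the profiled region, so *levels* are relative; *steps* are what
the analysis uses. Change points come from recursive binary segmentation on
the mean ratio with threshold `min_step = 0.3` and a minimum segment width
of 2 windows (single noisy windows cannot become segments); a final merge
pass guarantees every reported step's magnitude is ≥ `min_step`. This simple
segmentation is this package's own stand-in for the targeted
read-count copy-number tooling used in capture experiments; it is exhaustive
enough at desk scale and is cross-checked in the tests against an exhaustive
minimum-SSE segmentation oracle. A junction breakend within ±1 window of a
step is labelled unbalanced (with the step's direction); reciprocal
junction pairs with no dosage change stay balanced.

## Reconstruction

`build_segment_graph()` cuts each chromosome at every breakend (left-retained
breakends cut after their position, right-retained before), giving, per
chromosome, segments = breakpoints + 1, plus variant adjacencies (one per
junction) and reference adjacencies. `enumerate_walks()` does a bounded
depth-first enumeration of oriented segment walks (default cap 12 segment
traversals, deduplicated up to reverse complement, flagged if truncated);
all consistent walks are reported rather than asserting one, because such
reconstructions are inherently under-determined. `explain_transcript()`
checks that a walk presents the two exons of an observed splice junction in
transcription order, both in sense orientation. Walk segment multiplicities
can be scored softly against copy-number segments
(`walk_cn_consistency()`), not enforced. The
tandem-duplication-with-inverted-insertion motif is recognised from its
two-junction signature (a left/left join from duplication end to insert end
and a right/right join from insert start to duplication start); the
signature is symmetric in which fragment is "the duplication", so the span
overlapping the gene of interest is preferred when a gene is supplied.

## The synthetic data: what it does and does not emulate

The generator (`make_toy_genome()`, `rearrangement_preset()`,
`simulate_rna_reads()`, `simulate_sv_vcf()`, `simulate_cn_reads()`,
`build_cohort_fixture()`) reproduces the *structure* of the study inputs at
desk scale:

* two ~200-kb chromosomes; a plus-strand 5' gene with a non-coding first
  exon; a 16-exon minus-strand middle gene whose coding length through
  exon 12 is a multiple of three; a 78-nt antisense cryptic exon in its
  intron 15; an 18-exon NRG1-like gene with the domain-tagged exons above;
  and a WRN-like gene immediately 5' of it;
* five rearrangement presets: the double fusion with inverted cryptic-exon
  insertion (`mda175`), a deletion fusion (`simple_del`), a novel-partner
  fusion with a 57-kb tandem duplication carrying a 24-kb inverted insert
  (`dup_inv_insert`), a transmembrane-exon splice-in (`inactivating`), and
  an incoherent multi-breakpoint case (`complex_multi`);
* RNA reads of 75 bp planted across junctions at exact counts (the
  fixed cell-line composition: 38 cryptic-exon + 122 exon-12 reads at the
  NRG exon-3 acceptor; 144 + 1 reads at the middle gene's exon-3 acceptor),
  with every other read reverse-complemented and at least 20 bases on each
  side of the junction so every planted read is recoverable;
* breakend VCFs with paired tumour/normal support columns, plantable
  germline junctions and excluded-contig decoys, and a BEDPE panel of
  normals;
* a 571-case cohort fixture with 4 RNA-supported fusions and, among the
  first 250 DNA-sequenced cases, 20 further breakpoint-only cases (13
  multi-breakpoint).

It deliberately does **not** emulate: sequencing error and base-quality
structure (reads are error-free unless a uniform substitution rate is
requested), expression-level realism (junction counts are specified, not
drawn from an expression model), paired-end structure, GC or mappability
bias in coverage, or genome-scale repeat content (anchor uniqueness is
verified, not earned). Passing tests therefore demonstrate correctness of
the computations and interpretation rules under clean inputs — recovery of
planted truth — not detection power on real libraries.

All simulation is seeded; identical configurations give byte-identical
FASTQ/VCF outputs, and problem sizes (200-kb chromosomes, ~300 planted
reads, 100-window copy-number profiles, 20-seed repetition for the
step-recovery property) were chosen so the entire test suite and the
acceptance script run in about a minute on a single CPU.

## Numerical and degenerate-input choices

* Percentages round half away from zero (`round_half_up()`), fixing
  23.75% → 24% and 100·4/571 → 0.7.
* Empty inputs return empty, typed tables (empty FASTQ → empty summary;
  zero-junction graph → one segment per chromosome and only reference
  walks); empty cohorts summarise to zeros without division errors.
* Malformed FASTQ records, unpaired breakend mates, junction positions
  outside chromosome extents, k longer than an exon, and negative partner
  CDS lengths are errors; anchors containing N are flagged ambiguous with a
  warning.
* Ties in walk deduplication are resolved by canonical (lexicographically
  smaller of a walk and its reverse complement) keys; junction tables are
  compared via `canonical_junctions()`.

## Known limitations

* Frame calls on alternative isoforms downstream of the acceptor exon reuse
  the annotation-table phases (see above); a per-isoform phase recomputation
  would be needed if frame at downstream junctions ever mattered.
* The scan is exact by default; true positives carrying sequencing errors
  inside the anchor are missed unless the 1-mismatch mode is enabled.
* `detect_steps()` is a stand-in segmentation: adequate for targeted
  regions with tens-to-hundreds of windows, not a genome-scale CNV caller.
* Walk enumeration is exponential in junction count and relies on the
  `max_length` cap; complex karyotypes should be inspected via the exported
  DOT graph rather than exhaustive walks.
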