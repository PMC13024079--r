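---
title: "From structural-variant breakpoints to prioritized neoantigen candidates"
author: "svpepgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From structural-variant breakpoints to prioritized neoantigen candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svpepgen)
```

## The problem

Somatic structural variants (SVs) — deletions, duplications, insertions,
inversions and inter-chromosomal breakends — can rearrange coding sequence
and create tumor-specific peptides that the wild-type proteome never
contains. Such SV-derived neoantigens are attractive immunotherapy targets,
particularly in tumors with low point-mutation burden, but converting a VCF
of breakpoints into a credible, prioritized peptide list requires a long
chain of bookkeeping: breakpoints must be mapped into spliced transcript
coordinates, a mutant coding sequence reconstructed per isoform, the
reading frame classified, junction-restricted peptide windows enumerated,
wild-type-identical windows removed, and the surviving candidates pushed
through a cascade of predictor-based and multi-omics evidence filters.

`svpepgen` implements that computational core. It deliberately does *not*
run the upstream callers and predictors (SV calling, HLA typing, cleavage /
binding / immunogenicity prediction, MS database search, BLAST): it
consumes their standard output shapes and owns everything between.

## Coordinate conventions

GTF and VCF coordinates are 1-based inclusive on input; all internal
arithmetic is 0-based half-open, and conversions happen only at parse and
write boundaries. For symbolic VCF ALTs the POS base is the last retained
base, so a `<DEL>` with `POS=1030, END=1033` deletes bases 1031–1033; the
same padding-base convention is applied to `<DUP>` and `<INV>`. Breakend
(BND) records are decoded from the four bracket forms of VCF notation into
"which side of the breakpoint is retained", and reciprocal `MATEID` pairs
are merged into one event.

## Mutant CDS reconstruction

Events are retained per (event, transcript) pair when both breakpoints fall
in the spliced CDS, when exactly one does, or when neither does but the
event interval spans at least one whole CDS segment (interval-based SVs;
the rule is applied to DEL, DUP and INV alike and is configurable via
`spanning_types`). Reconstruction happens in transcript space:

* **DEL** — CDS bases inside the deleted span are excised; a spanning
  deletion thereby removes whole exon bases. Deletions that remove the
  start codon are flagged `no_start` and excluded from translation.
* **DUP** — assumed tandem and direct-orientation; the covered CDS bases
  are repeated in place.
* **INS** — the inserted sequence is spliced at the anchor offset
  (reverse-complemented for minus-strand transcripts).
* **INV** — the covered CDS bases are replaced by their reverse complement
  in transcript space. Inversions that also cover intronic sequence reuse
  the wild-type splice structure — true post-inversion splicing is
  unknowable without RNA evidence — and carry a `simplified_splice` flag.
* **BND** — the 5' head segment runs from the start codon to the head
  breakend; the tail is read *in the frame implied by the head* when the
  partner breakend lies in a coding transcript, which is what makes the
  head-length divisibility rule meaningful. When the join runs into
  non-coding territory, up to `fusion_horizon` (default 600 nt = 200
  codons) of genomic sequence is appended; the bound prevents unbounded
  frameshift tails.

Frame classification prioritizes a gene-level frameshift annotation
(AnnotSV-style split-mode table) when one is attached; otherwise
single-event SVs are frameshift iff the net coding-length change is not a
multiple of three, and fusions iff the head-segment length is not divisible
by three. "Net change mod 3" was chosen over "absolute mutant length mod 3";
the two agree whenever the wild-type annotation is codon-complete, and
transcripts with incomplete CDS annotations are flagged rather than
dropped (`cds_mod3_ok = FALSE`, trailing partial codon trimmed at
translation).

Translation uses the standard genetic code from the annotated start, halts
at the first stop codon, and records junction residues as `floor(offset/3)`.
A frameshift with no stop before the sequence end is translated to the last
full codon and flagged unterminated; an internal stop upstream of the first
junction yields a `junction_lost` protein whose windows are empty.

## Peptide windows and self-filtering

All windows of 8–11 residues are enumerated (the pre-filter count is
$\sum_{k=8}^{11}\max(0, L-k+1)$) and a window is retained iff it spans a
junction residue or overlaps the novel residue span (the frameshift tail,
or the inserted/duplicated/inverted span of in-frame events). Windows
identical to a wild-type k-mer are then removed. The default wild-type
scope is transcript-local (the source transcript's wild-type protein plus
the fusion partner's) — the minimal faithful reading of "identical to the
wild-type sequence" — with an optional proteome-wide mode
(`self_filter = "proteome"`) that additionally screens against a reference
proteome FASTA, anticipating the later normal-proteome removal at the MS
stage. Candidates are peptide-centric: the final table is deduplicated on
sequence with all (event, transcript, offset) lineages preserved, and the
FASTA headers carry the `neo_` prefix that the MS evidence step keys on.

Peptides are generated for every overlapping coding isoform rather than a
longest-CDS representative; whether a per-gene canonical isoform should be
collapsed afterwards is left to the consumer, since the candidate table
keeps full lineage.

## Cleavage-risk model and filter cascade

Per-position proteasomal cleavage scores (NetChop-style) are summarized per
peptide. Internal positions (excluding both termini) with score
$\ge$ 0.5 are potential internal cleavage sites, and

$$\mathrm{Internal\_Risk} = \alpha\cdot \mathrm{max\_internal\_score}
  + \beta\cdot \ln(1 + \mathrm{internal\_cleavage\_count}),$$

with defaults $\alpha = 1.0$, $\beta = 0.3$: a single confident internal
cut is enough to destroy a short 8–11-mer, so the maximum dominates and the
count acts as a weaker auxiliary penalty. The logarithm is natural — the
base is not dictated by the formula's origin and only rescales $\beta$,
which is exposed in the configuration anyway; the choice is frozen here and
in the tests. `max_internal_score` is taken over qualifying sites only
(0 when none qualifies), with `max_over_all_internal = TRUE` available as a
sensitivity option. Risks are min–max normalized per invocation (the cohort
is whatever one call scores; a constant cohort maps to all zeros), and

$$\mathrm{NetChop\_Score} = \frac{N\_score + C\_score}{1 + \mathrm{Internal\_Risk}}$$

is prescreened at $\ge 0.5$ (inclusive). As risk $\to$ 0 the score
approaches $N\_score + C\_score$ exactly.

The downstream gates, in the default funnel order, are:

| gate | rule | boundary |
|---|---|---|
| binding | SB/WB bind level (`net_pass`) **or** affinity < 500 nM **and** rank < 2.0 (`flurry_pass`), for ≥ 1 sample allele | 500 and 2.0 fail (strict) |
| expression | gene-level TPM > 0 | 0 fails (strict) |
| MS evidence | `neo_`-prefixed Protein field, not mapping to the reference proteome, spectral count > 0; tumor-only (primary) or tumor-and-normal (secondary) retained, normal-only removed; multi-mapped `neo_` entries kept | — |
| immunogenicity | score > 0.7 is high; 8/11-mers bypass with NA and are strictly retained | 0.7 is low (strict) |
| similarity | best hit (bitscore, then E-value, then length) with identity ≥ 80 % and E-value ≤ 200 | both inclusive |

Missing predictor columns default a tool's pass flag to FALSE so partial
runs (e.g. one binding predictor only) remain usable; a gene absent from
the TPM table fails the expression gate with a warning; a 9–10-mer missing
an immunogenicity score is an error (the table is incomplete), whereas 8-
and 11-mers are outside the predictor's length support by design. The
permissive E-value bound reflects that random-match E-values for 8–11-mer
queries are intrinsically large, so identity does the real work; no
full-length coverage is required because validated-neoantigen databases
consist of short peptides. When the same peptide–HLA pair recurs, the
highest immunogenicity score is the representative. The relative order of
the expression and binding gates is not fully pinned by the source
material; the default order above is fixed, and the per-gate columns in the
output table let a consumer re-cut the funnel in any order. Funnel counts
are unique peptide sequences per tier and non-increasing by construction.

## Benchmarking statistics

Two candidate tables are compared under a shared "reference budget" (the
smaller table's size): each side contributes its best
$\lceil f \cdot \mathrm{budget}\rceil$ candidates at cutoffs
$f \in \{0.5, 0.75, 1.0\}$, sorted stably in the favorable direction, and
the score distributions are compared with a two-sided Mann–Whitney U test.
For pair-level metrics (EL rank, presentation score) the caller supplies
one optimal HLA record per peptide.

The U test is exact by full enumeration of rank assignments when the
combined sample size is ≤ 12 without ties — desk-scale exactness where
enumeration is cheap — and otherwise uses a normal approximation with
midrank tie correction and continuity correction. The plain
continuity-corrected approximation deviates from enumeration by up to
0.011 at $n = 8+8$, so the tail is refined with an Edgeworth kurtosis term
using the tie-free excess kurtosis of $U$,
$\gamma_2 = -\tfrac{6}{5}\,(n_x^2+n_y^2+n_xn_y+n_x+n_y)/(n_xn_y(n+1))$
(verified numerically against the exact distribution), bringing the
worst-case error at $8+8$ to $5.5\times 10^{-4}$. Deep in the tails, where
the kurtosis term can turn a tail non-positive, the plain normal tail is
used. All-identical data gives $p = 1$; p-values are reproducible
bit-for-bit across runs.

## The toy fixture: what it does and does not emulate

`make_fixture(seed, dir)` writes a fully self-contained bundle: two contigs
(10 kb and 8 kb), three coding genes on both strands with multi-exon CDS
(60–300 nt, small enough that every junction is hand-checkable), one SV of
each type — in-frame and frameshift deletions, a tandem duplication on the
minus-strand gene, an insertion, an inversion, a reciprocal breakend pair
forming an in-frame fusion — plus one non-PASS record, and predictor
tables that parse through every prioritization reader and contain exact
boundary rows for every cutoff. The truth manifest (expected mutant CDS,
frame class and peptide set per event) is derived by direct string surgery
on the designed coding sequences — an oracle independent of the genomic
reconstruction path — and is stored as TSV data so any implementation can
consume it.

The generator emulates coordinate bookkeeping, strand handling, frame
arithmetic and threshold semantics. It does **not** emulate realistic SV
size spectra, repeat-mediated breakpoints, sequencing error, isoform
complexity of real annotation, or the score distributions of the real
predictors (table values are scenario-driven, not model-driven). Passing
tests therefore demonstrate correctness of the computational core, not
recall on real tumors: cohort-scale results additionally depend on the
upstream callers and predictors this package intentionally treats as
inputs.

Test and acceptance runs use the bundle at its designed scale (a few
hundred candidate windows per run), 100 randomized events for the
frame-rule property, 1000 random vectors for normalization bounds, and all
two-sample splits of eight ranks plus random splits at the $n = 12$
switchover for the exact U test — sizes chosen so the whole suite runs in
about a minute on one core while still exercising every rule.

## Known limitations

* Post-rearrangement splicing is assumed to reuse the wild-type exon
  structure; intron-containing inversions and intronic breakends are
  flagged, not re-predicted.
* No NMD modeling: frameshift transcripts that would be degraded in vivo
  still yield candidate windows.
* HLA class II (longer windows) is out of scope, as are the upstream
  predictors themselves.
* The MS evidence gate consumes peptide-level search output at face value
  (1 % FDR assumed upstream); it does not re-score spectra.
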