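---
title: "Methods: desk-scale characterization of plant mitochondrial genomes"
author: "mitokit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale characterization of plant mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitokit)
```

# Scope and model system

`mitokit` re-implements, as a tested R package, the standard analysis
battery applied to a newly assembled plant mitochondrial genome:
recruitment of organelle long reads from a mixed read pool, C-to-U RNA
editing effect classification, relative synonymous codon usage (RSCU),
repeat mining in three classes, quantification of plastid-derived
sequence (MTPT), and pairwise Ka/Ks with nucleotide diversity. The
reference study system is the *Forsythia suspensa* mitochondrial genome
(GenBank OQ534870; 535,692 bp, circular, 44.90% GC, 60 genes), whose
published summary tables — the editing-type table, the gene table and
the chloroplast homologous-fragment table — are bundled as plain-text
fixtures under `inst/extdata/` and serve as exact arithmetic checks for
the summarizers.

Because the raw sequencing data are not part of the package, every
sequence-level stage is validated against a synthetic study system
(`syntheticConfig()` / `makeGenomes()` / `makeReads()`): a desk-scale
circular mitogenome in which genes, repeats, plastid insertions and
editing sites are planted at recorded coordinates with recorded
content. Detection is then judged against that ground truth.

# Coordinates and containers

All user-facing coordinates are 1-based inclusive, the GenBank and
IRanges convention; intervals are held as `IRanges` and sequences as
`Biostrings` objects inside the S4 classes `GenomeRecord` and
`GeneModel`. On a circular genome a feature may run past the sequence
end, in which case positions wrap modulo the length; `rotateGenome()`
exists so tests can assert that detection is invariant under the choice
of origin. A deliberate consequence of the published gene table's
arithmetic: its printed gene lengths exclude the stop codon, so
`proteinLength()` expects a CDS *with* its terminal stop and returns
`length/3 - 1` residues, which reproduces the printed amino-acid counts
when applied to a CDS of printed length plus one stop codon.

# Read recruitment

Recruitment follows the published two-stage "baiting" design with its
printed thresholds as defaults:

1. **Candidates and seeds.** Reads sharing a similar fragment longer
   than 50 bp with any conserved core gene are candidates; candidates
   are ranked by (number of distinct core genes hit, mean completeness
   of the hit genes, read length, id) and the top 10 become seeds. The
   seed count is configurable; the study this follows does not print
   one.
2. **Iteration.** Any unrecruited read overlapping a recruited read by
   at least 1 kb at 70% or better identity joins the set; iteration
   stops at the first empty round.

The aligner behind both stages is internal, so the stage is
self-contained: a minimizer sketch (k = 15, window w = 10) proposes
chains of colinear shared minimizers, and every candidate chain is
*verified* by dense exact 11-mer matching along the chain diagonal.
Verification matters: the minimizer chain alone cannot distinguish a
full-length read overlap from a short shared segment (for example a
plastid-derived insertion carried by a mitochondrial read), and an
implied-overlap estimate would recruit the entire plastid read
population through such segments. The verified matched block is what
the 1 kb rule is applied to. Two refinements keep the block estimate
honest at the scale where it matters:

* chance shared words arrive as single short runs of adjacent k-mer
  matches, so isolated terminal anchors (runs more than 60 bp from the
  rest of the block) are trimmed before the extent is measured, and
* when the verified block falls just short of the threshold
  (50–100% of `min_overlap`), the aligned block is measured exactly by
  a local alignment (`pairwiseAlignment`) of the window around it,
  because k-mer "droughts" near block edges can otherwise underestimate
  a true overlap by a few hundred bases at 80% identity.

Identity over a verified block is estimated from matched k-mer density:
a k-mer survives at per-base identity *p* with probability about
*p^k*, so identity = density^(1/11), capped at 1. On pairs with planted
substitution counts the estimate is accurate to about ±0.02 over the
0.75–1.0 range. The minimizer screen itself cannot see overlaps much
below ~72% identity at these lengths — an inherent property of k = 15
sketches, acceptable here because the recruitment threshold is 70% and
the study's reads pair at ~81% identity (two reads at 10% error each).

**What the synthetic mixture shows.** At the default conditions (2,000
reads, 5% mito / 15% plastid / 80% nuclear, 10% uniform error with
substitutions:indels 3:1, mean read length 5 kb, gamma shape 5), recall
and precision of truth-labelled mitochondrial reads are both ≥ 0.95
across seeds. The nuclear fraction is random sequence, so precision
against it is structural; the plastid fraction is the interesting
contaminant, held out only by the verified-block rule because the
planted MTPT insertions (150/500/800 bp; about 2.4% of the mitogenome,
matching the scale of real MTPT content where most fragments are well
under 1 kb) are all shorter than the 1 kb overlap rule. Real data
differ in ways the generator does not emulate: homopolymer-biased
Nanopore errors, chimeric reads, and genuine MTPT fragments longer
than 1 kb (the reference genome has six), which *would* recruit plastid
reads — as they do for any recruitment scheme with these thresholds.

# RNA editing

Editing sites are inputs (gene + 1-based CDS position with reference
base C); site discovery is out of scope. `applyEdits()` performs the
C→T substitutions; `classifyChange()` translates the codon pair and
assigns one of the hydropathy-transition categories using the
convention of organelle editing tables: hydrophobic = {A, V, L, I, P,
F, M, W}, hydrophilic = {R, N, D, C, Q, E, H, K, S, T, Y, G}, stop its
own class. This table is taken from the published classifications
themselves (e.g. R→C is hydrophilic→hydrophilic, T→I/M
hydrophilic→hydrophobic) rather than from a numeric hydropathy scale;
glycine, which never occurs in such tables for C→T edits, is assigned
hydrophilic by the sign of its Kyte–Doolittle value and can be
overridden. Codons edited at both position 1 and 2 count once, as one
dual-position site. Fed the bundled published table, the summarizer
reproduces every printed count and percentage exactly (460 sites;
47.17% hydrophilic→hydrophobic; 44.78% unchanged; 46.52% edited to
leucine; 20 dual-position sites, 4.35%). One published inconsistency is
worth knowing: the in-text split of 136 position-1 and 304 position-2
sites cannot be derived from the published codon-change table, which
implies 122 and 318; the package derives position usage from the codon
changes and asserts only the table's own numbers.

# Codon usage

`rscu()` computes RSCU = n·k/Σ within synonym families of the standard
genetic code; families with zero usage report `NA`, and single-codon
families (Met, Trp) are exactly 1 whenever used. Terminal stop codons
are excluded from counting by default and multi-copy CDS are
deduplicated by exact sequence ("unique CDS"). The published RSCU
figure groups the alternative initiation codons CUG/UUG with AUG; the
`met_family` argument reproduces that three-codon family without
making it the default. `atEndingCensus()` reports the count of codons
with RSCU > 1 and the share of them ending in A/T, the usual statement
of organelle A/T bias.

# Repeats

* **SSRs** are maximal perfect runs with the MISA minimum copy numbers
  (1-10, 2-5, 3-4, 4-3, 5-3, 6-3). Runs whose motif is a repetition of
  a shorter unit are reported only at the shorter unit; reported motifs
  are canonicalized to the lexicographically minimal rotation; lengths
  are truncated to whole copies; circular genomes are scanned across
  the origin by doubling, with wrap-tail duplicates suppressed.
  Detection is proven equal to a brute-force enumerator on random
  sequences and is origin-rotation invariant. Composite MISA rules
  (merging two SSRs within 100 bp) are deliberately not applied; each
  perfect run is reported separately.
* **Tandem repeats** use the published weight set (match 2, mismatch 7,
  indel 7, min score 50, max period 2000) but a deterministic scoring
  scheme rather than a probabilistic model: candidate periods are
  proposed by exact 7-mer recurrence at a fixed distance, and each
  candidate region is scored against its majority-rule consensus.
  Overlapping candidates keep the best score, ties to the smaller
  period.
* **Dispersed repeats** are found by comparing the genome against
  itself in four orientations — unchanged (forward), reverse
  complement (palindromic), reversed (reverse) and complemented
  (complement) — via exact 11-mer seeds clustered by diagonal and
  extended ungapped with an X-drop. Pairs overlapping a reported SSR or
  tandem interval by more than half of a copy are removed, as are
  symmetric duplicates. E-value screening is replaced by explicit
  (length ≥ 30, identity ≥ 0.80) thresholds, which make planted-repeat
  recovery exact; database e-values depend on composition conventions
  that are not pinned down here.

# Plastid-derived fragments (MTPT)

`findHomologs()` seeds exact 12-mers between the two genomes on both
strands, clusters them by diagonal, and measures each candidate region
by local alignment with blastn-like weights (match 2, mismatch −3, gap
open 5, extend 2), reporting length, mismatches, gap openings,
identity and Table-style coordinates (minus-strand subject intervals
have start > end). The screening defaults are the published criteria —
identity ≥ 70%, length ≥ 30 bp — and an `evalue_proxy` computed from
the alignment score and genome-length product is reported for
reference only. `transferSummary()` reports both the plain sum of
fragment lengths and the overlap-merged union on the query genome. The
distinction matters: in the bundled published fragment table the 25
printed lengths sum to 21,420 bp, while the overlap-merged union of
the mitochondrial intervals is exactly the published total of
21,037 bp (3.93% of 535,692 bp) — the published "total length" is the
deduplicated union, because fragments overlapping on the mitogenome
(e.g. one fragment nested in another, or inverted-repeat duplicates)
would otherwise be double-counted. Both numbers are always emitted.
`annotateGeneCoverage()` merges fragment
intervals before computing per-gene coverage so IR-duplicated plastid
regions are not double-counted.

# Ka/Ks and nucleotide diversity

`ng86()` implements Nei–Gojobori (1986): per-codon site fractions
(changes to stop codons counted as nonsynonymous, so synonymous plus
nonsynonymous sites is exactly three per codon), pathway averaging over
multi-hit codons with stop-passing paths excluded when alternatives
exist, and Jukes–Cantor correction (undefined at p ≥ 3/4, reported as
missing). `mlwl()` implements the Li–Wu–Luo degeneracy-class framework
with Kimura two-parameter correction per class and the modified
weighting of twofold-degenerate sites: instead of LWL85's fixed 1/3
synonymous share, twofold sites are apportioned `kappa/(kappa+2)`
synonymous, with the transition/transversion ratio `kappa` estimated
from the fourfold class (`2*A4/B4`, clamped to [0.1, 20]; with kappa = 1
the estimator reduces to LWL85, available via `use_kappa = FALSE`).
Sites whose degeneracy class differs between the two codons are split
half-and-half, and differences at such sites likewise. Alignments must
be provided pre-aligned; gap-containing codon columns are removed
(complete deletion) and a shared terminal stop is stripped; internal
stops are an error. `ks = 0` or a saturated correction yields a missing
ratio, classified "undetermined" rather than infinite.

`piDiversity()` is the mean pairwise difference per site with complete
deletion of gap/ambiguity columns (pairwise deletion by flag). Note
that the standard estimator is *not* invariant under duplicating the
whole sequence set (the pair count grows faster than the difference
sum); the tests assert the exact 8/9 scaling for a duplicated
five-sequence set rather than pretending otherwise.

`makeDivergentPair()` plants synonymous/nonsynonymous budgets
(`ks_target * S` and `omega_target * ks_target * N` with S, N the NG86
site counts of the input) by accept/reject proposals, at most one
change per codon so every realized change has an unambiguous identity.
At 500 codons and `ks_target = 0.1`, the NG86 median estimate over 20
replicates recovers planted omega in {0.2, 1, 2} within 25%; the
residual upward bias at omega = 2 (~10%) is the Jukes–Cantor correction
inflating the larger of the two proportions, not an implementation
artifact.

# Sizes, tolerances and degenerate inputs

Default problem sizes were chosen as the smallest at which every
threshold relationship of the real study survives: mitogenome 60 kb
(10x smaller than real), plastid 20 kb, nuclear 200 kb, 2,000 reads.
Brute-force oracles run on 5 kb sequences; recruitment recovery on the
full default mixture over three seeds; omega recovery at 500 codons.
Percentages in reports are rounded to 2 decimals; category percentage
sums are asserted to 100 ± 0.02 to absorb rounding. Empty inputs yield
empty tables or zero summaries rather than errors, except where a
precondition is scientific (no seeds, fewer than two sequences for pi,
frame violations), which error with a message naming the offending
position. An all-N sequence has undefined GC, reported `NA`.

# Known limitations

* The recruitment aligner is a sketch-based stand-in tuned for the
  threshold regime of the published procedure; it is not a
  general-purpose overlapper and cannot see identity below ~0.72.
* The tandem finder is deterministic and consensus-based; it does not
  reproduce a specific external tool's output row-for-row, and its
  acceptance is property-based (planted recovery, score arithmetic).
* Editing-site *prediction* is out of scope; sites are inputs.
* The nuclear-genome homology analysis runs with the same machinery
  per contig, but no validation target depends on it; the full-scale
  nuclear analysis of the reference study is far beyond desk scale.
* Phylogenetics, plotting and assembly polishing are out of scope.
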