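---
title: "Arbitrating two long-read assemblies: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arbitrating two long-read assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(duoasm)
```

## The setting

Two assemblies of one genome disagree in two distinct channels. The
fragmented-but-accurate assembly (here "B", consensus-long-read-like)
breaks at repeats longer than its read span, and the assembler's
resolution of each break is either an *uncovered gap* (the repeat is
dropped) or an *overlap redundancy* (the repeat is carried by both
flanking contigs, duplicating the locus and any genes on it). The
contiguous-but-noisy assembly (here "A", ultralong-nanopore-like) spans
those repeats but carries residual consensus errors — substitutions and
small InDels — that survive short-read polishing wherever short-read
coverage is locally poor. `duoasm` implements the decision rules for both
channels plus the downstream accounting (genes gained/lost, translation
impact, telomere/centromere/T2T status), and a synthetic-truth generator
that makes every rule testable offline.

All internal coordinates are 0-based half-open; 1-based closed appears
only at the GFF3/VCF boundary. This is the native PAF convention and
removes off-by-one ambiguity at interval arithmetic.

## Structural arbitration

Alignments of B onto A are consumed as PAF. Per query contig the primary
hits are kept (`tp:A:P`; when no hit is flagged, the single largest block
wins, ties broken by matches then leftmost target start). Projection onto
the target merges same-query intervals with a 0 bp gap tolerance by
default: gap calling downstream must see true discontinuities, so merging
across gaps would hide exactly the signal of interest. The optional
reciprocal-match filter (both spans ≥ 1 Mb) reproduces the backbone
restriction used when binning mismatches; "reciprocal" is read as the
span condition on both sequences.

* `call_gaps`: maximal target intervals covered by zero projections, at
  least `min_gap_bp` long. Default 50 bp — sub-50 bp uncovered slivers
  are alignment boundary jitter, not structure.
* `call_overlaps`: pairwise intersections of distinct queries'
  projections.
* `classify_redundancy`: an overlap is a redundancy iff similarity
  ≥ 0.97 **and** the copies' depths satisfy `d1 + d2 < 60`,
  `d1 < 40`, `d2 < 40`. Similarity is alignment identity
  (`n_matches / block_len`) — the natural reading of a "similarity
  level" of e.g. 99.67%. The depth bounds suit roughly 50× consensus
  coverage and are exposed as configuration. Missing depth yields
  `"unknown"`, never a silent redundancy. The rule is monotone:
  raising similarity or lowering either depth can never undo a
  redundancy verdict (property-tested).
* `call_loss_and_double_cover`: gap intervals with zero projection
  coverage are losses; those covered ≥ 2× over a majority of their bases
  are redundancies; single coverage is deliberately uncalled (the
  dichotomy defines only the two extremes).
* `annotate_repeat_context`: *tandem* when a non-identity self-alignment
  of A pairs two same-contig copies that flank or contain the call, both
  within 100 kb; *dispersed* when the call's interval matches at ≥ 95%
  identity on another contig or > 100 kb away. The 100 kb flank distance
  is this package's choice — the source analyses distinguish the two
  qualitatively — and the requirement that the call lie inside the span
  of the paired copies prevents an unrelated nearby tandem from
  mislabeling a dispersed event.
* `count_gene_gain_loss`: a gene counts toward a call when ≥ 1 bp of CDS
  overlaps it (whole-gene containment is available as a stricter
  option), once per call kind.

The per-copy depth fed to `classify_redundancy` by `run_compare` is half
the consensus-track depth over the interval: the track is expressed on
assembly A, and reads mapped to a redundant assembly split between the
two copies.

## The consensus-error model

Variant records (one sample, GT field) are filtered with the per-class
hard conditions listed in `filter_thresholds()`. A record missing an
annotation **passes** the conditions that reference it, mirroring GATK
semantics — failing on absence would bias the error set toward
well-annotated sites. Heterozygous records represent true heterozygosity
of the sequenced individual (the assemblies each hold one haplotype), so
only homozygous-alternate (1/1) records become assembly errors. Filtering
before genotype selection or after is observationally identical for the
final set; the package filters first. The InDel position convention
anchors the error at the VCF POS base (0-based internally) with
`length = |len(ref) − len(alt)|`.

Clustering is assessed formally: under random placement, errors form a
homogeneous Poisson process and adjacent distances are exponential with
mean `1000 / rate` bp (943.4 bp at 1.06/kb, conventionally "~1 kb").
`clustering_test` runs a one-sample Kolmogorov–Smirnov test against that
law and reports "clustered" only when the test rejects **and** the
observed median is below the exponential median, so heavy right tails
alone cannot trigger the verdict. The descriptive normal(1000, 200)
overlay sometimes drawn for this comparison is a plotting convention,
not the null used here. Fewer than 10 distances yield "undetermined".

Windows tile each contig at width 1,000 bp and step 500 bp; the final
short window is kept and flagged. A window with ≥ 5 errors is
error-enriched. Each interior error therefore lands in exactly
`window/step = 2` windows (brute-force-verified). GC content comes from
the assembly sequence, methylation from sites with `called_sites ≥ 10`.
Enriched-vs-other contrasts use two-sided Mann–Whitney U tests with
group medians for direction; significance without a named test in the
source is formalized this way. The genome-wide error rate is reported
under both denominators — full assembly and projected backbone — since
the source leaves the denominator ambiguous.

## Translation impact

`classify_error_impact` compares the protein of the error-bearing
assembly (`protein_before`) with that of the corrected sequence
(`protein_after`): errors corrupt the annotation, the evidence allele
repairs it. An InDel with length ≢ 0 (mod 3) inside CDS is a frameshift
regardless of downstream sequence. Otherwise both CDS are rebuilt (exon
substrings in genomic order, reverse-complemented as one unit on the
minus strand) and translated with the standard code, stopping at the
first stop: an earlier first stop in the assembly is a stop-gain, a later
one a stop-loss, a changed protein a missense, an identical protein
synonymous. Splice sites are not modeled; an intronic error within 2 bp
of a junction is flagged `splice_adjacent` but stays noncoding. Affected
exon/gene counts are reported under both criteria — missense-inclusive
(anything that changes the protein prevents correct translation) and
disruption-only (frameshift/stop) — because either reading of "failed to
translate correctly" is defensible. The classifier is property-tested for
exact agreement against an independent rebuild-and-translate oracle with
its own hardcoded codon table.

## Telomeres, centromeres, T2T

Telomere arrays are maximal tandem runs of the 7-mer motif (forward or
reverse complement) with per-unit mismatch fraction ≤ 0.1 and at least
10 units, classified by proximity (10 kb) to contig ends. Centromeres
are found by exact-word seeding from the unit consensus followed by
global alignment of each candidate full-length window; units at identity
≥ 0.8 are kept and merged within 10 kb. Partial (sub-unit) matches never
found a region — full units are required. These cutoffs are this
package's operating points: the original identifications used a
tandem-repeat finder and a read aligner whose parameters do not translate
directly, so the detectors are declared approximations of the described
intent, with every threshold exposed. T2T requires a telomere hit at each
end and zero Ns; centromere presence is reported and optionally required.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the study conditions: 2 chromosomes
(10 Mb each by default), GC 0.435, telomere arrays of 100 `AAACCCT`
units at both ends, one 155 bp-unit centromere array per chromosome,
tandem repeat units of 14/23/48 kb (two copies) and dispersed 48/15 kb
duplication pairs across chromosomes at ≥ 97% mutual identity, gene
models of 2–4 exons hosting ATG…TAA open reading frames (one gene embedded
per repeat unit, so redundancies and losses carry genes), errors at
1.06/kb with half placed in designated 1 kb cluster windows,
geometric InDel lengths of mean 1.39 bp (the source reports the mean and
an overflow note only, so the law is a declared modeling choice),
heterozygous sites at 0.5/kb, and 5% spurious filter-failing records.
Cluster windows receive Beta(8,2) methylated fractions versus Beta(2,8)
elsewhere, and shotgun depth ≤ 5 versus Poisson(30) elsewhere — the
declared choices that make the methylation contrast and the
depth-at-error fraction recoverable. Assembly B breaks at every repeat
span ≥ 20 kb (a consensus-read span proxy mirroring the observation that
14–48 kb repeats break such assemblies), choosing gap or overlap mode
with equal probability. True alignments are emitted directly from
construction with exact difference strings — no aligner runs in tests.

Deliberate simplifications, hence limits on what passing tests show
about real data: errors are never planted inside telomere/centromere
arrays (an indel there would make the planted-array ledger ambiguous),
InDel anchors keep 200 bp clear of repeat boundaries and 12 bp clear of
CDS boundaries so every planted interval maps cleanly between truth and
assembly-A coordinates, repeat copies diverge by substitutions only,
background sequence is i.i.d. (no homopolymer or SSR structure, although
real consensus errors concentrate there), and no read-level simulation
is attempted. Structural recovery at precision = recall = 1 on this
system demonstrates the decision logic, not robustness to noisy
real-world alignments.

Everything is a pure function of `(config, seed)`: fixture regeneration
is byte-identical under a fixed seed and diverges when the seed changes
(tested via checksums).

## Numerical and degenerate-input choices

* Interval algebra is delegated to IRanges; coverage profiles are
  run-length encodings, compared against per-base brute force in tests.
* `read_vcf` splits multi-allelic records (per-allele genotype
  re-expression), drops symbolic alleles with a counter, and never
  converts a missing annotation to zero.
* Empty inputs return empty, well-typed frames; missing optional inputs
  (methylation, depth, consensus) skip their analyses with a recorded
  reason rather than failing the run.
* Ties in primary-hit fallback: block length, then matches, then
  leftmost target start — fully deterministic.
* KS ties warnings on integer distances are suppressed; the test is used
  as a one-sample decision rule, not for exact p-values in the tail.

## Problem sizes

The shipped analyses and acceptance checks run at 2 × 10 Mb (structural
and error recovery), 1 Mb (window brute-force and motif-free feature
controls), 50 Mb of simulated point placement (spacing null), 200/50
replicates (clustering calibration/power) and 1,000 random gene–error
pairs (oracle equivalence) — sizes chosen so the full suite completes in
a few minutes on one core while keeping every estimate's Monte-Carlo
error far below the tolerances tested.
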