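---
title: "Evaluating gaps and structural variation in phased assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating gaps and structural variation in phased assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmgaps)
library(dplyr)
```

## The problem

Haplotype-resolved ("phased") diploid assemblies built from long reads still
break into a few hundred contigs per haplotype. Understanding *where* and
*why* they break — and what sequence lives at the breakpoints — is the
prerequisite for closing the remaining gaps. Given contig-to-reference
alignments (PAF) against a complete reference, `asmgaps` computes four
complementary views of assembly quality:

1. **Assembly gaps** — reference intervals between the end alignments of
   subsequent contigs.
2. **Contig-end annotation** — which sequence features (segmental
   duplications, satellite DNA, GA/TC and AT low-complexity windows,
   chromosome termini) coincide with contig breaks, with a permutation test
   for enrichment.
3. **Alignment discontinuities** — intra-contig gaps below 1 Mbp, classified
   as sequence *contractions* (reference gap larger than the contig gap) or
   *expansions* (the converse), the signature of structural variation that
   cannot be linearly aligned.
4. **Multi-coverage regions** — reference intervals covered by more than one
   contig of a single haploid assembly, including fully embedded contigs,
   screened against windowed copy-number profiles.

Orthogonal validation closes the loop: long-read spanning of gaps, and
phasing concordance of megabase blocks against a trusted phased variant set.

All functions take and return tibbles with 0-based half-open intervals
(BED/PAF convention), so stages compose with the pipe.

## Alignment model and filters

Alignments enter through `read_paf()` and are filtered exactly once:
mapping quality ≥ 10, alignment width on the reference ≥ 1 kbp, and contig
length ≥ 100 kbp. The width filter is applied on the reference axis because
all downstream interval logic (gaps, discontinuities, coverage) lives in
reference coordinates. Secondary alignments are expected to be absent
(assemblies are aligned with secondary reporting disabled); a tagged
secondary record is dropped with a warning rather than an error. Every
numeric threshold lives in a single validated `asm_thresholds()` object that
writers echo into a `## thresholds:` header line, so a run is reproducible
from its outputs.

## Contig ends, pieces and gaps

Two notions of a contig end serve different purposes:

* **Simple ends** (`simple_ends()`): walking inward from each contig
  extremity, the first alignment with ≥ 25 kbp on the reference anchors that
  side. These are the unit of the enrichment analysis. When smaller
  alignments lie outside the qualifying one, the end is anchored at the
  qualifying alignment's outer boundary — the smaller outer fragments are
  exactly the spurious mappings the 25-kbp floor is there to ignore.
* **Contig-end alignments** (`end_alignments()`): terminal alignments of
  ≥ 50 kbp delimit contig *pieces*. When a contig's end-to-end reference
  span exceeds its length by more than 5% — the signature of ends mapping to
  distal duplication pairs or across a centromere — the contig is split into
  the minimal number of pieces such that each piece satisfies the 5% rule.
  The split points are chosen by an exact dynamic program: among all minimal
  partitions it cuts at the largest target-coordinate jumps (ties resolved
  toward the earliest cuts). Parsimony is the natural reading of "split into
  more than one alignment": each cut asserts a real discontinuity, so we
  assert as few as possible, at the places where the mapping jumps farthest.

`report_gaps()` then emits the reference intervals left uncovered between
subsequent pieces of one haploid assembly. The gap opens at the *running
maximum* of piece right ends rather than at the right end of the immediately
preceding piece: a piece wholly contained in another piece's span (an
embedded contig) would otherwise manufacture a gap inside perfectly
assembled sequence. Abutting or overlapping pieces emit nothing, so
zero-width gaps cannot occur.

## End annotation and enrichment

`annotate_ends()` gives every end exactly one label, by priority:
chromosome ends (within 100 kbp of a reference chromosome terminus) beat the
composite SD+GA/TC label, which beats SD, satellite, GA/TC and AT in that
order; the order is configurable. An end matches a track when it lies within
10 kbp of an interval (distances count intervening bases, so an end
immediately adjacent to a feature is at distance 0). Ends matching nothing
are *Poisson ends* when no end of any other haploid assembly lies within
10 kbp on the same chromosome — breaks private to one haplotype and
therefore plausibly random — and `other` otherwise. Because labels are
exclusive and exhaustive, category counts always sum to the number of ends.

`permutation_enrichment()` asks a different question — *how much more often
than chance?* — and therefore deliberately lets an end count toward several
tracks. The null places the same number of ends uniformly over the
concatenated chromosome lengths (no masking by default; an exclusion track
can be supplied by padding the input tracks). Fold enrichment is the
observed count over the median of 10,000 random counts, and the empirical
p-value is `(1 + #[random ≥ observed]) / (1 + n)`. With a fixed seed the
whole result is reproducible. Two guarded corners: an empty track yields an
`NA` fold flagged `empty_track`, and a zero random median reports the
observed count as the fold, flagged `median_zero`.

`recurrent_gap_regions()` merges pooled gaps into maximal regions and counts
*distinct haploid assemblies* per region (a sample contributes at most one
per haplotype); `gene_overlap()` counts, per gene, the assemblies whose gaps
touch it, after collapsing each gene's ranges to one bounding interval.

## Low-complexity tracts

`dinucleotide_profile()` counts overlapping occurrences of TA, TC and GA in
non-overlapping 100-bp bins; an occurrence straddling a bin boundary is
counted in neither bin (the straddle count is recorded, which makes the
conservation check *bins + straddles = whole-sequence count* exact). Within
the profiled sequence, `enriched_tracts()` turns each dinucleotide's bin
counts into Z-scores and calls bins with Z ≥ 1.96 enriched; maximal runs of
enriched bins become tracts sized as `bins × 100`. Sizing is therefore
quantized: a planted pure tract of length L is recovered within ± 200 bp
(one bin either side) for every possible bin phase. Z-scores are computed
per analyzed region, not genome-wide, so the profiled window should be an
order of magnitude longer than the tract of interest; a region dominated by
its own tract inflates the mean and variance and suppresses the call (a
degenerate all-identical profile yields no tracts at all, recorded in the
`degenerate` attribute).

`gatc_windows()` flags 1-kbp sliding windows (100-bp step) in which ≥ 80% of
bases participate in GA or TC dinucleotide occurrences, then merges
overlapping flagged windows. This content measure is 1.0 on pure tracts and
≈ 0.25 on uniform-random sequence, so the 80% threshold separates them with
a wide margin; merging makes the result insensitive to the step for tracts
of window size and above. `at_windows()` applies the same machinery to
AT/TA with the same default threshold — the AT-richness cut-off is a package
default, chosen to mirror the GA/TC rule, and is configurable.

## Discontinuities and structural variation

`find_discontinuities()` walks query-adjacent alignment pairs of each contig
on one chromosome, computing the gap on both axes in the contig's forward
coordinate system (reverse-strand pairs measure the target gap right-to-left;
pairs spanning a strand switch are evaluated and flagged, since an inversion
breakpoint legitimately presents as two such pairs). Gaps ≥ 1 Mbp are not
discontinuities — those are the assembly gaps of the previous section.
Classification follows the two gap sizes: contraction when the reference gap
is larger, expansion when smaller (a point insertion has reference gap 0),
neutral when equal; the event size is their absolute difference and the
query gap is the count of unaligned bases. Pairs with overlapping query
intervals are artifacts of split alignments and are skipped with a warning.

`censat_flagging()` marks events within ± 1 Mbp of centromeric satellite
DNA; `summarize_unaligned()` totals unaligned bases per assembly inside and
outside that flag; `recurrent_sv_regions()` merges same-class events of
≥ 100 bp and keeps regions supported by ≥ 5 distinct assemblies.

## Multi-coverage and copy number

`multicoverage_regions()` is a sweep over one haplotype's target intervals
(IRanges coverage), emitting maximal depth ≥ 2 regions with their
contributing contigs; the `embedded` flag fires when one contributor's whole
aligned span lies inside another's. `depth_to_copy_number()` converts a
windowed depth table to diploid copy number by scaling the control-window
mean to 2 (per-GC-decile when a `gc` column exists — a linear stand-in for a
full GC-bias model, sufficient because the contribution here is the
classification, not the depth estimator). `classify_cnv()` averages windows
over each region, rounds half-up to integers, and applies the four-way rule
in `cnv_category()`: `noCN` when the sample copy number is 2 *or* equals the
reference ("or" read literally); else `CNV` when below 10 with an increase
of ≥ 1 over the k-merized reference copy number; else `more10CN` when above
10 with an increase; else `none`. A sample copy number of exactly 10 with an
increase satisfies neither bound and falls to `none` — the rule's strict
inequalities leave that single value unassigned, and we do not guess
otherwise. Regions with no window in either track are `uncallable`, kept
distinct from `none`.

`loh_screen()` addresses the embedded-contig pathology where one of two
overlapping same-haplotype contigs has lost its allelic variation and
instead mirrors the opposite parental haplotype: a contig is flagged when
its het-variant density falls below 10% of the assembly-wide median *and*
its differences from the opposite haplotype fall below 10% of the expected
heterozygous rate. Both 10% values are package defaults (the pattern is
qualitative in origin) and are arguments.

## Validation

`gap_spanning()` counts reads (mapq ≥ 10) whose alignment strictly contains
a gap; ≥ 10 such reads mark the gap closable by the longer read type.
Strict containment is the literal reading of "spanned"; partial-overlap
counting would measure coverage, not traversal.

`phase_concordance()` splits each chromosome into 1-Mbp blocks and assigns
each block of each test haplotype to truth haplotype H1 or H2 by majority
vote over truth-heterozygous sites (ties unassigned). Because the truth
labelling is arbitrary, each test haplotype is anchored to the truth
haplotype it matches at the majority of sites genome-wide before discordance
is counted — which makes the result invariant under relabelling the truth.
Maximal runs of consecutive discordant blocks are reported as candidate
large-scale switch errors. Terminal sub-megabase blocks participate
whenever they contain an informative site.

## The synthetic truth set

`reference_spec()`/`build_reference()` generate a uniform-random background
with planted, non-overlapping features: SD blocks (a source copy plus copies
mutated at `1 - identity`), satellite arrays (repeated monomer), and pure
dinucleotide tracts, each emitted as an annotation track.
`simulate_assembly()` derives contigs deterministically from a plan of
events (gap, contraction, expansion, inversion, embedded contig, tandem
copy-number gain) and writes the truth alignment set *analytically* — one
record per maximal co-linear segment, mapping quality 60 — rather than by
running an aligner, so tests carry no aligner nondeterminism. A
`low_mapq_frac` option injects mapq-2 records to exercise the filter.

The bundled study conditions (`demo_truth()`) are a 10-Mbp chromosome in two
haplotypes carrying 12 gaps (ten sitting on SD, satellite and GA/TC
features, two private), 6 contractions (0.8–30 kbp), 6 expansions
(2–50 kbp), 2 inversions (150–200 kbp) and 3 embedded contigs
(150–200 kbp). Feature sizes mirror the scales at which real assemblies
break: 50–60-kbp SDs at 98–99% identity, a 250-kbp satellite array, and
dinucleotide tracts of 0.6–3 kbp. What the generator does *not* emulate —
read-level errors, coverage fluctuation, aligner ambiguity in near-identical
repeats, true centromeric higher-order structure — bounds what passing tests
show: they certify the interval logic and classification rules, not
robustness to aligner noise.

## Numerical choices and problem sizes

Tests and the acceptance script run on the 2 × 10 Mbp synthetic diploid,
200-replicate permutation calibrations at 1,000 permutations, 500-window
copy-number recovery, and tract sizing over all 100 bin phases for tract
lengths 300–6,500 bp — sizes chosen so the full suite certifies every stage
on one CPU in minutes while keeping all combinatorial oracles exhaustive.
Other conventions: sorting is stable with ties broken by target start then
target name; interval merging treats abutting intervals as one region;
point events are widened to 1 bp only for overlap computations; and all
randomness flows through explicit integer seeds recorded in results.

## Known limitations

* The truth alignment set is idealized; against real minimap2 output,
  alignment-end wobble of a few bases will blur exact-coordinate recovery
  into near-exact recovery.
* Enrichment's uniform null does not mask unassemblable sequence; supplying
  pre-padded tracks or restricting chromosomes is the workaround.
* The GC correction is linear per decile, not a spline-based bias model.
* `loh_screen()` consumes variant tables; it does not call variants.
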