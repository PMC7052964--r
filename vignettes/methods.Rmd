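---
title: "Methods: window-based synteny blocks and comparative genomic screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-based synteny blocks and comparative genomic screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomescreens)
```

`genomescreens` implements five comparative-genomics screens for small
eukaryotic (yeast-scale) genomes, each operating on plain tables and each
testable against seeded synthetic genomes with exact ground truth. This
vignette records the models, the tunable parameters, the numerical choices,
and the limits of what a green test establishes.

## Coordinate convention

Every interval inside the package is 0-based, half-open, `start < end`.
Conversions happen only at I/O boundaries: MUMmer `show-coords` input is
1-based inclusive (reverse-strand query intervals arrive as start > end and
become an explicit `orientation = "reverse"` flag); VCF `POS` is 1-based;
PAF is already half-open. No function outside the readers and writers
converts bases, which removes the usual off-by-one ambiguity from the
analysis code.

## Window-based synteny blocks

The rearrangement statistic is the number of synteny blocks between a
reference and a query assembly. The caller works at window resolution:

1. **Windowing.** Each genome is cut into sliding windows (defaults:
   `window_size` 20 kb, `step_size` 10 kb). Windows start at multiples of
   the step while the start lies inside the contig and end at
   `min(start + window, contig_length)`; a final truncated window shorter
   than the step is merged into its predecessor, so no window shorter than
   one step exists except on sub-step contigs. The trailing window of a
   contig whose length is a step multiple has length exactly one step and
   is kept. This enumeration rule is normative: the test suite carries an
   independent loop-based enumeration and requires exact agreement.
2. **Pairing.** Each alignment's overlap with every intersecting reference
   window is projected affinely onto its query interval (mirrored for
   reverse orientation; coordinates rounded to integers — with exact truth
   alignments the map is the identity and rounding is a no-op) and
   attributed to the query windows the projection intersects. Support for a
   (ref window, qry window, orientation) triple is the summed projected
   overlap in query bp, capped at the shorter window. Triples with support
   below `min_support_bp` (default 2000 bp, 10% of a window) are dropped;
   the floor suppresses spurious pairs from short repeat alignments.
   Each triple also records the *diagonal* of its dominant contribution
   (forward: `qry = ref + diag`; reverse: `qry = diag − ref`; ties between
   equal-support contributions resolve to the smaller diagonal).
3. **Merging.** Two window pairs are concordant when they share contigs and
   orientation, their reference window starts lie within `max_gap_windows`
   steps (default 1, i.e. consecutive sliding windows, which physically
   overlap), and their diagonals differ by strictly less than one step.
   Maximal sets under the transitive closure merge into one block spanning
   the union of their intervals. The diagonal requirement is the design
   choice that makes this work: windows straddling a rearrangement
   breakpoint legitimately carry support from two different alignment
   diagonals, and any purely grid-based adjacency rule lets such windows
   transitively fuse the blocks on either side of the breakpoint. Requiring
   diagonal coherence is the minimal definition of "concordant" that keeps
   collinear chains intact and splits them at breakpoints.
4. **Trimming.** Where the reference intervals of two remaining (hence
   discordant) blocks overlap, the block with smaller support is trimmed to
   remove the overlap; ties trim the later block in reference order. A
   block whose trim would split it keeps its longer remaining piece (tie:
   the left piece); blocks trimmed to nothing are dropped. Trimming acts on
   the reference only — the output is reference-anchored, as in Circos-style
   synteny plots — so query-side overlaps may remain, and the query interval
   of a trimmed block keeps its merged span.

Block boundaries are therefore accurate to roughly one window, and events
smaller than about one window are not resolvable — a planted inversion
shorter than `window_size` can be absorbed by its flanking forward chains.
Two nearby events can also merge their boundary fuzz, so the block count
carries a ± boundary-window uncertainty; the exhaustive-search oracle in
the test suite is the normative reference for the exact output on any
given instance.

## Synthetic genome pairs

`sample_rearrangement_truth()` composes translocations and inversions on an
evolving query arrangement, tracking an exact segment map (query order,
reference intervals, orientations) whose intervals tile both genomes.
`make_rearranged_pair()` adds i.i.d. uniform ACGT sequence; substring
equality holds segment by segment (reverse complement for inversions).
Repeat structure is deliberately absent: alignments are supplied from the
truth, so sequence self-similarity plays no role in the tests. Events are
drawn sequentially from the seed, so extending the event list reuses the
earlier events — this nesting is what makes "adding one event never
decreases the block count" a testable family property.

Breakpoints are rejected (bounded retries) within `min_segment` of an
existing breakpoint. The default is 30 kb = `window_size + step_size`: the
smallest spacing for which every truth segment contains at least one
complete sliding window whatever its phase on the step grid, i.e. the
smallest spacing at which segments are window-resolvable. (An earlier 10 kb
default produced sub-window segments that the caller cannot resolve, and
block-count monotonicity failed on exactly those instances.) Tests that
only need oracle equivalence — not resolvability — pass a smaller explicit
`min_segment` to fit more events onto small genomes.

A green synteny test therefore establishes that the caller implements the
declared window rules exactly and recovers window-resolvable rearrangements;
it does not establish performance on real aligner output with indels,
repeats, and fragmented alignments, which the generator does not emulate.

## Average nucleotide identity

`ani_matrix()` computes, per sequence pair of an aligned FASTA,
`100 × matches / comparable_sites`, where comparable sites are columns with
an unambiguous base (A/C/G/T) in *both* sequences — gaps and N are excluded
pairwise, not alignment-wide, matching pairwise-identity semantics of
alignment-based ANI estimators. Whether a gap-vs-base column should instead
count as a mismatch is a genuinely open choice; exclusion is this package's
normative rule, and switching would lower reported identities in gappy
alignments. Identities are reported at one decimal in exported TSVs; full
precision is kept internally.

`make_codon_msa()` derives each sequence independently from a hidden common
ancestor with per-site substitution probability `q` solved from
`(1-q)² + q²/3 = t`, the star-topology condition under which every emitted
pair has expected identity `t` (two sequences match when both sites are
unmutated or both mutated to the same of three alternatives). The solution
is valid for `t > 0.25`, the random-sequence floor. At 9000 sites the
binomial standard deviation is ≈ 0.45 percentage points, so the 2-point
recovery band used in the tests is a ≈ 4.5-sigma check.

## Gene-family expansion and GO enrichment

For each orthogroup and focal species the expansion statistic is the ratio
of the species' gene count to the mean count over an averaging set; ratios
≥ 2 are flagged. The averaging set defaults to *all* species in the table
and is configurable to a subset, because the natural-language description
of "the average gene count" is ambiguous between the focal clade and the
full taxon set of the orthology run — both readings are expressible, neither
is asserted as canonical. Orthogroups with zero mean are skipped (no
denominator); a count of 2 against an otherwise absent family (mean 0.4 in
a 5-species table) yields ratio 5 and is flagged, which is the intended
behaviour for lineage-specific amplifications.

Enrichment uses the upper-tail hypergeometric probability
`P(X ≥ k)` for `k` study hits of a term among `n` study genes, with `K`
population hits in `N` population genes, computed as a sum of
`exp(lchoose(...))` terms (exact to well beyond 10 significant digits for
`N ≤ 10⁴`; verified against exhaustive draw enumeration for `N ≤ 12` and
against `stats::phyper`). One test per term with ≥ 1 study hit; the
Bonferroni multiplier is the number of tested terms; `significant` means
corrected p ≤ α (default 0.05). Term annotations are flat — no GO-DAG
ancestor propagation unless the caller supplies pre-propagated annotations —
keeping the package self-contained.

## Alien Index

For each protein with BLAST hits partitioned into a self lineage (e.g.
Fungi) and a candidate donor lineage (e.g. Bacteria),

AI = ln(best_e_self + c) − ln(best_e_alien + c)

with pseudo-count `c = 1e-200` and missing best hits substituted by E = 1.
The pseudo-count bounds scores at ±ln(1/c) ≈ ±460.5 and the natural log
matches the score range of published screens (strong candidates at AI
30–140). Candidates satisfy a strict `ai > 20`. The exact constants of the
original formulation are declared here rather than inherited: log base,
pseudo-count and missing-hit substitution are all configurable. Masking the
recipient genus is done by substring matching against subject identifiers
(`exclude_taxa`), not by taxonomy resolution; subjects absent from the
lineage map are an error by default because silently dropping them biases
the score.

## Loss of heterozygosity

SNP densities (SNPs/kb) are computed per contig (default) or per sliding
window under the same windowing rules as the synteny caller; half-open
membership puts a boundary SNP in the window that starts there. A unit is
called homozygous when its density falls below the threshold, default 0.5
SNPs/kb: the two density regimes reported for heterozygous yeast assemblies
sit roughly 100-fold apart (~0.03 vs ~3 SNPs/kb), so any threshold between
them separates the regimes and 0.5 is simply a round geometric midpoint.
At that separation, Poisson noise cannot cross the threshold on ≥ 100 kb
contigs except with negligible probability, which is why the acceptance
test demands exact plan recovery in 1000/1000 replicates. The per-class
summary densities are *aggregates* (total SNPs in the class / total bp in
the class), not means of per-contig densities — the two differ whenever
contig lengths differ, and the aggregate is this package's definition.
Note the window-level summary double-counts SNPs where windows overlap;
class-level aggregate densities are intended for contig-level calls.

`simulate_snp_track()` draws `Poisson(density × length / 1000)` SNPs per
planned region, placed uniformly without replacement, and can write a
minimal VCF 4.2 (heterozygous genotypes, FILTER PASS). It emulates density
mosaics only — no linkage, no clustering, no genotype error — so a green
LOH test establishes threshold classification and bookkeeping, not
robustness to real variant-calling artefacts.

## Pipeline

`run_all()` executes the configured stages in a fixed order, writes one TSV
per stage plus a JSON manifest (package version, parameters, input MD5
checksums, completed stages), and aborts on the first stage error naming
the stage; the manifest then records which stages completed. Orchestration
adds no computation: each stage's output equals the corresponding direct
function call, which the test suite asserts. Configuration is a plain list
or a JSON file (no YAML parser is required at runtime); unknown top-level
keys are rejected. The exported functions plus `run_all()` are the
package's interface — there is no shell entry point, since the intended use
is interactive or scripted R.

## Known limitations

- Block boundaries are window-quantised; reported `support_bp` counts
  query-bp over overlapping windows and is a chain weight, not a bp tally.
- Trimming is reference-anchored; query intervals of trimmed blocks retain
  their merged span.
- The synthetic world omits indels, repeats, and alignment noise; claims
  about real NUCmer/minimap2 output rest on the format readers and the
  algorithm definition, not on the tests.
- ANI assumes the input is a trustworthy codon alignment; no frame or
  codon-position checks are made.
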