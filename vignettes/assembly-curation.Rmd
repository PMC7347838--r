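---
title: "Assembly curation, synteny analysis and consensus selection calling with asmforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly curation, synteny analysis and consensus selection calling with asmforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmforge)
```

# Scope and coordinate conventions

`asmforge` packages the bespoke computational stages that sit between
the big genome-assembly tools: mate-pair in-silico size selection,
junction validation by spanning long-read support, link-graph
scaffolding with a reference-synteny guard, end-overlap joining, synteny
block chaining with chromosome anchoring and rearrangement counting,
assembly QC, and consensus positive-selection calling with
hypergeometric enrichment.

One coordinate dialect is used throughout: alignments and layouts are
**0-based half-open** (the PAF convention), and minus-strand records
keep both query and target coordinates on the forward strand. The only
1-based format is AGP (written and read as v2.1, component rows `W`,
gap rows `N`), because that is how AGP is defined. The package consumes
alignments; it never computes them. SAM/BAM or MAF input must be
converted to PAF upstream — this keeps a single coordinate dialect in
the whole pipeline and is a stated precondition, not a limitation we
work around internally.

FASTA I/O goes through Biostrings `BStringSet`, which preserves
character case byte-exactly; soft-masked (lowercase) bases survive a
round-trip, and `N` is the only character interpreted as an assembly
gap.

# The synthetic-data model

Every stage is testable without external data because the `simulate_*`
generators produce inputs **with planted truth**. All generators are
pure functions of their parameters and a seed (the caller's RNG state is
saved and restored).

**Genomes.** `simulate_genome()` concatenates a 5' `(CCCTAA)n` array,
an i.i.d. interior at a configurable GC content (default 0.41, a
typical teleost value), and a 3' `(TTAGGG)n` array. Default
`telomere_units = 10` gives 60 bp arrays, long enough to be unambiguous
and short enough not to distort base composition.

**Long reads.** Read lengths are truncated-normal (default
10 ± 1 kb, the scale of modern long-read subreads), positions uniform,
strands fair, and errors pure substitutions. Indels are deliberately
not modeled: the downstream logic (spanning support, link building)
consumes alignment *intervals*, so substitution-only reads exercise it
fully while keeping the truth alignment of every read exact and
gap-free. The truth PAF carries `mapq = 60` — the simulator emulates
uniquely mapped reads only.

**Gel-free mate pairs.** A library without physical size selection is a
mixture: inward-facing small-insert paired-end contaminants plus
outward-facing large-insert circularization mate pairs. The default
study mixture (50% inward 300 ± 30 bp, 50% outward 3000 ± 300 bp,
100 bp reads) has components separated by dozens of standard
deviations, so orientation and insert together identify the component
essentially perfectly — which is exactly the regime the in-silico
size-selection idea assumes.

**Misassemblies.** `plant_misassemblies()` first fragments each
chromosome by uniform breakpoints until the fragment N50 falls below a
target (a simple, seedable stand-in for contig structure; minimum
fragment 1 kb), then plants events:

* *fusion* — two whole fragments from different chromosomes joined
  across an N gap (default 100 bp), the classic chimeric join;
* *true join* (`n_true_joins`) — two genome-adjacent fragments of the
  same chromosome rejoined across an N gap. These emulate **correct**
  scaffold joins and exist so junction validation is tested against
  support-positive junctions, not only chimeric ones;
* *inversion* — an internal interval (≥ 500 bp, ≥ 500 bp margins) of a
  fragment reverse-complemented in place;
* *translocation* — an internal interval excised from a donor fragment
  and inserted into an acceptor fragment from another chromosome.

The derived assembly is described by a *layout* (segments = source
intervals with strand; gaps flagged `bridged` when genome-contiguous).
Base content is conserved: the non-N base multiset is identical to the
genome's except under inversions, where reverse complementation
conserves the strand-pooled counts A+T and G+C instead — the tests
assert exactly that.

**Truth alignments on the derived assembly.** `lift_alignments()`
projects genome-coordinate truth alignments through the layout:
intersect with segments, map to derived coordinates, and merge pieces
across *bridged* gaps into a single record spanning the gap. This is
the package's model of how an aligner reports a true read across a
correct scaffold gap (one alignment, the N run inside the block) versus
a chimeric junction (alignments clipped on both sides). Pieces shorter
than 50 bp are dropped, mirroring an aligner's reluctance to report
tiny fragments. Using an analytic truth mapper rather than an external
aligner keeps the tests deterministic and the truth exact.

**Marker maps and P-value matrices.** `simulate_marker_map()` places
markers uniformly (one linkage group per chromosome, genetic position
monotone in physical position) and reassigns exactly
`round(n × discordant_fraction)` markers to a different group.
`simulate_psg_table()` draws four i.i.d. Uniform(0,1) P-values for null
genes and four i.i.d. Beta(α, 1) values (CDF `x^α`) for selected genes
— a single-parameter alternative with closed-form tails, so the
consensus caller can be calibrated analytically.

What the simulations do **not** emulate: repeat families and
low-complexity sequence, heterozygosity/diploidy, CIGAR-level indel
error profiles, chimeric reads, multi-mapping ambiguity, and
non-uniform fragmentation. Passing tests therefore demonstrate the
correctness of the decision logic under clean mappings, not robustness
to repeat-induced mismapping — on real data the mapping-quality
thresholds are the defense, and they are exercised literally by the
tests.

# Junction validation

A junction is an inter-base coordinate. A read supports it when a
single alignment covers it with at least `min_flank` bases on **both**
sides at `mapq ≥ min_mapq`. The defaults — `min_flank = 100`,
`min_mapq = 60`, `min_spanning_reads = 1` — encode the curation rule of
requiring at least one confidently, uniquely mapped long read
overlapping the junction by a minimum of 100 bp on each side. Long-read
data are unpaired, so "one read" is the coherent unit of evidence;
`min_spanning_reads` is exposed for stricter readings (e.g. 2).

The junction universe defaults to the flanks of every N run (`"gaps"`
mode) plus externally supplied breakpoints (e.g. unverified
collinearity breakpoints); per-base tiling is available but opt-in,
since evaluating every base adds quadratic work without adding power
when support is interval-based.

`split_unsupported()` turns each unsupported junction into a sequence
boundary. Splits falling on one N run are collapsed (with a warning)
into a single cut that removes the whole run; pieces are named
`<old>.1, .2, …` left-to-right, and the log records piece coordinates
and removed gap lengths so the input is reconstructible byte-exactly —
an invariant the test suite asserts on every simulated case.

# Scaffolding

`build_link_graph()` links two contig ends when one read aligns to both
contigs, each alignment reaching within `end_window` (default 1000 bp)
of the respective end, with ends implied by read order and strands. The
implied gap is the unaligned read span between the alignments minus the
contig overhangs; negative values mean overlap. Edges below `min_reads`
(default 1, matching the one-read evidence rule) are dropped.

`filter_links_by_synteny()` removes edges joining contigs anchored to
different reference chromosomes, and same-chromosome edges that skip
over another anchored contig lying strictly between the two anchors.
Edges touching unanchored contigs are kept — the guard gives the
benefit of the doubt, since an unanchored contig is absent evidence,
not contrary evidence. The filter is idempotent.

`linearize_scaffolds()` selects edges greedily by (support descending,
gap-MAD ascending, lexicographic node ids), rejecting any edge whose
contig end is already used or that would close a cycle. This is
deterministic, keeps every contig end at degree ≤ 1, and on conflicts
prefers corroborated, consistent joins while still letting a single
read make an uncontested join. Paths are emitted starting from the
lexicographically smaller terminal; a contig traversed head→tail is
`+`. Gap estimates are the median of the implied gaps, floored at 10 N
when non-positive; joins with median gap ≤ −50 bp are flagged as
overlap candidates for the overlap-joining stage rather than padded
with N.

# Overlap joining

Neighboring contigs in a scaffold sometimes share a large terminal
overlap. Detection is exact 15-mer seeding between the left contig's
terminal `max_search` window (default 20 kb) and the right contig's
prefix window; every seed diagonal proposes an overlap length, and each
candidate is scored by ungapped identity over the full overlap.
Hyper-repetitive seeds (> 10 occurrences in a window) are skipped to
bound the candidate set. The best candidate per pair is reported iff
length ≥ `min_len` (100 bp) and identity ≥ `min_identity` (0.99).
Gapped (banded) extension is deliberately omitted: terminal overlaps
left by assembly consensus are substitution-level artifacts, and an
ungapped evaluation ties the behavior to the two thresholds rather than
to alignment-engine heuristics.

Merging keeps the left contig's bases inside the overlap (no
base-quality model exists to arbitrate) and preserves everything
outside it verbatim, so merged length is always
`len(left) + len(right) − overlap`. Chains are applied left-to-right
with id aliasing; conflicting candidates on a shared end resolve to the
higher-identity, then longer one.

# Synteny

**Chaining** sorts alignments by query position and extends a block
while target sequence and strand match, query and strand-aware target
gaps stay within `max_gap` (default 100 kb), and target order stays
monotone (coordinate overlaps up to 100 bp tolerated). Blocks below
`min_block` (10 kb) are discarded. Defaults are deliberate: 100 kb
bridges alignment breaks inside conserved chromosomes without chaining
across real rearrangements at the 10 kb block scale.

**Anchoring** assigns each scaffold to the chromosome holding a strict
majority (> 50%) of its block-aligned bases; exact ties and blockless
scaffolds stay unplaced rather than being guessed. Order follows the
median block target midpoint; orientation is the aligned-base-weighted
majority strand.

**Collinearity verification** declares a junction verified when at
least one evidence block set spans both flanks — either one block
covering `pos ± min_flank`, or two same-target, same-strand,
order-consistent adjacent blocks with query gap ≤ `max_gap`. Evidence
sets combine by disjunction, so adding evidence can only verify more;
unverified junctions feed back into junction validation as breakpoints.

**Rearrangement counting** defines an event as a *maximal run of
displaced blocks*, not a raw breakpoint: per query chromosome, blocks
aligning off the majority ("home") target chromosome form
inter-chromosomal events (one per maximal run); the remaining sequence
is decomposed into a maximum-cardinality collinear backbone (consistent
strand, monotone target positions; among maximum backbones the one with
fewest complement runs, computed by an O(n²) dynamic program) plus
maximal displaced runs, each one intra-chromosomal event — an
inversion when every block in the run opposes the backbone orientation,
otherwise a transposition. One inversion therefore counts once
regardless of how many blocks it spans, self-comparison yields zero
events, and the tests verify the decomposition against an exhaustive
subset-enumeration oracle on all block permutations up to length six.
The raw breakpoint count is also reported. This counting rule is the
package's own explicit definition; published rearrangement totals
produced by unspecified rules should not be expected to reproduce
exactly.

**Breakpoint profiles** map each breakpoint to
`min(d_start, d_end)/(L/2)` — 0 at a chromosome end, 1 at the center —
and return a normalized histogram, making "rearrangements concentrate
toward chromosome ends" a one-line check.

# Assembly QC

N50/L50 use the standard definitions (shortest sequence in the minimal
covering set / that set's size) and are property-tested against
brute-force enumeration. Telomere detection scans the first and last
`window` bp (default 10 kb) for tandem arrays of the motif or its
reverse complement with ≥ `min_units` copies (default 3), tolerating a
single unit-length interruption between consecutive copies — perfect
arrays are rare in real assemblies, and one skipped unit is the
smallest meaningful tolerance. Detection commutes with reverse
complementation up to swapping end labels and strands.

Linkage concordance infers the group→chromosome correspondence by
majority vote when not supplied (the correspondence is usually
implicit), reports concordance as a percentage rounded to two decimals,
and calls per-chromosome orientation from the sign of the Kendall tau
between genetic and physical marker order (`unknown` below 3 markers or
at tau 0). With 2166 markers of which 4 are discordant the report reads
99.82% / 0.18% — the printed-summary arithmetic the tests pin down.

# Consensus positive-selection calling

Each gene carries four P-values (two codon aligners × gaps
allowed/disallowed). A gene is called when ≥ `min_passing` (default 3)
of its present P-values fall below `alpha` (default 0.05), and is
assigned the **largest passing P-value**. When all four tests pass, the
default `max-passing` rule takes the maximum over all four — the more
conservative reading — with `max-top3` available for the
largest-of-the-three-smallest alternative. Genes with fewer than
`min_passing` non-missing tests cannot satisfy the rule and are
excluded with a log entry. Under the null the consensus type-I error
has the closed form `P(Binomial(4, α) ≥ 3) ≈ 4.81e-4` at α = 0.05;
`consensus_calibration()` reproduces it by simulation and contrasts it
with single-test calling. The four tests are treated as given inputs —
any correction applied inside the upstream branch-site machinery is
upstream's business.

Paralog collapsing implements the ohnolog naming convention narrowly:
two symbols collapse to their common base only when both the `a`- and
`b`-suffixed forms are present, the base is at least 3 characters, and
the base symbol itself is absent from the input. This mirrors the
cyp19a1a/cyp19a1b → cyp19a1 situation while refusing to merge when the
base symbol exists independently; genuinely distinct families that
happen to end in a/b (a known residual risk) can be excluded by
pre-filtering the symbol list.

Enrichment is the exact upper-tail hypergeometric probability
(`stats::phyper`) with BH adjustment across terms; both the raw and
adjusted columns are reported because conventions differ on which one
readers expect. The test suite checks the implementation against an
independent exact rational-arithmetic oracle (big-integer Pascal
triangle) to 1e-12, exhaustively for small backgrounds and by sampling
up to N = 60.

# Numerical and degenerate-input choices

* Empty inputs return empty, well-typed results (empty FASTA, empty
  link graph, empty block list, empty breakpoint profile) rather than
  erroring, except where a statistic is undefined (N50 of an empty set).
* Bin edges are half-open `[e_i, e_{i+1})`; a pair exactly on an edge
  goes to the bin starting there. Classification and binning never drop
  or duplicate a pair — the bucket counts always sum to the input count.
* All percentage-style outputs that echo printed summaries are rounded
  to two decimals; everything else is returned at full precision.
* Greedy tie-breaks (edge selection, backbone choice, conflict
  resolution) are fully deterministic: support, then dispersion, then
  lexicographic ids; `+` orientation preferred on exact backbone ties.

# Problem sizes used by the test suite

The suite validates at scales chosen to make the statistics sharp while
keeping a full run around a minute on one CPU: 2 Mb genomes with 20
planted fusions and 30× 10 kb reads for junction validation; a ~50
contig fragmentation of a 1 Mb chromosome for scaffolding; 10,000
mate pairs; 10⁶ null genes for consensus calibration; exhaustive
oracles up to permutation length 6 (rearrangements) and background 18
(exact hypergeometric), with randomized coverage beyond.

# Known limitations

* The scaffolder emits simple paths only; repeat-induced branching is
  resolved greedily, not by global optimization.
* Overlap detection is ungapped; indel-containing terminal overlaps
  longer than the seed spacing may be missed or under-scored.
* The rearrangement event definition is principled but not canonical;
  counts from other definitions (breakpoint graphs, DCJ distance) will
  differ systematically.
* The simulators' clean-mapping assumption means mapping ambiguity on
  repetitive real genomes is exercised only through the MQ thresholds,
  not emulated.
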