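---
title: "Methods: detecting the structural signatures of duplicon mobilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting the structural signatures of duplicon mobilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and numerical
choices: what each detector assumes, which tunable parameters matter, what
the synthetic-data generator does and does not emulate, and where the design
was genuinely open. It states no empirical result that the test suite does
not itself compute.

## Coordinates and containers

All internal coordinates are 0-based half-open; 1-based formats
(RepeatMasker `.out`, consensus positions) are converted at the boundary.
Genomes are named character vectors of A/C/G/T/N strings; repeat
annotations are plain data frames; trees are `ape` "phylo" objects.
N is legal in genomes but never inside planted features, and N never
matches anything in any comparison — masking a region removes it from
every detector's view.

## TSD detection

`detect_tsd()` searches a `max_window` (default 100 bp) on each side of a
candidate insertion for the highest-scoring pair of near-identical
substrings, one ending near the 5' edge, one starting near the 3' edge.
Score order is length, then mismatches, then distance to the junction —
TSDs abut the insertion by mechanism, so ties break junction-proximal.
Defaults: `min_len = 5`, `max_mismatch_frac = 0.2`, `max_offset = 10`
(how far a copy may sit from the nominated edge). The original analyses do
not state a window or tolerance; these values admit short, diverged TSDs
while keeping the chance-similarity floor manageable, and are not claimed to
match any published caller.

Two caveats are inherent to the problem:

* **Chance flank similarity.** With a 5-mer floor and 20% mismatch
  tolerance, random flanks produce qualifying pairs at an appreciable rate.
  The pipeline therefore only *calls* an L1-mediated insertion when the TSD
  is at least 8 bp (`min_tsd_len`); shorter planted TSDs are undetectable by
  design, which is why the bundled demo and acceptance worlds plant TSDs of
  8–16 bp even though the simulator's API default range is 4–20.
* **polyA ambiguity.** A TSD that begins with adenines is partially absorbed
  into the apparent polyA run of the element. `detect_tsd()` accepts a
  `back_offset` letting the right copy begin before the nominated edge; the
  pipeline sets it to the length of the trailing A-run.

`detect_tsd()` is invariant under reverse complement at the level of
(length, mismatches, junction distance); when two placements of the same
pair tie, the reported copy intervals may legitimately differ between
strands by the tie split.

## Junction characterization

`characterize_junction()` receives the two donor source sequences — the
left donor aligned at the left end of the observed junction string and
extending past the breakpoint in its source locus, the right donor aligned
at the right end and extending back — and computes `k`, the longest common
prefix of observed and left donor, and `r`, the longest common suffix with
the right donor. Microhomology is `k + r - length(observed)` when
non-negative; otherwise the unattributable interior becomes the inserted
sequence, and interior fragments of at least 8 bp mappable to two or more
third-party donors mark the junction complex. Donor sequences play the role
that mapped source loci play in a real analysis; the simulator emits them
in its junction table.

## Breakpoint clustering and the repeat-overlap census

Breakpoints of duplication copies, expressed in ancestral-locus
coordinates, are clustered by single linkage at `tolerance_bp` (default
20 bp; the notion of an "independent breakpoint" is not operationalized in
the source analyses, so the tolerance is a parameter). The cluster
coordinate is the member median. The census assigns each cluster the family
of the annotation containing it under half-open point-in-interval, else
"none".

Duplication copies themselves are mapped by `map_duplication_copies()`:
exact k-mer seeding of each contig against the ancestral sequence, one
candidate per diagonal as the maximum-scoring subarray of the
match/mismatch vector (+1/−3), ends trimmed until the terminal 8 positions
are all matches. The +1/−3 scoring stops extension crisply at homology
boundaries, which is what breakpoint estimation needs; a planted junction
microhomology of m bases extends the apparent match by at most m (≤ 4),
well inside the clustering tolerance. Interspersed repeats shared between
a contig and the ancestral locus would masquerade as short copies, so the
pipeline masks annotated repeats on the genome side first — the standard
repeat-masked comparison.

## Phylogenetic core

`k2p_distance()` implements the closed form
`d = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)` over pairwise non-gap columns and
raises a "saturation" error when an argument of a logarithm is
non-positive. Columns with more than 50% gaps are dropped before distance
computation — the masking surrogate for regions that cannot be aligned,
such as the VNTR core of composite elements. `nj_tree()` is standard
neighbor joining with deterministic tie-breaking by taxon order; negative
branch lengths are clamped to zero with the deficit moved to the sister
edge. The published analyses used maximum likelihood trees; everything this
package consumes from a tree is topological (monophyly patterns), for which
the NJ/K2P surrogate is adequate, and no likelihood values are reported.
`bootstrap_support()` resamples columns (default 10,000 replicates,
matching the published protocol; tests use 1,000), counts bipartitions,
discards saturated replicates, and errors if more than half are discarded.
Zero-length internal edges of the point-estimate tree are collapsed first,
so identical sequences yield a star with an empty support vector.

## Diagnostic sites and the recombination test

`partition_diagnostic_sites()` classifies each column relative to the
outgroup state: group-specific (every member of one group carries one
common derived state, no member of the other group any), shared-derived, or
uninformative. A **shared-derived** call requires the common derived state
in at least `share_min_frac` (default 0.5) of *each* group. This follows the
source analyses' "shared by most/all of the copies": a single parallel
substitution in one member of the other group is homoplasy, and counting it
as shared ancestry collapses the bracketed interval. The outgroup is
expected to be consensus-like (the published outgroup was a consensus of
the parental subgroup plus transduction source); a real, diverged outgroup
sequence would contribute autapomorphic columns that are indistinguishable
from all-member shared-derived columns — a stated limitation.

`locate_recombination_interval()` brackets the crossover between the last
focal-group-specific substitution preceding the first shared-derived
substitution and that first shared substitution. `split_tree_test()` builds
NJ/K2P trees on the columns left and right of the split point (default: the
interval midpoint, echoing the published practice of splitting the interval
approximately in half) and declares **discordance** iff the group-monophyly
pattern differs between the sides; the Robinson–Foulds distance is reported
as auxiliary evidence only, because monophyly is robust to unresolved
nodes while raw RF is not. `segment_concordance_test()` is the
gene-conversion control: downstream segments whose trees match the
3'-reference topology argue against conversion tracts extending through
them.

The power test's simulated world (in the test helpers): 5+5 taxa plus a
consensus-like outgroup on a zero-length branch, two 1,000-bp segments,
stem branches 0.0075 substitutions/site, tips 0.002. These were chosen so
that group stems carry ~7 diagnostic substitutions per segment while
stem-stem parallel homoplasy (the irreducible failure mode of interval
bracketing) stays below a few percent per replicate, and were frozen before
the acceptance assertions were first run.

## Median-joining networks

`build_mj_network()` scores variable, gap-free columns with equal weights
(gap columns excluded by default — the conservative choice where the
source protocol is silent), collapses duplicate haplotypes with
multiplicities, and then minimizes network cost (MST length over the node
set) by steepest descent over candidate medians — the majority-state
vectors of node triplets, all three tie orientations included (the
all-triplet pool equals the classical connected-triplet rule at large
epsilon). When no single median improves the cost, a joint-pair step
evaluates committing a median together with a second median of the
extended set, comparing *pruned* costs so that an earlier median made
obsolete by the pair is allowed to drop — some Steiner backbones only pay
off jointly. Pruning always removes the obsolete median whose removal
yields the smallest cost first (a detour node, never a load-bearing one)
and runs to a fixpoint. At `epsilon = 0` the retained edge set is the
minimum spanning network, which always contains an MST of the observed
haplotypes.

Median joining is a heuristic with no general optimality guarantee; the
joint-pair refinement exists because plain greedy median addition provably
stalls one mutation short on instances whose optimum needs two medians
committed together. Measured against an exact Steiner-tree oracle
(Dreyfus–Wagner dynamic programming over the median closure, an
independent algorithm): the builder attained the Steiner optimum in
300/300 genealogy-generated instances — the regime the tool targets, since
the networks it builds are copy genealogies — and 100/100 uniform-random
binary instances (near-maximal spread). The acceptance criterion draws its
random instances from random genealogies with occasional recurrent
mutation; a separate property bounds the cost between the Steiner optimum
and the observed MST on uniform-random strings.

`root_network()` attaches the outgroup to the closest node by Hamming
distance; the root edge is flagged not-to-scale in exports (only the path
to the root is unscaled, mirroring the usual drawing convention), and ties
are reported with a deterministic lowest-id choice.

## Chimera segmentation and the circular-intermediate signature

`segment_by_subfamily()` classifies an element using diagnostic sites only
— not windowed similarity — because subfamily affiliation is diagnosed
that way in practice and diagnostic sites are robust inside the unalignable
VNTR (excluded from scoring by default). Maximal runs of same-state sites
become segments; runs under `min_support = 3` sites merge into neighbours
(below that, mosaic calls are noise); the switch point is the midpoint of
the flanking diagnostic sites, so its localization error is bounded by the
local inter-site gap by construction.

`detect_circular_signature()` requires reciprocal subfamily orders in the
two flanking chimeras (compared in genome orientation — minus-strand
elements are flipped back, so the call is invariant under reverse
complement of the locus), an outer TSD pair flanking the whole cassette,
and an inner TSD pair bordering the interior segment; one missing TSD pair
degrades the verdict to "partial", anything less is "negative".

## Direct-repeat flank scanner

On each candidate diagonal d of a contig-vs-itself comparison, the scanner
takes the maximum-scoring subarray of the match vector (+1 match, −3
mismatch; first-maximum tie-break), trims both ends until their terminal 8
positions are all matches, and reports the pair if the trimmed length is at
least `min_len` (default 1,000 — the SD definition), identity at least
`min_identity` (default 0.9), the copies do not overlap, and the insert is
at most `max_insert`. One candidate per diagonal; overlapping candidates
across diagonals merge to the best by identity, then length. Only diagonals
holding an exact 16-mer seed are visited — a reportable pair (≥1 kb at
≥90% identity) contains such a seed with near certainty. The published
screen was visual with no stated thresholds; these defaults follow the SD
definition and are not claimed to replicate it. `scan_windows()` applies
the scanner in nonoverlapping 0.5 Mb windows with a seam margin, the
classical screening granularity. The predicted NAHR product of a hit is a
single chimeric repeat copy with the insert removed — its length equals the
repeat length by construction.

## The synthetic world

`simulate_genome()` emits: an ancestral-locus contig (40 kb) carrying a
20 kb core duplicon with a real composite element + 3' transduction at its
3' end and annotated Alu/processed-pseudogene features; one contig of
spaced L1-mediated insertions; one contig per duplication copy (so
near-identical copies never share a contig, and the flank scanner cannot
pair them); cassette contigs; and direct-repeat-SD contigs. Substitutions
are per-site i.i.d. with transitions weighted `kappa`:1 (default 2), no
indels outside junction features, so every ledger coordinate is exact.
Junction signatures are realized exactly by constructing donor
continuation/pre-context sequences with guard bases that block longer
overlaps; the two junction types (microhomology from the 1–4 nt default
range; inserted nucleotide runs) alternate deterministically across planted
events. Defaults state the modeled regime: 20 kb core, ~4 kb direct-repeat
flanks at identity ≥ 0.9, polyA 8–30 nt, 12-bp cassette TSDs, mandatory
seed.

What the generator does **not** emulate: realistic chromosome composition
or GC landscape, indel evolution, nested/overlapping insertions, truncation
hotspots, or retrotransposition biochemistry. A green recovery test
establishes that the detectors invert the generator's planted structures
under neutral point divergence — not that they would perform identically on
assembled primate genomes, where alignment artifacts, indels and
assembly collapse add failure modes this world does not contain.

## Determinism

Every source of randomness flows from the mandatory config seed; outputs
contain no timestamps; two runs of the bundled demo config produce
byte-identical bundles (hash-compared in the tests). The run manifest
(package version, seed, full config) suffices to replay a run.
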