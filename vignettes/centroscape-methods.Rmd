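---
title: "Methods: centromere and pericentromere repeat landscapes with centroscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: centromere and pericentromere repeat landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package computes

Plant centromeres are megabase-scale domains of tandem satellite repeats
heavily invaded by LTR retrotransposons; the flanking pericentromeric
heterochromatin carries its own satellites and an older transposon
population. `centroscape` implements the computational core of a
centromere/pericentromere landscape analysis:

1. **Probe density tracks** — satellite monomers ("probes") with roles
   centromeric, pericentromeric or telomeric are aligned to the assembly
   and summarised as sliding-window covered-bp fractions (default 500 kb
   windows, 100 kb step).
2. **Compartment calling** — dense windows are merged into explicit
   centromere and pericentromere interval calls.
3. **LTR chronology** — each full-length LTR retrotransposon (FL-LTR-RT)
   is dated from the divergence of its two long terminal repeats, which
   are identical at insertion: `T = K / (2*mu)` with `K` the
   model-corrected substitutions per site and `mu` the substitution rate
   per site per year. Elements with `T <= 0.5` MYA are "young". Nested
   insertions are detected by strict span containment.
4. **Identity landscape** — pairwise sequence identity between all
   non-overlapping 10 kb bins of a region, plus a change-point
   segmentation of the resulting block structure.
5. **Repeat discovery** — an occurrence filter that finds novel repeat
   units: all-vs-all alignment of pericentromeric element sequences,
   keep units occurring in at least 50 elements, keep those with more
   than 1000 merged hits on the pericentromere, drop units similar to
   known satellites.

Every stage is exercised end-to-end on a synthetic chromosome simulator
that plants all of these features with recorded ground truth.

## The substitution and dating model

`mutate_sequence(seq, K)` substitutes each site with probability
$\tfrac{3}{4}\!\left(1 - e^{-4K/3}\right)$, choosing uniformly among the
three alternative bases. This is exactly the Jukes–Cantor transition
matrix at branch length $K$, so two copies mutated independently with
branch $K$ diverge as one JC branch of $2K$ — which is precisely the
assumption the dating step inverts. The simulator introduces no indels:
divergence-based dating is then exactly invertible, and gap handling is
an aligner concern tested separately against dynamic-programming oracles.

Dating an element:

```{r}
elements <- read_ltr_annotations("elements.gff3", genome)
elements <- estimate_age(elements, genome, mu = 1.5e-8, model = "JC69")
```

aligns the 5′ and 3′ LTR copies with a banded global alignment, takes
the observed mismatch fraction over match/mismatch columns only (gap
columns are excluded — a substitution clock should not count indel
columns), corrects it with JC69
($K = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$) or K2P, and converts to MYA.
Divergences at or beyond the model's domain ($p \ge 0.75$ for JC69) are
flagged unreliable and excluded from all summaries. `mu` defaults to
$1.5\times10^{-8}$ substitutions/site/year — a community-standard
Brassicaceae rate — and is stamped into every output; it is a parameter,
not a constant, because upstream sources for this procedure do not print
the value they used.

**Precision limits.** Over an LTR alignment of $L$ columns the observed
mismatch fraction is binomial, so the age estimate has standard
deviation $\approx \sqrt{p(1-p)/L}\,/(2\mu)$ after correction. For 1 kb
LTRs this is ~0.18 MYA at a true age of 1 MYA and ~0.27 MYA at 2 MYA;
the expected mean absolute error for ages uniform on (0, 2) MYA is
0.14 MYA. Parameter-recovery tests therefore check correlation,
near-unbiasedness, and an MAE consistent with this floor — no estimator
of LTR-pair divergence can beat it. Per-compartment *mean* ages are much
better determined (the noise averages out), but means of populations
near zero age are inflated slightly because estimated ages cannot be
negative.

## Alignment primitives

`local_align()` is a seed-and-extend local aligner: exact k-mer seeds
(default k = 13) chained by diagonal, banded affine-gap Smith–Waterman
extension around each chain, overlapping hits merged to the
highest-scoring. Scoring defaults to match +1, mismatch −2, gap open 3,
gap extension 1. The (identity, length) hit thresholds are the package's
analog of a BLAST e-value cutoff; e-value statistics depend on
database-size models that are irrelevant on synthetic tests and are not
computed. `N` never matches anything, including itself, so gap
placeholders cannot seed or extend hits. On planted-homology instances
the aligner returns the same score as an exhaustive Smith–Waterman
oracle; equal-scoring optima may differ by a few tie-broken edge
columns, which is the tolerance the oracle tests use.

`global_identity()` is a banded Needleman–Wunsch; identity is matches
over all alignment columns (gaps count as columns), and the band must
cover the length difference or the call fails rather than silently
truncating. Probe mapping (`map_probes()`) lowers the seed to k = 11:
at the 0.8 identity threshold a 176 bp monomer at ~13% observed
divergence has a ~3% chance of containing no exact 13-mer, which would
cap copy recall below the advertised 95%; with k = 11 the seed-miss
probability is under 1%.

## Compartment calling

Probe signal is summarised as covered-bp fraction per window — not hit
counts, which tandem-array fragmentation would inflate — with
overlapping hits unioned first. `call_regions()` makes the boundary
criterion fully explicit, because published centromere interval tables
generally do not state one: windows at density ≥ `threshold` (0.1) form
runs, runs separated by ≤ `merge_gap` (2) below-threshold windows are
merged (this also controls whether embedded satellite-free gaps stay
inside a call), runs shorter than `min_run` (2) windows are dropped, and
boundaries snap to the outermost probe-hit endpoints inside the run, so
the call has hit-level rather than window-level resolution. All three
parameters are stamped into a JSON sidecar next to every BED output.
Pericentromere calls come from the pericentromeric track only and are
trimmed to the portions flanking (not inside) the centromere call.
Elements are assigned to compartments by the midpoint rule — the only
unambiguous choice for elements straddling a boundary — with centromere
taking precedence on overlap.

## Identity landscape

`identity_matrix()` cuts a region into non-overlapping bins (default
10 kb; the trailing partial bin is dropped rather than padded), aligns
every bin pair with the banded global aligner (band 10% of the bin), and
returns the symmetric identity matrix. Bins are compared on the forward
strand; a reverse-complement-aware mode exists but defaults off and is
recorded in the object. A k-mer containment estimate
(`method = "kmer"`) is available for large regions and is always
labelled an estimate. `segment_blocks()` is a deliberately minimal
recursive change-point heuristic — published heatmap region labels are
assigned by eye, so this is an interpretive aid, not a reproduced
algorithm: a segment splits at the boundary maximising the
within-minus-between mean identity gap whenever that gap exceeds `cut`
(0.1).

## Repeat discovery

`self_cluster()` aligns every element pair on both strands (a shared
k-mer prescreen skips strand/pairs with no common seed material), then
single-linkage clusters the hit intervals: the two intervals of a hit
are linked, and intervals on the same element are linked at ≥ 50%
reciprocal overlap. A cluster's `self_occurrences` is the number of
distinct element records it touches — deliberately per record, so
duplicated inputs double the count. The representative is the
highest-scoring interval of the cluster's typical (median) length,
which keeps occasional fused intervals (a unit plus shared flanking
sequence from same-family pairs) from standing in for the unit.

`filter_candidates()` applies the two occurrence rules: keep clusters
with `self_occurrences >= 50` (the boundary value 50 is kept — the
filter is described in two conflicting ways at exactly 50 in its source
analysis, and the "fewer than 50 are removed" reading is used; the
threshold is configurable), then count hits of survivors on the
pericentromere sequences and keep those with **strictly more than**
1000. Hits are merged per target before counting so tandem staircase
alignments count once; raw-hit counting would report different absolute
numbers on arrays. Candidates contained (≥ 80% of their length) in a
longer candidate are absorbed. `filter_known()` drops candidates with
≥ 50% identity over ≥ 100 bp against known satellite probes, using
mismatch-tolerant but gap-expensive scoring (match +1, mismatch −1, gap
open 6, extension 3): the default scoring cannot extend through ~60%
identity homology at all, while cheap gaps would manufacture spurious
50%-identity pseudo-matches between random sequences.

## The simulator and what it does (not) emulate

`simulate_chromosome(sim_config(...))` builds
telomere–arm–pericentromere–centromere–pericentromere–arm–telomere.
Defaults (the package's study conditions): a 3 Mb chromosome, 3 kb
TTTAGGG telomeres, a 500 kb centromere tiled from a 176 bp monomer, two
300 kb pericentromeres tiled from 238 bp and 1022 bp monomers with a
630 bp hidden repeat (300 dispersed copies, 20 embedded in elements),
satellite copies at per-copy divergence K = 0.02 (this produces the
block-like identity heatmaps without modelling higher-order repeat
structure), arm background i.i.d. at GC 0.36 (the simplest null that
still exercises probe false positives), and compartment insertion ages
drawn from normals truncated at zero — mean (sd) 0.14 (0.15) MYA in the
centromere, 0.51 (0.15) in the pericentromere, 0.32 (0.15) on arms,
matching the compartment means the analysis is designed to resolve;
only means are published for the real populations, so the common sd is
a package choice. Compartment spans are final region sizes: satellite
cores shrink to absorb the planted elements, so layouts are exactly
conserved. 10% of elements nest inside an earlier element of the same
compartment; a nested child's age is truncated at its parent's so
planted chronology is self-consistent. `discovery_config()` scales the
pericentromeres to 2 × 750 kb with 80 elements in four families of 20
and the hidden repeat at 1200 dispersed + 60 embedded copies, so the
planted unit passes the 50/1000 filters while no LTR family does.
Monomer and family sequences are generated from the seed; they make no
claim of sequence fidelity to real satellites (the real monomer
sequences are not printed in the source analysis), only of structural
fidelity. Fixed seed implies byte-identical FASTA and truth tables.

Not emulated: reads, assembly error, Hi-C, genes and expression,
methylation, target-site duplications, higher-order satellite
structure, and indel mutation. Passing tests therefore demonstrate that
the pipeline inverts its own generative model and honours its filters'
semantics — not that it would segment a real assembly identically to
annotation pipelines built on LTR_retriever/EDTA output. The simplified
structural LTR finder (`find_ltr_elements()`: exact-repeat anchor pairs
trimmed to TG…CA) exists so annotation-free synthetic runs work; it
uses no target-site or protein-domain evidence and is explicitly not
equivalent to LTR_retriever. Pipelines on real data should supply a
GFF3.

## Statistics

Compartment age contrasts use Welch's unequal-variance two-sample t-test
with two-sided p (pooled-variance available as an option); with zero
variance in both groups and equal means, t = 0 and p = 1 by convention.
No multiple-testing correction is applied across the small fixed set of
compartment contrasts, and the report footnotes say so. The Welch p is
cross-checked against a permutation oracle in the test suite.
`coverage_fraction()` merges features, intersects with regions and
divides covered bp by region bp; it is tested for exact agreement with
a per-base oracle.

## Problem sizes and determinism

The shipped analyses and tests run on desk-scale problems chosen to
exercise every code path: 3 Mb chromosomes with ~100 elements for
boundary recovery and nesting (20 replicates), 2.8 Mb discovery genomes
(20 planted + 20 null), 200 elements for dating recovery, 60 kb
two-monomer regions for heatmap segmentation (20 seeds), and 100-seed
power checks for the compartment contrast. All randomness flows from
explicit integer seeds; identical configuration implies identical
output bytes. `scripts/acceptance.R --seed S --out f.json` recomputes
the headline quantities from scratch at any seed.

## Known limitations

* Dating precision is bounded by LTR length as derived above; ages of
  individual young elements carry ~0.1 MYA noise and truncation at zero
  inflates means of very young populations (observed: a population
  planted at mean 0.14 MYA is estimated near 0.17).
* `self_cluster()` is quadratic in element count; it is sized for the
  hundreds-of-elements scale of pericentromeric element sets, not for
  whole-genome TE libraries.
* The change-point segmentation is a labelling aid; it recovers planted
  two-block structure reliably but has no significance model.
* BLAST e-values are not reproduced anywhere; thresholds are (identity,
  length) pairs.
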