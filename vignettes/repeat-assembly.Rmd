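---
title: "Assembling repeat consensus sequences from raw reads: methods and design"
author: "repforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling repeat consensus sequences from raw reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repforge)
```

## The problem

Transposable elements and satellites make up a large fraction of most
eukaryotic genomes, yet the reference assemblies those genomes are annotated
against are weakest exactly where repeat content is highest. `repforge`
reconstructs the *consensus sequence* of high-copy, low-divergence repeat
families directly from raw paired-end shotgun reads, with no reference
genome and no curated repeat library. Its target regime is families with
tens to thousands of near-identical genomic copies — recently expanded
repeats — not ancient, highly diverged ones.

## The method

The pipeline has three phases.

**1. Frequent k-mers to raw contigs.** Every window of k consecutive non-`N`
bases in every read is counted (canonically: a window and its reverse
complement are one k-mer, since shotgun reads sample both strands). A k-mer
is *frequent* when its count strictly exceeds `freq_cutoff_factor` (default
10) times the average k-mer frequency — the mean count over distinct
observed k-mers. A single-copy locus sequenced at depth $d$ contributes
roughly $d\,(L - k + 1)/L$ to the count of each of its k-mers ($L$ the read
length), so a family with $c$ identical copies pushes its k-mers to about
$c$ times that — far above any sensible cutoff once $c$ is in the tens.

Frequent k-mers are then partitioned into overlapping *frequency bins*
before assembly: targets form a geometric ladder starting at the highest
observed frequent count and halving each step (`bin_ratio = 2`), and the bin
at target $f$ spans $[0.2f, 5f]$. K-mers of one family have similar counts,
so binning separates co-frequent families and reduces chimeric joins; the
25-fold width of each bin against the 2-fold ladder step makes consecutive
bins overlap, so no frequent k-mer falls between bins. Each bin is assembled
by a unitig-only de Bruijn assembler — nodes are (k−1)-mers, member k-mers
are edges, and every maximal non-branching path is spelled out. Because the
inputs are exact k-mers rather than error-bearing reads, nothing more than
unitig spelling is needed, and lexicographic traversal order makes the
output byte-reproducible. The procedure runs for each of several k-mer
lengths (default 29, 39, 49: shorter k tolerates internal variation, longer
k resolves ambiguity), and the combined contig list is deduplicated —
a contig whose sequence or reverse complement lies inside another is
removed.

**2. Raw contigs to long repeats.** Raw contigs are usually *fragments* of
a full consensus: wherever within-family divergence rises, k-mer counts dip
below the frequent cutoff and the de Bruijn graph breaks. The second phase
rejoins the fragments through a directed contig graph. An edge $v_1 \to
v_2$ requires (i) a suffix–prefix overlap of at least `min_overlap_bp`
(15 bp) with a mismatch fraction — substitutions plus indels, from
edit-distance DP — strictly below `max_mismatch_rate` (5%), and (ii) when
the insert size makes a straddling read pair geometrically possible in the
tentative merged layout, at least `min_read_pair_support` (1) read pair
with one mate on each contig, in forward–reverse orientation, spanning
within `insert_size_mean ± 3 sd`. Candidate pairs are prefiltered by an
exact shared substring of `k0 = 5` bases; any 15 bp overlap at under 5%
mismatches contains an exact common 5-mer (pigeonhole over at most
$\lfloor 15 \times 0.05 \rfloor$ mismatch positions), so the prefilter
loses nothing. Cycles are handled by contracting strongly connected
components; the condensation is acyclic, each component is linearly ordered
by Kahn's algorithm with deterministic tie-breaks, and greedy walks follow
the order — preferring the out-edge to the nearest subsequent node — from
every in-degree-zero node, plus one walk per still-uncovered node. Paths
that are contiguous subsequences of other paths are dropped; each maximal
path is concatenated into one repeat, keeping the predecessor's bases in
mismatching junction columns.

**3. Coverage validation.** Reads are re-mapped to the contigs (and again
to the merged repeats) by a seed-and-extend mapper: exact 20 bp seeds from a
substring index, local-alignment extension, all placements reported, a
placement kept when its aligned span covers at least a seed length at no
more than 6% edits. A contig whose mean per-base coverage falls below
`min_avg_coverage` (2) is discarded as mis-assembled; a contig with uneven
coverage is truncated to its maximal runs of positions at or above that
depth, provided a run is at least as long as the largest assembly k-mer
(so truncation cannot emit fragments shorter than the assembly scale).

**Evaluation.** Against a reference library, the package reports the
matching ratio (aligned query span over query length, best local alignment
on either strand, match +1 / mismatch −2 / gap −2.5), the number of library
entries hit at the cutoff `t_L` (0.85), the mean coverage of hit entries by
an optimal non-overlapping set of matched repeats, the mean coverage by the
single longest match, and the N50 of the assembly.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `kmer_lengths` | 29, 39, 49 | bases | short k is robust to variation, long k to ambiguity; the union of all three is deduplicated |
| `freq_cutoff_factor` | 10 | × average k-mer frequency | separates repeat k-mers (∝ copy number × depth) from single-copy and error k-mers |
| `bin_low_factor`, `bin_high_factor` | 0.2, 5 | × target frequency | a bin must hold a family despite Poisson spread of counts |
| `bin_ratio` | 2 | — | ladder step; must stay below 25 (= 5/0.2) so bins overlap |
| `min_overlap_bp` | 15 | bases | below this, suffix–prefix overlaps arise by chance too often |
| `max_mismatch_rate` | 0.05 | fraction | junction regions of true neighbours rarely match exactly |
| `prefilter_substring_len` | 5 | bases | lossless speed-up of the all-pairs alignment |
| `min_read_pair_support` | 1 | pairs | existence of straddling pairs, when expected, confirms adjacency |
| `min_avg_coverage` | 2 | × | contigs real reads never touch are artefacts |
| `matching_cutoff` | 0.85 | fraction | a hit must cover most of the library entry |

## Design decisions

Several points are genuinely open in this kind of pipeline; the choices
made here, and why:

* **Canonical k-mers.** Reads sample both strands, so counting is
  strand-collapsed by default; `canonical = FALSE` exists for strand-aware
  tests.
* **Average k-mer frequency baseline.** The default is the mean count over
  distinct observed k-mers. An alternative reading — the typical count of a
  single-copy k-mer, i.e. a read-depth proxy — is available as
  `freq_baseline = "depth-estimate"` (median count of k-mers seen at least
  twice, since singletons are dominated by sequencing errors). The two
  differ when error k-mers inflate the distinct count.
* **Strict cutoff.** "Over the cutoff" is a strict inequality; a count
  exactly at the cutoff is not frequent. This makes boundary behaviour
  deterministic and testable.
* **Geometric bin ladder.** Bin targets halve each step. An evenly spaced
  (arithmetic) ladder is the natural alternative; the geometric ladder keeps
  the number of bins logarithmic in the dynamic range of counts, which suits
  copy numbers spanning orders of magnitude.
* **Overlap selection.** Among qualifying suffix–prefix overlaps the one
  with the *lowest edit fraction* wins, longest among ties — not the
  longest overall. The longest qualifying overlap at an exact 30 bp
  junction is 31 bp with one spurious indel (1/31 < 5%), which would delete
  one base at every clean junction of a merged repeat; selecting by edit
  fraction recovers the exact junction and preserves exact reconstruction
  of zero-divergence plantings.
* **Containment.** A contig lying entirely within another at under 5%
  divergence is discarded rather than linked — it is the same sequence, not
  a neighbour.
* **Orientation.** Repeats occur on both strands, so overlaps are tested in
  both orientations and each connected component is two-coloured by BFS;
  contigs coloured "minus" are flipped before edges are finalised, and
  parity-violating overlaps are dropped with a warning.
* **Insert-size window.** "Expected given the insert size" is made concrete
  as mean ± 3 sd, the conventional window; straddling is *expected* only
  when a fragment in that window can place one full mate on each side of
  the junction in the merged layout.
* **Soft-clipped mapping.** The mapper accepts partial placements (aligned
  span ≥ seed length). This matters for junction support inside divergent
  blocks: an 8%-divergent read cannot map full-length under a 6% error cap,
  but its conserved stretch still anchors a mate to the right contig.
* **Junction bases.** In a mismatching junction column the predecessor's
  base is kept — deterministic and simple; with coverage recorded per
  contig a coverage-weighted choice would also be defensible.
* **Walk starts.** Greedy walks start at all in-degree-zero nodes; any node
  still uncovered then starts its own walk. This guarantees every contig
  appears in at least one path, at the cost of some short paths that the
  sub-path filter usually removes.
* **Exact interval scheduling.** The optimal non-overlapping coverage of a
  library entry is computed exactly by weighted interval scheduling; a
  pure greedy by length can be suboptimal and the DP is equally simple.
* **Coordinates.** All interval coordinates in the package are 1-based
  closed, the R/IRanges convention.
* **Replacing external tools.** K-mer counting, raw-contig assembly, read
  mapping and local alignment are all in-package (hash counting, unitig
  spelling, seed-and-extend, Smith–Waterman via Biostrings), so the whole
  pipeline runs with no external binaries and is deterministic given
  `rng_seed`.

## The synthetic-data generator

`generate_genome()` plants repeat families in an i.i.d. uniform background:
each family draws a random consensus, mutates every copy independently
(per-base substitutions, per-base single-base indels, optionally a per-base
divergence profile to emulate a diverged internal block), and places copies
at non-overlapping uniform positions on random strands. `simulate_reads()`
produces `round(depth × genome / (2 × read_length))` pairs with normal
fragment lengths and i.i.d. substitution errors, recording every fragment
position and every error position.

What this emulates: the k-mer frequency structure of high-copy families,
insert-size geometry, base-calling errors, strand symmetry. What it does
not: GC bias, quality decay along reads, indel sequencing errors, nested or
truncated insertions, target-site duplications, tandem higher-order
structure. Tests passing on these simulations therefore demonstrate the
algorithmics — selection, binning, assembly, merging, filtering — under the
method's stated regime, not robustness to every artefact of real libraries.

## Calibration of the divergent-block scenario

One test scenario plants a 1.2 kb family whose middle 150 bp diverges at 8%
while the flanks stay at 0.5%, the regime in which raw contigs are
fragments and only graph merging recovers the full consensus. The copy
number controls which side of the frequent cutoff the middle block falls
on: a consensus 29-mer inside the block survives unmutated in a copy with
probability $0.92^{29} \approx 0.089$, so with $c$ copies its count is
about $0.089\,c \times 7.2$ against a cutoff of roughly 40–50 in a 400 kb
genome at 10×. At 130 copies the flanks sit far above the cutoff, the
middle block straddles it — fragmenting the raw contigs — and the dropout
runs are narrow enough (≤ ~9 consecutive k-mer positions) that adjacent
fragments still overlap by ≥ 15 bp and chain through the graph. This is the
calibrated demonstration regime; at some seeds a dropout run wider than
$k - 1 - 15 = 13$ positions appears and the family is recovered only
partially, which is the honest boundary of the method.

## Problem sizes and numerical conventions

The shipped tests run whole-pipeline checks on 50–400 kb genomes at 10×
(2 × 100 bp), sizes chosen so the full suite completes in about a minute
while every stage operates in its intended regime; the acceptance script
uses a 600 kb genome with five families. All randomised steps are seeded;
identical seeds give byte-identical output. Ties everywhere (unitig
traversal, component numbering, Kahn candidates, walk successors, output
ordering) break lexicographically. Degenerate inputs (empty catalogs, empty
frequent sets, empty repeat lists, empty read sets) return empty results or
raise classed errors (`degenerate_input_error`, `capacity_error`, …) rather
than failing obscurely.

## Known limitations

In-memory hash counting bounds practical input size (whole-genome
resequencing data would need an external counter via the k-mer table
import). The all-pairs overlap DP is quadratic per pair and the path search
is heuristic — maximal paths are not guaranteed optimal, matching the
method's design. Evaluation alignment scores approximate megablast-style
scoring, so matched intervals need not be identical to those of an external
search tool. Consensus sequences are single sequences: within-family
variation is collapsed, and families below the frequent cutoff (low copy
number or high divergence) are invisible by construction.

## A minimal run

```{r example, eval = FALSE}
truth <- generate_genome(50000,
                         list(repeat_family(500, 40, divergence = 0.01,
                                            indel_rate = 0.002)), seed = 42)
sim <- simulate_reads(truth, depth = 10, read_length = 100,
                      insert_mean = 300, insert_sd = 30, error_rate = 0.005,
                      seed = 43)
res <- assemble_repeats(sim$reads, pipeline_config())
evaluate_repeats(res$repeats, truth$consensi, pipeline_config())
```
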