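---
title: "Methods: surveying local repeats with locrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying local repeats with locrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `locrep`. It is the place where design decisions that
were genuinely open are argued; the README shows the user-facing workflow.

## The objects of study

A **local repeat (LR)** is a sequence family whose copies recur multiple
times, discontinuously, within one genomic locus and rarely or never
elsewhere. A **tandem repeat (TR)** is a motif repeated adjacently (period
= motif length). **Transposable elements (TEs)** are interspersed
genome-wide repeats; they are masked before discovery because they are
neither LRs nor TRs. The prototypical LR host is the X-linked *FIRRE*
lncRNA locus: 13 repeat families of roughly 100–750 bp (median ≈ 167 bp)
at 3–40 copies each (median ≈ 12), mostly intronic, with lncRNA loci in
general carrying several-fold more LRs per kb than protein-coding loci.

## Coordinates and containers

Intervals live in `GRanges` (1-based, closed), the native convention of
the Bioconductor stack; conversion to and from the 0-based half-open BED
convention and the 1-based closed GTF convention happens only at the I/O
boundary (via `rtracklayer`), so round-trips are exact and no other code
ever adjusts coordinates. Sequences are `DNAStringSet`s restricted to
`{A,C,G,T,N}`; anything else is replaced by N with a warning at read time.

## De novo discovery

Discovery follows the classic seed-and-extend design: all exact k-mers
(default `k = 16`) are enumerated, forward and reverse-complement
occurrences pooled under the lexicographically smaller of a k-mer and its
reverse complement, and k-mers with at least `min_count` (default 3)
occurrences become seeds, processed in descending occurrence order.

**Extension.** From the seed, a consensus is grown one column at a time,
leftward then rightward. Each column's consensus base is the majority base
over the live copies (ties alphabetical, for determinism), and the column
contributes `n_agree − w · n_disagree` to a running sum; extension in a
direction stops when that sum falls more than `x_drop` (default 20) below
its running maximum, and the consensus is trimmed to the maximum-scoring
extent. A copy whose identity to the accepted consensus extent falls below
`min_identity` (default 0.8) leaves the live set permanently.

The disagreement weight `w = 3` deserves a note. An unweighted
agree-minus-disagree column score is not usable as a stopping signal: over
random flanking sequence, the expected maximum multiplicity of `n` copies
across 4 bases gives an expected score of `2·E[max] − n`, which is +0.375
per column for 3 copies and −0.04 for 5 — i.e. the running sum drifts
sideways or upward in random sequence and the X-drop rule never fires,
while the identity filter then erodes every copy. Any `w ≥ 2` restores a
strictly negative drift at all copy numbers; `w = 3` matches the
mismatch/match penalty ratio conventional in repeat-alignment scoring.
Extension is gapless by design — it keeps the stage deterministic and
O(copies × length) — so the simulator's default repeat families diverge by
substitutions only; single-base indels are supported by the mutator
(`mutate_copy()`) but a copy with an internal indel will be truncated at
the frame shift and recovered instead by consensus re-mapping (below).

**Tombstoning and re-mapping.** Genome positions claimed by an accepted
family are tombstoned so later seeds cannot re-discover the same element.
Because divergence destroys individual seed k-mers (a copy at divergence
`d` retains a given 16-mer with probability `(1−d)^16` ≈ 0.19 at d = 0.10),
the seed's occurrence list systematically underestimates the copy set. The
accepted consensus is therefore immediately re-mapped genome-wide
(`map_consensus()`) and the mapped hits become the family's instances and
claims. This mirrors standard practice (a de novo consensus library is
mapped back over the genome to enumerate instances) and is what prevents
fragment families.

**Objective.** Each family records `Σ per-copy (matches − mismatches) −
c·L` with `c = 2`, a fit-preferred-style penalty discouraging consensus
over-extension.

## Tandem detection and routing

For each lag `p` in `[1, max_period]` (default 2000 bp, spanning
microsatellites up to the LR length scale), the sequence is compared with
itself shifted by `p`; maximal segments with match purity ≥ `purity_min`
(default 0.8) and length ≥ `max(2p, 8)` bp are tandem arrays. Segments are
grown from long perfect runs by best-first absorption of neighbouring
runs, which keeps calls invariant under sequence reversal. Harmonics (a
true period-p array also matches at lags 2p, 3p, …) are resolved in favour
of the smallest period whose purity is within 0.05 of the group's best.
Note that thresholds this permissive genuinely call micro-tandems in
random sequence (a 9-bp period-3 repeat arises by chance every few kb);
these short calls are harmless downstream because routing is mass-based.

A discovered family is routed to the TR catalogue when ≥ 50% of its
instance base pairs lie inside tandem arrays, or when its instances are
adjacent (gap ≤ 10 bp) in at least half of consecutive pairs; every family
lands in exactly one catalogue. The thresholds are package choices — the
upstream literature states only that TRs were removed from the de novo
set.

## Locality classification

`map_consensus()` performs a seed (12-mer) and local-alignment search on
both strands (match +1, mismatch −1, gap open 4, gap extend 1), reporting
hits with identity ≥ 0.7 covering ≥ 50% of the consensus; within a
candidate window the best local alignment is masked and the window
realigned, so adjacent copies are resolved separately.

`classify_locality()` counts an instance inside a locus when ≥ 50% of its
bases overlap the gene span — introns included, since LRs are
predominantly intronic — and calls the family **LOCAL** when the fraction
of instances in the best single host reaches `locality_min = 0.8`. The 80%
threshold is promoted from the empirical summary that at least 80% of
*FIRRE*'s LR instances fall within the locus; no other operational cutoff
is available. Outside instances carry two descriptive diagnostics —
shorter than the in-locus median, and nearest-outside-neighbour distance
(flagged above 250 kb) — which are recorded but never veto a LOCAL call,
matching their descriptive role in the source analyses.

Per-gene burdens count instances (not families) of hosted LOCAL families,
normalized per kb of gene span; a `count = "families"` switch is provided
because the per-gene unit is ambiguous in the source analyses.

## Burden statistics

Gene classes are compared after decile length-matching on the pooled
log10-length distribution (equal numbers drawn per bin without
replacement; a rank-sum check on the matched lengths warns below p =
0.05). Null ensembles place windows with the original width multiset
uniformly (non-overlapping within a permutation; permutation `i` reseeded
`seed + i`), the intergenic mode rejecting any window that overlaps the
complete gene annotation. Windows are placed widest-first, which keeps
placement feasible when the intergenic space is fragmented. Comparisons
use the two-sided Mann–Whitney U test (`stats::wilcox.test`, tie-corrected
normal approximation); the bespoke content is the sampling and null
construction around it.

## ChIP enrichment with multi-mapping reads

Reads aligning to `n` locations are weighted `1/n` at each; when an
aligner reports more than `cap = 20` records for a read, the best 20 by
alignment score are kept (ties broken by coordinate) and `n` reset to the
kept count — so every read contributes total weight exactly 1. Coverage is
mean weighted depth over the region union, scaled to per-million weighted
reads; the normalization (not stated in the upstream method) prevents
unequal library depths from masquerading as enrichment. Enrichment is
`(chip + ε)/(input + ε)` with pseudocount `ε = 0.1` per-million units,
bounding the ratio under zero input without touching real signal.

Significance: 100 random region sets with the observed width multiset are
drawn genome-wide excluding N-masked bases (masked bases can carry no
alignments and would deflate the null), each scored identically; their
mean is the rate λ of a Poisson null, and the p-value is
`P(X ≥ ⌈observed⌉)` for `X ~ Poisson(λ)`. Applying a discrete null to a
continuous ratio is conservative; the ceiling makes the tail well-defined.
λ is estimated from enrichment scores (not raw counts), following the
stated averaging of permutation enrichment scores.

The read simulator plants alignment records directly: a read is reported
at every candidate position (the corresponding offset in every family
copy) within one mismatch, so reads from near-identical copies emerge
multi-mapped exactly as a multi-reporting aligner would emit them. The
family model there is indel-free and candidate positions are restricted to
family copies plus the origin — a 36-mer matching a random background
position within one mismatch is astronomically unlikely, so the
restriction loses nothing at these scales.

## Motif scanning

PFM counts become probabilities with a 0.8 pseudocount per cell and log2
odds against the background (uniform by default). The null score
distribution is computed exactly: partial sums are accumulated
left-to-right over columns with atoms merged on exact equality, so the
score set — and hence every tail probability — is identical to brute-force
enumeration of all `4^W` words (asserted to 1e-12 in the tests for W ≤ 8);
motifs wider than 10 columns fall back to a 1e-4 score grid. Hits at match
p ≤ 1e-6 are reported with Benjamini–Hochberg q-values over all windows
tested per motif, both strands.

## Phylogenetics

The built-in progressive aligner orders sequences by single-linkage on
shared 8-mer distance and merges profiles by global affine-gap dynamic
programming (match +1, mismatch −1, gap open −4, gap extend −1, a length-k
gap costing `open + ext·(k−1)`; ties prefer the diagonal) — implemented in
C++ since profile DP is the one genuinely quadratic step. Externally
computed alignments are ingested verbatim with `read_msa()`, preserving a
MAFFT-based workflow when preferred.

Identity excludes columns where either row has a gap or N. Distances use
Jukes–Cantor `d = −¾ ln(1 − 4p/3)` by default (p-distance available);
saturated pairs (p ≥ 0.75) map to a finite ceiling of 10 with a warning so
NJ stays defined on noisy inputs. `nj_tree()` is the Saitou–Nei
agglomeration with ties broken by label order and negative branch lengths
clamped to zero, the deficit moved to the sister branch. Bootstrap
replicates resample columns (replicate `i` reseeded `seed + i`); a
branch's support is the percentage of replicate trees containing its
bipartition (`ape::prop.clades`), the trivial all-taxa bipartition
reported as NA, and the >50% majority-rule consensus is returned alongside
the support-annotated original tree — both outputs are provided because
"consensus tree with bootstrap" reporting is ambiguous between them.

One honest caveat from calibration: an i.i.d. random alignment is *not*
guaranteed weak supports. The bootstrap measures stability of the realized
sample, and 300 random columns on 6 taxa often stabilize one split above
70. The package's no-signal test therefore asserts that random-alignment
supports sit well below the ≥ 95 clean-clade regime, not that they vanish.

## The simulator: what it emulates, and what it does not

`simulate_genome()` plants, without mutual overlap, on an i.i.d.
background (GC 0.45): TE copies from a small synthetic library (masked
before discovery, like a RepeatMasker annotation), tandem arrays, and
repeat families. The default (`preset = "firre_like"`) study conditions
are 13 local families with lengths
{100…750} bp (median 167) paired inversely with copy numbers {40…3}
(median 12), divergence 2–10%, most families fully local and five at
locality 0.9 with outside copies truncated to 60% of the consensus —
giving the locality classifier its discriminating signal — plus two
dispersed families placed genome-wide. Host genes are sized to hold their
copies (~1.3× the copy mass), 15 mRNA-like genes carry no planted
repeats, and within-locus copy spacing is uniform over the host, a neutral
choice in the absence of any published spacing distribution. Outside
copies of local families are kept ≥ 250 kb apart where the genome permits;
on a 500 kb chromosome the separation is relaxed stepwise (and logged),
since the constraint is geometrically impossible there.

Per-gene burden statistics use a lighter generator
(`simulate_gene_burdens()`): log-normal gene lengths (meanlog = log 30 kb,
sdlog 0.6, shared across classes) and Poisson LR counts at 25 vs 6 per
100 kb (the observed lncRNA/mRNA contrast; fourfold) with equal TR rates —
counts, not sequence, because the contrast being tested is statistical.
Ortholog sets evolve a root sequence down a tree under Jukes–Cantor
substitution only (no indels), with two-clade branch lengths derived by
inverse JC from target identities (90% within, 60% across, the
rodent-vs-primate regime).

What the simulator does **not** emulate — and hence what green tests do
not certify on real data: sequencing error beyond 1-mismatch placement,
paired-end structure, indel-rich repeat evolution, GC- and
mappability-biased coverage, overlapping/nested gene models, and repeat
families related to each other (each consensus is independent random
sequence). Real genomes are harsher on all counts; the simulation
validates the machinery, not the biology.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run, per invocation: one full
500 kb survey; 50 burden contrasts plus 200 null-level replicates at 200
genes per class; 100 + 100 (suite) or 20 + 20 (script) ChIP replicates at
100× family depth on 100 kb genomes; motif enumeration up to `4^8` words;
200 (suite) or 50 (script) random additive matrices on ≤ 6 taxa against an
exhaustive least-squares topology oracle; and 20 (suite) or 10 (script)
two-clade bootstrap runs at 3 kb columns. These sizes were chosen to give
stable Monte-Carlo estimates at interactive runtimes on a single core.

## Known limitations

- Gapless extension truncates copies at internal indels; recovery of such
  copies relies entirely on the re-mapping step.
- The lag-correlation tandem detector reports genuine micro-tandems in
  random sequence at the default thresholds; consumers needing a sparse
  TR catalogue should raise `min_len`.
- `map_consensus()` merges hits closer than ~50 bp into one candidate
  window and separates them by iterative masking; arrays of dozens of
  directly abutting near-identical copies are better handled as tandem
  arrays (which they are, by routing).
- The Poisson ceiling makes the enrichment test conservative for observed
  ratios just above an integer.
- NJ is O(n³) in taxa and intended for the dozens-of-orthologs scale.
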