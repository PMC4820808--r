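# locrep

Discovery and analysis of **local repeats (LRs)** — sequence families that
recur multiple times, discontinuously, within a single genomic locus and
rarely or never elsewhere in the genome. LRs of 100–750 bp are a hallmark of
several X-linked loci (the *FIRRE* lncRNA locus being the best-studied
case, with 13 repeat families at 3–40 copies each), sit mostly in introns,
and can act as platforms for architectural proteins such as CTCF, RAD21 and
YY1. They are distinct from tandem repeats (TRs; adjacent copies of a short
motif) and from transposable elements (TEs; interspersed, genome-wide).

`locrep` is an R package for the full computational survey:

1. **TE masking** — `mask_te()` blanks annotated TEs to N.
2. **De novo repeat discovery** — `discover_repeats()` seeds on repeated
   16-mers (strands pooled under the canonical k-mer) and grows a consensus
   by greedy gapless majority-vote extension with an X-drop stop; accepted
   consensi are re-mapped genome-wide and their hits claimed, so each
   repeat family is discovered once.
3. **Tandem filtering** — `detect_tandem_arrays()` finds tandem arrays by
   lag correlation (period `p` calls when the self-match purity at lag `p`
   is ≥ 0.8 over ≥ 2 periods); `split_tandem()` routes families into a TR
   catalogue or the LR candidate set.
4. **Locality classification** — `map_consensus()` maps each consensus
   genome-wide (seed-and-extend + local alignment); `classify_locality()`
   calls a family **LOCAL** when ≥ 80% of its instances fall in one host
   locus, recording the dispersal diagnostics of outside copies (shorter
   than the in-locus median; > 250 kb apart).
5. **Burden statistics** — `compute_burden()` counts LRs/TRs per gene per
   kb; `sample_length_matched()`, `build_null()` (shuffled /
   shuffled-intergenic window ensembles, 100 permutations) and
   `compare_burdens()` (two-sided Mann–Whitney U) test class contrasts.
6. **ChIP-Seq enrichment at repeats** — `load_alignments()` weights
   multi-mapped reads 1/n per reported location (best-20 cap), so a read
   aligning to 20 positions counts 1/20 at each;
   `permutation_poisson_test()` scores ChIP/input coverage ratio over all
   family instances against a Poisson null whose rate is the mean
   enrichment of 100 random equal-width region sets.
7. **Motif scanning** — `scan_motifs()` scans PFMs (JASPAR text format)
   with exact match p-values from the full log-odds score distribution,
   BH-corrected per motif.
8. **Phylogenetics** — `progressive_align()` (built-in progressive
   aligner; external MSAs ingestible via `read_msa()`), Jukes–Cantor
   distances, a hand-implemented neighbor-joining `nj_tree()`, and
   `bootstrap_support()` reporting branch supports and the >50% consensus.

Because the genome-scale catalogues behind published LR surveys cannot be
shipped, the package carries a first-class simulator
(`simulate_genome()`, `simulate_chip_reads()`, `simulate_ortholog_set()`,
`simulate_gene_burdens()`) that plants repeat families, tandem arrays, TEs,
multi-mapping reads and two-clade ortholog sets with full ground truth, so
every stage is validated end-to-end against what was planted.

## Worked example

The one-call pipeline simulates a 500 kb chromosome carrying 13 local
repeat families (100–750 bp, median 167 bp; 3–40 copies, median 12; up to
10% divergence), 2 dispersed families, 5 tandem arrays, 20 TE copies and
two gene classes, then runs the survey:

```r
library(locrep)
run <- lr_run_pipeline(lr_default_config(seed = 7))
run
#> lr_run (seed 7):
#>   planted families: 15; discovered: 20 (TR 5 / LR candidates 15)
#>   LOCAL calls: 13; LR recovery 100% at median consensus identity 100.0%
#>   tandem routing to TR: 100%; dispersed mis-called LOCAL: 0
#>   burden rank-sum: LR p = 1.2e-06, TR p = 0.89
```

All 13 planted local families come back as LOCAL calls with their
consensus sequences essentially exact; the two dispersed families are
correctly rejected; the five tandem arrays are routed to the TR catalogue;
and the lncRNA-like class shows a significant LR excess over the mRNA-like
class (rank-sum p ≈ 1e-06) while the equal TR rates do not (p ≈ 0.9).
`run$recovery$families` holds the per-family comparison against the
planted truth; `lr_run_pipeline(cfg, out_dir = "out")` additionally writes
each stage's FASTA/BED/TSV outputs, the effective YAML configuration and a
JSON summary, byte-identically across reruns with the same seed.

The ChIP branch, on its dedicated simulated experiment:

```r
ex <- simulate_chip_experiment(fold = 10, depth = 100, seed = 3)
# ... weight, then test
#> ChIP enrichment at family
#>   enrichment: 8.74  lambda (mean of 100 permutations): 0.977
#>   Poisson p-value: 9.34e-07
```

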