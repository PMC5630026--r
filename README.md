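# creevo

Cross-species analysis of cis-regulatory element (CRE) evolution in R.

## What this is for

Comparative epigenomics asks whether a regulatory element that is active in
one species is also active in its relatives, and when in a phylogeny its
activity was gained or lost. Peak-overlap comparisons confound that question
with depth, assembly and threshold artifacts. creevo implements the
quantitative alternative for a six-species primate design (human, chimp,
rhesus macaque, marmoset, mouse lemur, bushbaby; liver H3K27ac/H3K4me1
ChIP-seq with matched inputs plus RNA-seq):

* **Orthology mapping** — human CRE intervals are projected through
  multiple-sequence-alignment (MAF) blocks into each species; a CRE is
  *six-way-alignable* when every species covers ≥ 50% of it.
* **Differential histone modification** — per region and species
  comparison, a negative-binomial GLM with log link
  `count ~ assay + condition + assay:condition`, where `assay` is IP vs
  input: the Wald test on the interaction coefficient isolates changes in
  IP enrichment over input (FDR < 10%, Benjamini–Hochberg per comparison,
  both marks tested and merged).
* **Conservation classification** — nine human-centric comparisons (five
  pairwise + four clade contrasts) feed a deterministic classifier:
  `conserved` (nothing significant), `human/ape/catarrhini/haplorrhini_specific`
  (clade group test plus sign-consistent pairwise significance), else
  `other_divergent`.
* **Sequence divergence** — per-nucleotide mismatch fraction vs human over
  the CRE ± 500 bp, excluding human-gap columns, with iterative Grubbs
  outlier removal.
* **TE enrichment** — per RepeatMasker-style subfamily, the count of CREs
  ≥ 20%-covered by that subfamily (union rule), against a null of 1000
  uniform re-placements per chromosome; empirical p = (r+1)/(n+1), FDR < 1%.
* **Association statistics** — Cochran–Mantel–Haenszel common odds ratio
  across per-comparison 2×2 tables (differential expression × differential
  modification), Fisher's exact test, and logistic regressions of
  divergence-type covariates on regulatory state.
* **Reporter assays** — exact Wilcoxon rank-sum tests of construct activity
  vs empty-vector control with activator/repressor calls.
* **A synthetic-data generator** — six-species alignments (Jukes–Cantor
  substitutions, indels, branch-specific TE insertions), NB count matrices
  with known gain/loss effects, and a ground-truth table, so the entire
  pipeline is testable offline with no download.

## Worked example

Simulate a 300-CRE bundle and run every stage:

```r
library(creevo)
library(dplyr)

cfg    <- sim_config(n_cres = 300, n_genes = 240, seed = 42)
bundle <- simulate_bundle(cfg)
res    <- run_pipeline(bundle, pipeline_params(n_shuffles = 200, seed = 42))

res$conservation_summary |> filter(stratum == "overall")
#>   stratum stratum_value label                    n total percent
#> 1 overall all           ape_specific            18   300     6
#> 2 overall all           catarrhini_specific     22   300     7.3
#> 3 overall all           conserved              141   300    47
#> 4 overall all           haplorrhini_specific    18   300     6
#> 5 overall all           human_specific           7   300     2.3
#> 6 overall all           other_divergent         94   300    31.3
```

91.3% of the CREs simulated with a lineage-specific gain or loss recover
their exact clade label. Divergence medians reproduce the phylogeny —
chimp 0.0094, rhesus 0.0288, marmoset 0.0573, mouse lemur/bushbaby ≈ 0.149
mismatches per compared site — and every planted TE subfamily comes out
enriched, e.g.:

```r
res$te_enrichment
#>   subfamily observed null_mean fold empirical_p    padj enriched
#> 1 AluY             6     0.16  37.5     0.00498 0.00498 TRUE
#> 5 SVA_B           13     0.22  59.1     0.00498 0.00498 TRUE
#> ...
```

Genes linked to differentially modified CREs are enriched for differential
expression (`res$association$cmh`: Mantel–Haenszel OR = 15.5 on this
synthetic bundle, P = 6.6e-22, 5 strata — the simulator propagates half of
each CRE effect to its linked gene, a far stronger coupling than real
tissue data shows).

Plot helpers: `plot_conservation()`, `plot_divergence()`,
`plot_te_enrichment()`, `plot_comparison_fractions()`; NB GLM fits have
`tidy()`/`glance()` methods.

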