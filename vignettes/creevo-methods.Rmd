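---
title: "Methods: cross-species CRE evolution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species CRE evolution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(creevo)
```

# The problem

Regulatory evolution is hard to read off peak calls alone: whether a peak is
"present" in a species confounds biology with sequencing depth, assembly
quality and peak-caller thresholds. creevo instead treats cis-regulatory
element (CRE) evolution as a quantitative comparison of histone-modification
signal (H3K27ac, H3K4me1) over *orthologous intervals* across a six-species
primate phylogeny — human, chimpanzee, rhesus macaque, marmoset, and the two
strepsirrhines mouse lemur and bushbaby — with a matched input library as a
within-region control. On top of the differential-signal calls it layers a
phylogenetic classifier (conserved vs lineage-specific activity), sequence
divergence, transposable-element (TE) enrichment, and association statistics
linking regulatory to expression divergence.

Every stage is exercised end-to-end on synthetic data with known ground
truth, generated by the package itself, so the statistical behavior of the
whole pipeline is testable without any external download.

# The statistical core

## Differential histone modification

For one region and one comparison between species groups $A$ and $B$, counts
$y_{ij}$ (IP and input libraries from both groups) are modeled as negative
binomial (NB) with a log link:

$$\log \mu = \beta_0 + \beta_1\,\mathrm{assay}
  + \beta_2\,\mathrm{condition} + \beta_3\,(\mathrm{assay}\times\mathrm{condition})
  + \log s_j$$

where `assay` is IP vs input, `condition` is group membership, and $s_j$ are
median-of-ratios size factors. The coefficient of interest is the
*interaction* $\beta_3$: the change in IP enrichment over input between the
groups. Input-driven artefacts (copy number, mappability, library depth)
move `assay` and `condition` main effects, not the interaction. The Wald
statistic $\beta_3/\mathrm{se}(\beta_3)$ is referred to a t distribution
with the residual degrees of freedom (samples minus coefficients)
and Benjamini–Hochberg adjusted within each comparison; differential
histone modification is called at FDR < 10%. The two marks are analyzed
independently and merged: a region is differential if either mark is.

Fitting is iteratively reweighted least squares (Fisher scoring) with
working weights $\mu/(1+\alpha\mu)$, step-halving so the log-likelihood
never decreases, convergence at a maximum coefficient change of $10^{-8}$
(cap: 100 iterations), and covariance from the inverse Fisher information.
log2 fold changes are natural-log coefficients divided by $\ln 2$.

## Dispersion

The NB dispersion $\alpha$ (variance $\mu + \alpha\mu^2$) is estimated per
feature by maximizing the profile likelihood with the Cox–Reid adjustment
$-\tfrac12 \log\det(X^\top W X)$, bounded to $[10^{-8}, 10]$ on a log scale.
At the sample sizes here (a dozen libraries against four coefficients),
unadjusted ML is biased low enough to visibly inflate the interaction
test's type-I error; the CR adjustment removes most of that bias. No
empirical-Bayes shrinkage across features is applied — with three to four
individuals per species per assay the per-feature estimate is adequate, and
it keeps the estimator self-contained.

Why a t reference and not the plain normal: with a dozen samples the
standard error is itself an estimate, and a normal reference is
anti-conservative in exactly the far tail that BH thresholds live in (about
threefold at $p \approx 0.01$ for 8 residual df). Referring the same Wald
statistic to $t_{n-p}$ — the same move quasi-likelihood ChIP/RNA pipelines
make — restores calibration there, which the null simulations and the
false-discovery-proportion check in the tests verify. The standalone
[wald_test()] helper keeps the classical normal tail for generic use.

## Differential expression

Per gene, `count ~ condition` with offsets
$\log s_j + \log(\mathrm{length}/1000)$, Wald test on `condition`,
BH at FDR < 5%.

# The comparison battery and conservation classifier

Nine human-centric comparisons are run per region: human against each of the
five other species, and four clade contrasts — human vs all others; human +
chimp ("ape") vs the rest; Catarrhini (human, chimp, rhesus) vs the rest;
Haplorrhini (plus marmoset) vs Strepsirrhini. Each region's significance
vector holds `sig+`/`sig-` (signed by the interaction log2FC), `ns`, or
`untested` (all IP counts zero).

Labels are a deterministic function of that vector:

* **conserved** — nothing significant anywhere;
* **human/ape/catarrhini/haplorrhini-specific** — the clade's group test is
  significant, every pairwise comparison crossing the clade boundary is
  significant with one consistent sign, and the within-clade pairwise
  comparisons are `ns`;
* **other_divergent** — everything else.

This conjunction (group test *and* sign-consistent pairwise tests) is the
strictest reading of the design; `require_pairwise = FALSE` relaxes it to
the group test alone. An `untested` entry in a required comparison never
supports a lineage-specific call — missing evidence is not evidence of
lineage specificity. A `centric = "chimp"` battery re-roots the pairwise
comparisons for the species-bias control analysis.

# Orthology mapping and divergence

Alignment blocks are read from MAF; minus-strand rows are normalized to
forward-strand coordinates at parse time. A human interval is projected
through the block column-by-column: a species' orthologous interval is the
forward-strand span of its non-gap columns aligned to the human interval's
columns. A species is *present* when it aligns at least `min_coverage`
(default 50%) of the human bases; a CRE is six-way-alignable when all six
species are present. Projections split over several blocks are stitched
when collinear on one strand, otherwise the largest single-block projection
wins; among duplicate rows the one with maximal coverage (ties: lowest
start) is used.

Pairwise divergence per species is mismatches over compared columns within
the CRE ± 500 bp, where columns with a human gap are excluded outright,
columns where the species has a gap are excluded from the denominator, `N`
matches nothing, and case is ignored. Outliers of each species' divergence
distribution are flagged by an iterative two-sided Grubbs test at
$\alpha = 0.05$ (groups under 3 values are left untouched, with a warning)
and excluded from downstream regressions.

# TE enrichment

Observed statistic per TE subfamily: the number of CREs whose length is
covered at least 20% by the union of that subfamily's intervals (union, so
nested RepeatMasker-style records are not double-counted; the 20% boundary
is inclusive). The null re-places every CRE uniformly at random on its own
chromosome, length preserved, 1000 times by default; an optional exclusion
mask is honored by rejection sampling. The one-sided enrichment p is
$(r+1)/(n+1)$ with $r$ the number of shuffles at or above the observed
count — so p is never 0 and its floor is $1/(n+1)$. BH across subfamilies,
enrichment called at FDR < 1%; a depletion p is reported but does not feed
the flag.

# Association statistics

Differentially expressed genes are cross-classified against association
with a differentially modified CRE, one 2×2 table per pairwise species
comparison, and combined by the Mantel–Haenszel common odds ratio
$\sum_i a_i d_i / n_i \,/\, \sum_i b_i c_i / n_i$ with the CMH chi-square
(no continuity correction) and a Robins–Breslow–Greenland confidence
interval. These are computed directly (the single-stratum case must reduce
exactly to the plain odds ratio). Fisher's exact test and logistic
regressions (outcome: diverged vs conserved; covariates: divergence,
TSS-distance deciles, and similar, with ties binned down) round out the
toolkit; complete separation in the logistic fit is detected and flagged
rather than reported as a p-value.

# Reporter assays

Construct activity is compared to the empty-vector control with a two-sided
Wilcoxon rank-sum test — exact when both groups have ≤ 25 replicates and no
ties, else the tie-corrected normal approximation. A construct is an
*activator* (p < 0.05 and median above control) or *repressor* (below);
six replicates per construct is the default design. Raw p-values are
reported with an optional BH column, since per-construct decisions in this
assay are conventionally made on raw p.

# The synthetic-data generator

The generator is first-class, tested code that emulates the study design:

* **Phylogeny.** The fixed topology with branch lengths scaled so the
  expected human–chimp mismatch fraction is ≈ 0.01 and human–mouse lemur
  ≈ 0.15, preserving the observed ordering of primate divergences.
* **Sequence.** One alignment block per CRE (500 bp flanks around a 600 bp
  core), evolved by per-branch Jukes–Cantor substitutions
  ($p = \tfrac34(1-e^{-4t/3})$), geometric indels (mean 3 bp, rate 0.1 per
  substitution), and TE insertions realized as branch-specific inserted
  columns: SVA_F on the human branch, SVA_B/C/D and LTR12C on the ape
  branch, AluY/L2/MIR embedded at the root. Inserted material is not
  further mutated or deleted on deeper branches — a simplification that
  keeps every column attributable to one event and is invisible to the
  divergence rules, which only compare human-base columns.
* **Counts.** IP counts are NB with mean
  $d \cdot 2^{q + \mathbb{1}[\text{species} \in \text{clade}]\,\beta}$
  (depth $d = 100$, IP-over-input enrichment $q = 2$ log2 units, effect
  $|\beta| = 2$), input counts NB with mean $d$; dispersion
  $\alpha = 0.05$ (a typical within-species biological CV for this design;
  the study does not state one, so it is exposed in the config); log-normal
  per-sample size factors (sd 0.15). Gene expression inherits half of the
  linked CRE's effect by default. Pre-noise expected count ratios between
  clade and outgroup species equal $2^\beta$ exactly.
* **Layout.** Blocks are spaced 30 kb apart; promoter-intent genes put
  their TSS inside the CRE, enhancer-intent TSS land 2–20 kb downstream, so
  realized promoter/enhancer classes equal the intended ones and the
  catalogue stage can be verified deterministically.
* **Truth mix.** 63% conserved, 2% human-specific, 6% ape-specific,
  6% Catarrhini, 8% Haplorrhini, 15% "other" (a deliberately non-clade
  pattern the classifier must refuse to label lineage-specific).

What the generator does *not* emulate: read-level artifacts (GC,
mappability), assembly gaps, sex chromosomes, correlated indel processes,
or alignment error. Passing tests therefore demonstrate statistical
correctness of the methods under the model they assume — not robustness to
real-data artifacts upstream of counting.

# Numerical and design choices

* A TSS distance of exactly 1000 bp is an *enhancer* (promoters are
  strictly `< 1 kb`); distance is edge-based (0 when the TSS is inside).
* Nearest-gene ties break to the lexicographically smallest gene id.
* Regions with all-zero IP counts in a comparison are `untested` there and
  excluded from that comparison's BH denominator.
* BH is applied within each comparison, not pooled across the nine.
* Seeds: one master seed; per-stage child seeds derived deterministically,
  so any stage can be reproduced in isolation and identical configurations
  produce byte-identical fixture bundles.
* Default problem sizes: the shipped tests run on a 40-CRE bundle; the
  acceptance analyses use the 2,000-CRE configuration at which the
  classifier-recovery claims are stated.

# Known limitations

* No LFC shrinkage, Cook's-distance outlier handling, or independent
  filtering; effect estimates at low counts are noisier than shrunk ones.
* The Wald/normal reference is anti-conservative at very small n (see
  above).
* The shuffle null preserves chromosome and length but not GC,
  mappability, or inter-CRE spacing.
* Orthology projection trusts the input alignment; it has no notion of
  paralogy beyond the maximal-coverage row rule.
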