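---
title: "Constraint-aware ranking of interspecies ASE differences: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-aware ranking of interspecies ASE differences: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisconstraint)
```

# The model

`cisconstraint` asks, per gene, whether the expression difference
between two species exceeds the cis-regulatory variation tolerated
*within* one of them, and whether whole gene sets show directionally
coherent cis changes — the signature of polygenic lineage-specific
selection.

Two ASE distributions are compared per gene:

* **Population ASE.** For sample $s$ of a population cohort, the ratio
  $r_{gs} = (a^{(1)}_{gs} + c)/(a^{(2)}_{gs} + c)$ with pseudocount
  $c = 1$ per allele. Samples with fewer than 10 raw reads from either
  allele are removed *per gene* (the same sample may pass for one gene
  and fail for another). Retained ratios are divided by their median,
  so consistent expression bias of one allele — e.g. a common
  regulatory variant — is removed and only the spread remains. The
  sample variance of the normalized ratios, `ase_variance`, is the
  constraint proxy: tightly constrained genes tolerate little allelic
  imbalance across individuals.
* **Interspecies ASE.** In a hybrid, both parental genomes experience
  the same trans-acting environment, so the allelic ratio isolates cis
  divergence. Per replicate, $\log_2((h_{gr}+c)/(ch_{gr}+c))$ with the
  species-1 (human-like) allele in the numerator. No coverage filter
  (extreme differences between species are expected and are signal)
  and no median normalization (consistent bias *is* the quantity of
  interest). Genes are removed only when the mean count is below 25 on
  *both* alleles, and a user exclusion list handles known mapping-bias
  or structural-artefact genes.

The core statistic is the two-sided Mann-Whitney U p-value $p_g$
comparing the hybrid $\log_2$ ratios against the population $\log_2$
ratio distribution. Three rankings derive from it:

* `mwu`: ascending $p_g$;
* `signed`: descending $-\log_{10}(p_g)\,\mathrm{sign}(\mathrm{L2FC}_g)$,
  so one list reads species-1-biased divergence at the top and
  species-2-biased at the bottom;
* `diff_in_ranks`: descending $\mathrm{rank}_{DE}(g) -
  \mathrm{rank}_{MWU}(g)$, surfacing genes that the traditional
  DE-FDR ranking underrates because their fold change is modest while
  their population constraint is tight.

The externally supplied `mean_log2fc` and `de_fdr` come from a
conventional differential-expression fit of the same hybrid data
(e.g. DESeq2); fitting them is deliberately outside this package, and
the simulator provides a surrogate (below).

On the signed ranking, a preranked gene-set enrichment analysis is run,
and for each eligible set the genes before the running-sum peak (the
leading edge) are counted by direction of `mean_log2fc`. Because cis
changes of different genes rest on independent mutations, the direction
counts are binomial$(n, 1/2)$ under neutrality; the exact two-sided
binomial p, BH-corrected across sets, flags candidate targets of
lineage-specific selection.

# Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `pseudocount` | 1 | added per allele before any ratio |
| `min_reads` | 10 | per-allele, per-gene, per-sample coverage floor (population only) |
| `min_samples` | 50 | retained samples needed for a population profile |
| `min_mean_count` | 25 | per-allele mean-count floor; a gene is dropped only if **both** alleles are below it |
| `scale` | `"ratio"` | scale of `ase_variance` (`"log2"` available) |
| `n_perm`, `gsea_seed` | 1000, 6 | permutations and seed of the enrichment null |
| `min_size`, `max_size` | 10, 300 | gene-set size bounds (intersection with the ranked list) |
| `weight` | 1 | ES exponent on &#124;score&#124;; 0 gives the classical KS statistic |
| `gsea_fdr` | 0.25 | enrichment-eligibility cutoff for the sign test |
| `min_driving_genes` | 5 | leading edges must be strictly larger than this |
| `bh_threshold` | 0.1 | BH q cutoff for calling a set significant |

All are exposed in `pipeline_config()` and on the CLI subcommands.

# Numerical and procedural choices

* **Filter before normalizing.** Low-coverage samples are removed
  *before* the median normalization. Normalizing first and filtering
  afterwards could leave the retained samples with median $\neq$ 1,
  defeating the purpose of centering; the two orders differ only when
  discarded samples shift the median.
* **Mann-Whitney implementation.** When $n_1 n_2 \le 400$ and the
  pooled values are tie-free, the exact null distribution of U is used
  (`stats::pwilcox`), with the two-sided p as twice the smaller tail
  including the observed value, capped at 1. Otherwise the normal
  approximation with tie-corrected variance and continuity correction.
  Zero rank variance (all pooled values equal) returns p = 1. The test
  suite checks the exact branch against full enumeration of all
  $\binom{n_1+n_2}{n_2}$ group assignments and the approximate branch
  against the corrected-normal reference.
* **Signed-score convention.** The signed score is
  $-\log_{10}(p)\cdot\mathrm{sign}(\mathrm{L2FC})$ with the p-value
  floored at $10^{-300}$; $\mathrm{sign}(0) = 0$. A score written as
  $\log_{10}(p)\cdot\mathrm{sign}$ would invert the intended
  orientation (significant species-1-biased genes belong at the top),
  so the negative-log form is used.
* **Deterministic ties.** Every ranking breaks score ties
  lexicographically by gene id; this matters in the DE-FDR ranking
  where many genes share FDR 1, and makes `diff_in_ranks` and all
  downstream results reproducible.
* **Enrichment engine.** $P_{hit}$ increments by
  $|s_i|^w / \sum_{hits} |s_j|^w$ at member positions and $P_{miss}$
  by $1/(N - N_{hits})$ elsewhere; ES is the signed maximum-magnitude
  deviation, and if all member weights are zero the unweighted
  increments are used. The null permutes gene labels (the only option
  in preranked mode) by drawing set-sized position subsets; for the
  null only, ES is evaluated from sorted hit positions in $O(k)$,
  exploiting that the running sum is linear between hits — the test
  suite asserts equality with the position-by-position evaluation.
  NES divides ES by the mean magnitude of same-sign null ES for that
  set; nominal p is the same-sign exceedance fraction floored at
  $1/n_{perm}$; FDR follows the published positive/negative-pool
  procedure on the sign-wise mean-normalized null scores. Agreement
  with any particular external GSEA implementation is only expected
  at the level of eligibility decisions (FDR < 0.25), not in the last
  digit of q-values.
* **Sign-test bookkeeping.** "Genes driving the enrichment" are
  exactly the leading-edge genes (before the running-sum peak for
  positive ES, after it for negative); no further per-gene
  significance filter is applied. Genes with `mean_log2fc` exactly 0
  are excluded from both direction counts. A set enriched at several
  time points is tested once, at the time point with the lowest
  enrichment FDR, ties resolved toward the earliest time point. The
  BH threshold is 0.1.
* **Missing counts.** `NA` counts mean the gene was not quantifiable
  in that sample and never pass the coverage filter; they are not
  zeros, which are informative about imbalance.
* **Gene identifiers** are opaque case-sensitive strings matched
  exactly; mismatches are reported, never guessed.

# The synthetic-data generator

`generate_population()` draws, per gene $g$ and sample $s$: a mean
depth $m_g \sim \mathrm{LogNormal}(\log(\texttt{depth\_mean}),
\texttt{depth\_sdlog})$, a total $N_{gs} \sim \mathrm{Poisson}(m_g)$,
an allele-1 fraction $f_{gs} \sim \mathrm{Beta}(\alpha_g, \alpha_g)$,
and $a^{(1)}_{gs} \sim \mathrm{Binomial}(N_{gs}, f_{gs})$. The single
concentration parameter $\alpha_g$ is the constraint dial: large
$\alpha$ means tightly balanced alleles. `generate_hybrid()` centers
the fraction at $2^{\delta_g}/(1+2^{\delta_g})$ for a cis shift of
$\delta_g$ log2 units, with the same concentration across replicates.
The DE-summary surrogate takes `mean_log2fc` as the mean replicate
log2 ratio and `de_fdr` as the BH-adjusted one-sample t-test p-value
of the replicate log2 ratios against zero. Constraint scores are a
monotone function of $\log \alpha_g$ with 25% rank-scale noise by
default; the expression summary reuses the population depth model.
Everything is bit-reproducible from `config$seed`, with fixed offsets
per generator so stages can be reproduced individually.

Reference cohorts, fixed once:

* `default_cohort_config()` — the two-class study cohort: 100 genes
  all carrying the same interspecies shift $\delta = 0.5$, half
  constrained ($\alpha = 150$) and half unconstrained ($\alpha = 4$),
  500 samples at median depth 100, 8 hybrid replicates. $\alpha = 150$
  makes the normalized ratio spread a few percent (a tightly
  constrained gene), $\alpha = 4$ lets ratios range over roughly
  0.3-3x (essentially unconstrained); depth 100 is a typical ASE
  coverage once variant-level counts are collapsed per gene.
* `validation_cohort_config()` — a continuous constraint gradient:
  250 genes with $\alpha$ log-uniform on 3-300, 600 samples, median
  depth 300 with small spread so the coverage filter rarely truncates
  a gene's sample set (the down-sampling design needs genes
  quantifiable in every sample).

What the generator emulates: per-gene overdispersed allelic imbalance
with a constraint gradient, variable depth, directional gene sets, and
replicate-level hybrid noise. What it does not: tissue structure and
shared individuals across tissues, linkage between variants, reference
mapping bias, or correlated cis effects among neighboring genes that
share regulatory elements. Passing tests therefore demonstrate that
the statistics recover the structure they assume, not that real
cohorts satisfy those assumptions.

# Problem sizes used in the checks

The test suite runs the two-class cohort at its defining size
(100 genes x 500 samples), the validation cohort at 250 genes x 600
samples with a down-sampling grid of 600/100/25 and 20 replicates, and
the neutral-null FDR check over 20 simulated cohorts of 300 genes with
25 gene sets each at the default 1000 permutations. These sizes give
stable Monte-Carlo behaviour for every assertion while a full suite
run stays in the one-minute range.

# Known limitations

* The Mann-Whitney comparison treats population samples as
  exchangeable; cohorts pooling several tissues or related individuals
  violate this silently. `pool_counts_by_individual()` handles the
  one-individual-many-samples case; tissue stratification is the
  user's responsibility.
* The variance constraint proxy is depth-sensitive: shallow genes have
  inflated ratio variance. The down-sampling and expression-matched
  procedures quantify, but do not remove, this effect.
* The sign test assumes independent cis changes per gene; neighboring
  genes sharing cis elements weaken the binomial null.
* With maximally dispersed (near-unconstrained) genes, MWU p-values
  are close to uniform and their ranks are unstable under the
  arbitrary allele orientation; rankings of such genes carry little
  information, and orientation-robustness of the overall ranking is
  correspondingly bounded by the share of such genes in the input.
* Variant-to-gene collapsing of ASE counts is upstream of this
  package: the readers accept gene-level tables only.
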