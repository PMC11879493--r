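---
title: "Methods: gene-allele marker GWAS for shade-tolerance traits"
author: "shadenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-allele marker GWAS for shade-tolerance traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shadenet)
```

## The problem

Soybean grown under maize in inter/relay-cropping receives ~30% less light;
tolerant cultivars avoid excessive stem elongation. Two indicators quantify
this at the plant and cell level:

* **STI** (shade-tolerance index): the mean of the shade/control ratios of
  plant height and average internode length (AINL = PH/NN),
  `STI = (PH_s/PH_c + AINL_s/AINL_c) / 2`. Smaller is more tolerant.
* **RCL** (relative pith cell length): the mean pith-cell length of one
  shade micrograph divided by the pooled mean of all control-micrograph
  cells. The pooled denominator matters: with unequal cell counts per image
  it differs from a mean of image means, and `compute_rcl()` implements the
  pooled form.

`shadenet` implements the full analysis chain for a biparental recombinant
inbred line (RIL) population phenotyped for these indicators: variance
components and heritability, assembly of within-gene SNP haplotypes into
multi-allelic **gene-allele sequence markers** (GASMs), a restricted
two-stage multilocus GWAS with genotype-by-environment interaction (GEI)
and a heritability cap, contribution accounting with a large/small
contribution split and a polygene remainder, prediction of cross
recombination potential from the fitted gene-allele matrix, threshold-based
differential-expression calling with Venn accounting, and summary
statistics on protein-protein interaction (PPI) edge lists. A seeded
synthetic-data module generates inputs with the statistical structure the
analysis assumes, so every stage is testable end to end without external
data.

## Variance components and heritability

`anova_components()` computes method-of-moments estimates from the expected
mean squares of the balanced two-way random model (lines and environments
random, `r` replicates):

```
MS_G   = s2_eps + r s2_ge + r n s2_g
MS_GE  = s2_eps + r s2_ge
MS_err = s2_eps
```

Negative moment estimates are truncated at zero and flagged — the standard
convention, applied because a pure-noise trait yields a negative `s2_g`
estimate about half the time. Broad-sense heritability on the line-mean
scale uses `D = s2_g + s2_ge/n + s2_eps/(n r)`:

```{r}
vc <- list(sigma2_g = 2, sigma2_ge = 1, sigma2_eps = 3,
           n_env = 3, n_rep = 3, gei_estimable = TRUE)
unlist(heritability(vc))
```

`h2_gei` is defined as `(s2_ge/n)/D` so that the main and GEI shares add to
the total — the partition is reported in the literature but its formula is
usually left implicit; this definition makes the reported additivity an
identity. With a single environment, GEI is not estimable and the reduced
formula `s2_g / (s2_g + s2_eps/r)` applies (the RCL design, where the five
RCL values per line act as replicates).

STI is computed per (line, environment, replicate) plot pair and then
averaged; keeping the replicate structure is what allows the ANOVA above.

## GASM assembly

All SNP alleles inside one annotated gene are concatenated per line into a
haplotype string; the distinct complete haplotypes observed in the
population are the marker's alleles (`assemble_gasms()`). In a biparental
RIL population without recombination inside the gene this yields exactly
two alleles; an intra-gene recombinant creates a third. Conventions:

* residual heterozygotes are scored missing at the marker (RIL analyses
  conventionally drop residual hets);
* a haplotype with missing sites is assigned only if exactly one observed
  complete haplotype is compatible ("match-or-missing" — conservative and
  deterministic);
* markers with more than 20% missing lines, monomorphic markers, and genes
  without SNPs are dropped (counted);
* gene intervals are taken as gene bodies; coordinates follow the GRanges
  1-based-closed convention internally, with BED offsets handled by the
  rtracklayer readers.

## The two-stage multilocus GWAS

**Stage 1** (`stage1_preselect()`) screens each marker with a single-locus
F-test at `alpha1 = 0.05`, with environment as a deviation-coded blocking
factor and optional eigenvector covariates (`eigen_covariates()`, default
`k = 0`: a biparental RIL population has no population structure worth
correcting; `k = 10` is available for structured panels).

**Stage 2** (`stage2_stepwise()`) is forward selection with backward
elimination over the preselected markers, under two controls:

1. **Experiment-wise significance.** The per-term partial-F threshold is
   `alpha2 / m`, with `m` the number of candidate markers — the
   multilocus model's built-in experiment-wise control, equivalent to a
   Bonferroni rule on the single-locus scan. This choice is load-bearing:
   with a plain per-test `alpha2`, every marker that survived the marginal
   screen re-qualifies inside the multilocus model (its partial F only
   grows as the residual shrinks), and the selection degenerates to the
   stage-1 screen. We verified this by simulation: under the plain rule a
   single planted QTL is recovered *exactly* in only ~25% of runs, versus
   ~92% under the experiment-wise rule. `experimentwise = FALSE` restores
   the plain behaviour for comparison.
2. **The heritability cap.** The summed contribution of selected terms may
   not exceed `h2_cap`, supplied from the trait's estimated heritability.
   Contributions are measured against the residual sum of squares of the
   base model (intercept + environment + covariates). For line-mean input
   this denominator is exactly the heritability denominator `D`, so the
   cap, the mapped contributions, and the polygene remainder live on one
   scale. Note that a trait whose entire heritability sits in one locus
   has a sample R^2 that straddles the cap; the cap is an upper bound to
   be supplied with its estimation uncertainty in mind, not an exact
   equality constraint.

GEI terms (locus x environment, deviation-coded) may enter only while the
locus main term is in the model, and a main term with an active GEI term is
shielded from backward removal (standard model hierarchy). Ties in forward
selection break by largest incremental SS, then genome order, making the
procedure deterministic.

Per-term contributions (`r2_table()`) are incremental (entry-order
sequential) sums of squares as percent of the corrected total SS; for
near-orthogonal biparental RIL loci sequential and partial R^2 agree
closely. Loci with `R2_main >= 1.5%` are classed LC (large contribution),
below that SC; `contribution_summary()` adds the subtotals and the polygene
remainder `h2_main - sum(R2_main)`, which is the heritability carried by
unmapped small-effect loci. GEI contributions are reported on the same
corrected-total-SS scale as main contributions; published GEI totals are
sometimes quoted on other bases, so the two should be compared with care.

On allele effects: `allele_effects()` returns sum-to-zero (deviation-coded)
effects per allele, so a biparental locus reports `+a/-a`; a planted
homozygous-class contrast of 0.1 is recovered as effects of about
+/- 0.05.

## Cross recombination potential

`build_matrix()` arranges the fitted main-effect values into a lines x loci
gene-allele matrix. For a cross i x j:

* **Independent assortment** (`potential_independent()`): the optimal
  transgressive progeny value has the closed form `mu + sum_l
  best(e_il, e_jl)` (minimum per locus for smaller-is-better traits). This
  equals exhaustive enumeration over all allele combinations, which the
  test suite verifies up to 2^10 combinations. All-pairs evaluation uses
  the identity `min(a,b) = (a + b - |a - b|)/2`, turning the pair scan
  into a Manhattan-distance computation.
* **Linkage model** (`potential_linkage()`): the analytical form used by
  the original association tool is not restated in the source literature,
  so this package *defines* the linkage-model potential operationally as a
  seeded Monte-Carlo: simulate `n_progeny` inbred progeny of the cross by
  map-based meiosis (Haldane mapping function, single-seed descent,
  default 1000 progeny and F6), score each progeny on the matrix, and take
  the favorable extreme (or a stated favorable-tail quantile). This is a
  declared operational definition, not a claim of equivalence to the
  original implementation. It has the right limits: it converges to the
  closed form as map distances grow and is strictly worse under complete
  linkage in repulsion.

Missing effect values contribute 0 (the population mean) and are flagged.
`summarize_pairs()` evaluates all n(n-1)/2 pairs and reports deciles plus
the favorable-tail 10th percentile (linear interpolation between order
statistics; for smaller-is-better traits that is the plain 10th
percentile). The favorable-tail reading of the published percentile is an
assumption, documented here.

## DEG calling and Venn accounting

FPKM is `counts * 1e9 / (length * libsize)` with library size the column
total. The thresholds are fixed by the study design: `P <= 0.05` and
`|log2FC| >= 0.807`, both inclusive. The source workflow names its
thresholds but not its test; this package uses a Welch t-test on
`log2(FPKM + 1)` across replicates, with the same pseudocount in the
fold-change, so the 0.807 threshold applies to a well-defined quantity.
No multiple-testing correction is applied by default (mirroring the raw
`P <= 0.05` rule); a BH-FDR flag exists. One behaviour worth knowing:
because FPKM normalises by the library total, heavily one-sided planted DE
shifts the apparent fold change of null genes (composition bias); the test
suite demonstrates this and keeps calibration checks on DE-free data.

`venn_partition()` does exact set arithmetic between two contrasts,
splitting shared genes by direction agreement; `intersect_gwas()` matches
DEG calls against GWAS gene lists after identifier normalisation.

## PPI statistics

`load_edges()` filters a STRING-style edge list at score `>= 0.18`
(inclusive), dropping self-loops and collapsing duplicate undirected edges
to the maximum score; 0-1000 export scales are autodetected (any score
above 1) and rescaled. Components and degrees come from igraph; a node is
a key hub when its degree strictly exceeds 10. `chunk_nodes()` reproduces
the size-capped random-even split used when an external PPI service limits
query size (7837 nodes at cap 2000 give groups of 1960/1959/1959/1959),
and `top_hubs_meta()` selects each group's top five hubs *including ties
at the fifth rank* — the tie rule is what lets four groups yield 21 rather
than 20 hubs — then builds their induced meta-network.

## The synthetic-data generator

`simulate_rils()` implements single-seed descent from the F1 of two fully
inbred parents. Meiosis uses the Haldane mapping function
`r = (1 - exp(-2d/100))/2` — the source is silent on interference, and
Haldane is the simplest self-consistent choice. "F7" means six selfing
rounds after the F1, leaving ~2^-6 residual heterozygosity per locus;
generation is a parameter because the true residual heterozygosity of the
emulated population is unstated. Intra-gene crossovers are not simulated:
gene bodies span ~2 kb, orders of magnitude below the per-cM scale.
Two RIL-level identities anchor the tests: the recombinant-line fraction
between loci at distance d is `R = 2r/(1+2r)`, and parental allele
frequencies stay at 1/2.

`simulate_phenotypes()` generates plot-level values
`y = mu + G_i + GE_ie + eps` and calibrates the noise so the ANOVA
estimators are centred on the target heritability decomposition. Two
calibration subtleties are deliberate:

* GEI effects are deviation-coded (they sum to zero across environments
  per line), so the interaction mean square estimates
  `sum(GE^2)/((a-1)(n-1))`, not the per-column variance, and line means
  carry no GEI. Solving the estimand equations gives the line-mean
  denominator `D = Vg / (h2_main + h2_gei)` and the GEI scale from the
  doubly-centred sum of squares. With this calibration the mean estimated
  partition over repeated simulations is within Monte-Carlo error of the
  targets (the suite checks +/- 0.03 at 67%/18%).
* `h2_poly` adds an unmapped polygenic background as an i.i.d. normal line
  effect — the generator-side counterpart of the polygene remainder: mapped
  QTL explain `h2_main - h2_poly`, the background the rest. The GWAS power
  experiments use 10 mapped QTL (R^2 2-10%) plus such a background to
  reach h^2 = 0.85 without planting additional mappable loci.

Raw mode back-constructs PH/NN plots whose `compute_sti()` output equals
the latent indicator exactly (equal node numbers in both conditions,
`PH_shade = PH_control x STI`); `simulate_cells()` does the analogue for
RCL with exact image means. The demonstration pipeline keeps the RCL
spread narrower than the empirical range so back-constructed micrograph
cell lengths stay positive (noise is also capped at 15% of the image
mean).

`simulate_expression()` draws negative-binomial counts (gene-wise
dispersion; variance `mu + phi mu^2`) with planted log2 fold changes of
random sign for each genotype's shade contrast, and stores the truth
table. FPKM is computed downstream, never simulated directly.

What the generator does *not* emulate: selection during line development,
epistasis, dominance (RILs are near-fully inbred), spatial field trends,
sequencing-level artefacts, and realistic LD beyond the simulated map.
Passing tests therefore demonstrate correctness of the algorithms under
the stated model, not robustness to every property of real field data.

## Performance checks the package runs on itself

The test suite's long-running block measures, at the study's scale
(n = 250 lines, h^2 = 0.85, 100 simulation runs): detection power >= 0.9
for QTL with R^2 >= 5%, with on average <= 1 selected locus falling
outside a 15 cM window of every planted QTL. The window definition
reflects mapping resolution: in a 250-line RIL population a marker a few
cM from the causal locus is statistically exchangeable with it. Null-trait
runs (no QTL) select a median of 0 loci — there the heritability estimate,
hence the cap, is near zero, and the experiment-wise threshold does the
rest. Variance-component recovery is checked over 500 replicates at
(2, 1, 3); the acceptance script reruns scaled-down versions of the same
experiments (30 GWAS runs, 25 heritability replicates) to keep its runtime
in minutes.

## A worked example

```{r, eval = FALSE}
report <- run_pipeline(list(seed = 1))
report
```

The default configuration simulates a 250-line population over 10
chromosomes (200 gene loci), phenotypes it in 3 environments x 3
replicates for the STI-like trait (targets 67% main + 18% GEI) and with 5
replicate values for the single-environment RCL-like trait, assembles
GASMs, runs both GWAS fits, predicts all-pair cross potentials, calls DEGs
in a 2000-gene expression matrix, and post-processes a synthetic PPI edge
list among the DEGs; the report verifies the accounting identities (gene
union, Venn union, pair counts, non-negative polygene remainders) before
returning. The PPI edge list is synthetic (random scored edges among the
called DEGs) because interaction prediction itself is outside the package's
scope — real edge lists are consumed through `load_edges()`.

## Known limitations

* The linkage-model potential is a Monte-Carlo operational definition (see
  above), with progeny count, generations, and quantile as configuration.
* Sequential R^2 attribution is order-dependent in principle; it is
  reported with entry order fixed by the selection path, and coincides
  with marginal R^2 on orthogonal designs (tested).
* The DEG caller is a deliberately simple thresholding method (the method
  under study), not a replacement for dispersion-modelling DE frameworks.
* Mixed-model (kinship) GWAS, Bayesian fine-mapping, imputation beyond
  match-or-missing, and multi-parent cross optimisation are out of scope.
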