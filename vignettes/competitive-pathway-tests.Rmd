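---
title: "Competitive pathway tests on scaled ranks: models, calibration, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive pathway tests on scaled ranks: models, calibration, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathrank)
```

## The competitive null and the scaled-rank device

Pathway analysis of GWAS results asks whether a predefined group of genes is
collectively associated with a phenotype. Two null hypotheses are in use. The
*self-contained* null says no pathway gene is associated; it is easy to
reject but fragile in GWAS, because small biases (population stratification,
genomic inflation) accumulate over the many genes of a pathway. The
*competitive* null says the pathway's genes are **no more** associated than
the genes outside it. Rejecting it means enrichment: relatively more signal
inside the pathway than in the genomic background. Competitive tests are
self-calibrating against study-wide inflation because any uniform bias
affects pathway and background genes alike.

`pathrank` turns classical p-value combination tests into competitive tests
with one device: replace each gene's p-value $p_k$ by its **scaled rank**

$$u_k = \frac{\operatorname{rank}(p_k)}{K}, \qquad k = 1, \dots, K,$$

where $K$ is the number of genes in the study. Under the competitive null a
random pathway's statistics are a uniform draw from the discrete set
$\{1/K, \dots, 1\}$, regardless of how the gene p-values were produced, so
any test calibrated for Uniform(0,1) inputs becomes a competitive test.
Because ranks are invariant to strictly monotone transforms, all
rank-consuming tests in the package give identical results on $p$, $p^2$ or
any other monotone rescaling of the gene p-values.

Ties among p-values are broken by input order (ordinal ranking), so $u$ is
always a full permutation of $\{1/K,\dots,1\}$. Ties have probability zero
for continuous association statistics; the choice only matters for
pathological inputs, and any deterministic rule keeps the product and
order-statistic tests well defined.

## The five tests

**Fisher's method (FM).** $T = -2\sum_{k=1}^{L}\ln u_k$ over the $L$ pathway
genes; under independent Uniform inputs $T \sim \chi^2_{2L}$. The inputs here
are discrete and drawn without replacement, but at genome scale
($K = 20000$) the $\chi^2$ reference is indistinguishable from the
permutation null, which the test suite checks directly. A gene-label
permutation mode (redraw $L$ of $K$ ranks, $B$ times) is also provided.

**Hypergeometric over-representation.** Fix a significant-gene list (by
default the $n = 2000$ smallest p-values) and count pathway members in it;
the one-sided p-value is the hypergeometric upper tail. With short
significant lists the test's discrete support makes an exact 5% level
unattainable and the test conservative; the top-2000 variant restores
near-nominal calibration, which is why it is the default.

**Tail strength measure (TSM).** With the pathway's ranks sorted,
$TS = \frac1L \sum_k (1 - u_{(k)} \frac{L+1}{k})$ measures the average
standardized shortfall of each order statistic below its null expectation.
Three calibrations are available: the large-sample normal approximation
$N(0, 1/L)$, an empirical null of $TS$ over i.i.d. Uniform(0,1) draws of
size $L$ (the recommended variant, `tsm_e`), and gene-label permutation.
The exact null variance, $[(L+1)(L - H_L) + L]/(L^2(L+2))$ with $H_L$ the
harmonic number, is strictly below $1/L$ (0.041 vs 0.050 at $L = 20$), and
$TS$ is skewed at database-typical pathway sizes, so the normal mode is
deliberately conservative — reproduced as a pooled type-I error around
0.03 in the acceptance suite.

**GSEA-type weighted KS statistic.** Gene statistics $t_k = -\ln p_k$ are
ranked from largest to smallest; a running sum gains
$|t_j|^{w}/N_R$ at pathway hits ($N_R$ the sum of hit weights, $w = 1$ by
default) and loses $1/(K - L)$ at misses; the enrichment score is the
signed maximum of the walk — a one-sided, enrichment-at-top test.
Significance comes from $B$ random same-size gene subsets. This is the one
test whose statistic depends on p-value magnitudes, not only ranks; its
p-value remains label-permutation calibrated. Zero p-values are clamped to
the smallest positive double before the log; if every pathway gene has
$p = 1$ the hit weights degenerate and the walk falls back to unweighted
increments $1/L$.

**Adaptive rank truncated product (ARTP).** $W(j) = \prod_{k \le j} u_{(k)}$
combines the $j$ smallest pathway ranks; $-2\ln W(L)$ is exactly the FM
statistic. The adaptive version scans all truncation points $j = 1..L$ and
takes the one minimizing the estimated p-value $\hat p_j$. Significance uses
Ge's single-level scheme: one set of $B$ null rank-vectors serves
simultaneously to estimate every $\hat p_j$ (pooled over all $B+1$
replicates including the evaluated one, so observed and null replicates are
exchangeable and every $\hat p_j \ge 1/(B+1)$) and to calibrate the minimum
$\min_j \hat p_j$ — avoiding a nested permutation layer. Ties in
$\arg\min_j$ report the smallest $j$, a deterministic, parsimonious choice.
Null rank-vectors come either from gene-label permutation ($L$ of the $K$
scaled ranks without replacement) or from i.i.d. Uniform(0,1) draws
(`artp_e`); the continuous version is a negligibly different, reusable
approximation at genome scale.

## The simulator and what it emulates

`simulate_gwas()` reproduces a deliberately stylized quantitative-trait
GWAS: minor allele frequencies $q_j \sim$ Uniform(0, 0.5); genotypes 0/1/2
drawn per SNP under Hardy–Weinberg proportions; a sparse effect vector
($M$ SNPs with $\beta \sim N(0, \sigma^2)$); phenotype
$y = G\beta$; and per-SNP simple-regression p-values (slope t-test,
$N - 2$ df). One SNP is one gene.

Two modelling choices deserve emphasis:

* **No separate environmental noise by default.** The phenotype equation is
  additive in the effect SNPs; with dozens of effect SNPs, the other
  $M - 1$ effects already act as the noise background for any single SNP.
  A `noise_sd` knob exists for sensitivity analysis, and the power levels
  the acceptance suite reproduces confirm that the noiseless default matches
  the reference behaviour.
* **Null vs alternative scenarios.** Under the null, effect SNPs and pathway
  members are drawn independently, so the pathway is exchangeable with any
  random gene set — the competitive null exactly. Under the alternative,
  $\operatorname{round}(\pi L)$ pathway genes receive effects with variance
  $\sigma_1^2$ and $M - \operatorname{round}(\pi L)$ outside genes with
  variance $\sigma_2^2 < \sigma_1^2$; larger pathway effect variance is what
  makes the pathway *relatively* more associated.

What the simulator does **not** emulate: linkage disequilibrium between
SNPs, multi-SNP genes (hence no gene-size bias inside the simulation),
case-control traits, and population structure. Passing calibration and
power checks on these data therefore demonstrates correctness of the
statistical machinery under idealized sampling, not robustness to the
correlation structure of real genotype panels. For real inputs the package
expects the SNP-level biases to be handled upstream, and supplies
`map_snps_to_genes()`, `gene_min_p()` and `adjusted_gene_p()` (per-gene
phenotype-permutation calibration, which removes the gene-size bias of
minimum-p statistics) as the bridge from per-SNP summary statistics to the
per-gene inputs the tests consume.

## Study conditions and problem sizes

The scenario grids mirror the reference study conditions: $N = 100$
individuals, $K = 20000$ genes; null grid = pathway size
$L \in \{20, 60, 100\}$ $\times$ effect count $M \in \{50, 100, 200\}$
$\times$ effect variance $\sigma^2 \in \{1, 2, 4\}$ (27 scenarios); power
family $L = 20$, $M = 50$, $(\sigma_1^2, \sigma_2^2) = (4, 1)$ with
$\pi \in \{0.4, 0.6, 1.0\}$. These defaults are the study conditions, not
tuning knobs. The acceptance script runs the full null grid at 200
replicates per scenario (pooled $n = 5400$, SE $\approx 0.003$) and each
power scenario at 300 replicates (SE $\le 0.03$); the test suite uses 60
and 200 replicates with 3-SE assertions at those counts. Replicate counts
are the package's own desk-scale choice; all other conditions are fixed.

## Numerical and design choices

* **Permutation p-values** use the add-one convention $(1 + c)/(1 + B)$ with
  ties counted as extreme: never zero, bounded below by $1/(B+1)$, standard
  bias correction.
* **Null caching.** Scaled ranks of a complete study are always the fixed
  set $\{1/K, \dots, 1\}$, so the empirical-uniform *and* the gene-label
  permutation nulls of TSM/ARTP depend only on $(K, L)$. The scenario driver
  builds them once per scenario and reuses them across replicates; this
  introduces a small shared-null correlation between replicate p-values
  (slightly wider Monte-Carlo error on pooled rates, no bias) and is what
  makes thousand-replicate grids run on a desk machine. Fresh draws per call
  remain the default in the user-facing tests.
* **Per-replicate seeds** are derived from (master seed, scenario id,
  replicate index), so any scenario can be reproduced in isolation and
  method subsets see identical data streams.
* **Empirical-uniform order statistics** are generated by the backward
  recursion $U_{(L)} = V_L^{1/L}$, $U_{(k)} = U_{(k+1)} V_k^{1/k}$,
  vectorized across replicates, avoiding per-replicate sorting; TSM nulls
  are built in bounded-memory chunks.
* **Compiled hot paths.** Genotype sampling ($N \times K$ per replicate) and
  the $B = 1000$ GSEA subset-null loop are C++ (Rcpp) using R's RNG stream,
  so `set.seed()` reproducibility is preserved bit-for-bit.
* **Degenerate inputs.** Monomorphic genotype columns get $p = 1$ rather
  than NaN; $p = 0$ is clamped only where a log is taken (GSEA weights),
  never in the rank computation; pathways are always intersected with the
  study universe first, and the minimum post-intersection size defaults to
  2 (the KS walk needs at least one hit and one miss; the combination tests
  are defined, if degenerate, at size 1).
* **SNP-to-gene mapping** measures distance to the strand-aware coding
  start, breaks exact ties by the lexicographically smaller gene id, and
  exposes the window (default 10 kb) as an argument because the appropriate
  distance is study-specific. Coordinates are 1-based inclusive; BED input
  is converted on read.

## Known limitations

* The chi-square reference for FM and the $N(0, 1/L)$ reference for TSM are
  asymptotic conveniences; for small $L$ or small $K$ prefer the empirical
  or permutation modes.
* ARTP p-values inherit the $1/(B+1)$ granularity of the permutation
  scheme; multi-pathway studies needing very small p-values must raise `B`.
* The package reports nominal per-pathway p-values only; multiplicity
  across pathways or databases is left to the analyst.
* Nothing in the package corrects for LD-induced correlation between
  gene-level p-values; with correlated inputs the gene-label permutation
  null remains valid for exchangeable pathways but the analytic references
  do not.

## A worked miniature

```{r example, eval = FALSE}
set.seed(1)
scn <- scenario("alternative", L = 20, M = 50, N = 100, K = 20000,
                pi = 0.4, sigma1_sq = 4, sigma2_sq = 1)
sim <- simulate_gwas(scn, seed = 1)
scores <- sim_scores(sim)
pathway <- scores$gene_id[sim$pathway_idx]

dplyr::bind_rows(
  fisher_test(scores, pathway, pathway_name = "planted"),
  artp_test(scores, pathway, B = 1000, null_source = "empirical_uniform",
            seed = 2, pathway_name = "planted"),
  gsea_test(scores, pathway, B = 1000, seed = 3, pathway_name = "planted"),
  tsm_test(scores, pathway, seed = 4, pathway_name = "planted"),
  hypergeometric_test(scores, pathway, pathway_name = "planted")
)
```

The README shows the printed output of this example together with a small
type-I error run; the acceptance script (`scripts/acceptance.R`) recomputes
the full calibration and power tables from scratch.
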