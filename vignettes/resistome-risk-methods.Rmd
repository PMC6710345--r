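---
title: "Methods: heavy-metal risk scoring and resistome co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heavy-metal risk scoring and resistome co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`resistrisk` analyses soil gradients contaminated by multiple heavy metals
together with qPCR panels of bacterial resistance genes: metal resistance
genes (MRGs), antibiotic resistance genes (ARGs) and mobile genetic element
markers (MGEs, e.g. the class 1 integron integrase *intI1* and the
transposase *tnpA*). It covers four stages — ecological risk scoring,
abundance processing, site statistics, and co-occurrence network inference —
plus a synthetic-data generator that provides datasets with known ground
truth for every stage.

## Potential ecological risk index

For metal $i$ with measured concentration $C_D^i$ (mg/kg dry soil) and
regional background $C_R^i$, the contamination factor is

$$C_f^i = C_D^i / C_R^i,$$

the monomial potential ecological risk factor is $E_r^i = T_r^i \, C_f^i$
with $T_r^i$ the Hakanson toxic-response factor
(Zn 1 < Cr 2 < Cu = Pb = Ni 5 < As 10 < Cd 30), and the integrated index is
$RI = \sum_i E_r^i$ per sample. All three are dimensionless and
non-negative, and $E_r$ is linear in concentration, so site means of $E_r$
equal $T_r \cdot \bar{C}_D / C_R$ exactly — the property the golden tests
exploit.

Two reference profiles ship with the package. `"default"` carries the
textbook toxic-response ordering above. `"table2-compat"` sets
$T_r(\mathrm{Ni}) = 2$: the published per-site Ni risk factors of the
copper-tailings study this package is modelled on are arithmetically
consistent only with that value, while the accompanying text states 5. The
package does not guess which was intended; both profiles are explicit
arguments and the profile used is logged by the pipeline. Background values
are configuration, not constants.

Two further numerical choices were genuinely open:

* **Contribution to RI.** The per-metal contribution column is computed as
  the unweighted mean over site means of $E_r$, divided by the unweighted
  mean over site means of $RI$, times 100. Sites count once each regardless
  of sample size (3 vs 9 here); this is the only formula that reproduces
  every published percentage exactly, and a sample-weighted variant is
  available through the `weights` argument of `contribution_to_ri()`.
* **Dispersion.** Site summaries report the sample standard deviation
  (denominator $n-1$); a single-sample site reports `NA` rather than 0.
  Report tables round half-up to 2 decimals for display only — internal
  values are never rounded.

## Abundance processing

qPCR triplicates are collapsed by averaging the replicates that amplified;
a sample–gene combination with fewer than `min_detect` (default 2 of 3)
amplifying replicates is a non-detect. Non-detects are stored as explicit
zeros with a parallel logical detect mask rather than as missing values, so
rank-based statistics downstream stay computable, and a gene counts as
"detected at a site" when detected in at least one sample of that site.
Copies (not Ct values) are averaged by default; the standard-curve helpers
convert between the two via $copies = 10^{(Ct - b)/m}$ for slope $m < 0$ and
intercept $b$, with amplification efficiency $10^{-1/m} - 1$.

Relative abundance is the gene's copies divided by the same sample's 16S
rRNA gene copies — an approximation of the fraction of bacteria carrying
the gene — and is invariant under any per-sample rescaling of absolute
values. 16S operon multiplicity is deliberately not corrected for.

Before parametric site tests, values are square-root or natural-log
transformed. The log transform needs a pseudocount when non-detect zeros
are present; the rule is half the smallest nonzero value in the table,
applied only if zeros exist and reported via a message, so fully-detected
tables are transformed exactly.

## Site statistics

One-way ANOVA uses the classical between/within decomposition through
`stats::lm`. Degenerate layouts get explicit conventions: no variance at
all gives $F = 0$, $p = 1$; distinct means with zero within-group variance
give $F = \infty$, $p = 0$.

Duncan's multiple range test compares ranked group means: a range spanning
$p$ consecutive means is significant when it exceeds
$q_{1-(1-\alpha)^{p-1}}(p, \nu)\sqrt{MSE/n_h}$, with studentized-range
quantiles from `stats::qtukey` and the harmonic mean $n_h$ of group sizes
(the study design has $n = 3$ at one site and $n = 9$ elsewhere). The
*protected stepwise* form is implemented: subranges of a non-significant
range are declared non-significant without further testing. This matters
because it guarantees that non-significance is interval-structured along
the mean ranking, which is exactly the condition under which a compact
letter display can represent the significance matrix without loss — the
test suite asserts that reconstruction equivalence on random data. Letters
start at "a" on the largest mean.

Spearman correlations use average ranks and the product-moment formula on
ranks. Two-tailed p-values default to the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$; perfect correlations are reported at the
permutation bound $2/n!$ instead of 0. For small samples
(`p_method = "exact"`, $n \le 9$) the exact permutation distribution is
enumerated in full. Constant variables have undefined rank correlation and
are reported as `NA`, never coerced to 0. No multiple-testing correction is
applied to correlation matrices by default, matching the unadjusted
pairwise reporting practice this workflow mirrors; Benjamini–Hochberg is
available via `correlation_long(..., adjust = "BH")`.

## Co-occurrence network

An edge joins two variables when $|\rho|$ strictly exceeds the threshold
(default 0.6) **and** $p$ is strictly below the significance threshold
(default 0.05). The absolute value is used because negative correlations
are retained as (signed) edges. The variable set is the per-sample relative
abundances plus eight risk components: the seven per-metal $E_r$ series and
the integrated $RI$. Correlations are computed on all samples pooled across
sites; this is documented as an assumption rather than a fact about the
original study, which does not state it. Note that per-metal $E_r$ is a
global monotone transform of the metal's concentration, so its pooled rank
correlations — and hence its edges — are identical to the raw metal's.

Modules are communities found by Louvain multi-level modularity
maximization (igraph) on $|\rho|$ edge weights, with an explicit seed;
a deterministic fast-greedy agglomeration is available as
`method = "greedy"`. Degree-0 nodes form singleton modules. The hub of each
non-singleton module is the node with maximal within-module degree, ties
broken by the larger within-module sum of $|\rho|$, then lexicographically;
the tie-break path is recorded in the hub table. Exports (GraphML, GEXF
1.2, TSV edge + node tables) carry category, module, degree and hub flags
and are round-trip tested to 1e-12 on weights; no layout or rendering is
computed.

## Synthetic-data generator

The generator emulates the study conditions: four sites (3/9/9/9 samples),
seven metals with per-site lognormal marginals moment-matched to the
published site means and standard deviations, and a panel of 10 MRGs,
17 ARGs, 2 MGEs and 16S with baseline copy numbers chosen so class
compositions echo the study's qualitative pattern (*arsC* dominant among
MRGs, *ereA* among ARGs; 16S near $10^9$ copies with site factors making
the dam-top site poorest). Planted structure mirrors the study's headline
findings: an MRG block co-varying with Cd at target Spearman 0.7 that
includes *sulII*, *copB* co-varying with an ARG block, and *intI1*
structurally absent at the dam-top site.

Dependence is induced by a Gaussian copula: target Spearman correlations
are converted to latent Pearson correlations via the exact bivariate-normal
identity $r = 2\sin(\pi\rho/6)$, the latent matrix is checked for positive
definiteness (with a nearest-PD suggestion on failure), and marginals are
mapped to lognormals with $\sigma^2 = \log(1 + s^2/m^2)$,
$\mu = \log m - \sigma^2/2$. Lognormal marginals were chosen because both
concentrations and copy numbers are positive and right-skewed; the
generative family is the package's own choice, not an estimate from data.
Gene copies are rounded to integers *after* correlation induction — the
small rank distortion this causes is covered by the ±0.05 recovery
tolerance verified at $n = 1000$ — and structural zeros are applied last,
so they are exact in every replicate (a structural zero on 16S is refused).

What the generator does **not** emulate: spatial structure along the
dam-to-stream gradient (sites are exchangeable groups), compositional
closure, PCR inhibition or efficiency drift, taxon-level community
structure, and between-class correlation beyond the planted blocks and
shared site effects. Tests passing on synthetic data therefore validate
the computational pipeline, not field-scale ecological claims.

## Validation problem sizes

The suite validates each stage at deliberately modest sizes: exact
Spearman permutation p against independent enumeration at $n = 5..7$;
Duncan decisions against a pair-by-pair stepwise oracle on 100 random
4-group datasets; network edge sets against brute-force pair enumeration
on 20 random 10-variable tables; planted 3-block module recovery
(within-block edge probability 0.9, between 0.05) with adjusted Rand
index averaged over 20 seeds; marginal-moment recovery at $n = 10^4$ and
rank-correlation recovery at $n = 10^3$. The published site-mean table is
reproduced exactly for As, Cr, Cu, Pb, Zn (and Ni under `table2-compat`);
Cd is excluded because the published Cd risk means are not consistent with
the published Cd concentration means under any stated factor combination
(presumably rounding of the printed means), and the comparison tolerance is
half a unit in the last *printed* digit.

## Known limitations

* Duncan's test is implemented only in its protected stepwise form; the
  unprotected pair-by-pair variant some software reports can differ on
  configurations where an inner range exceeds its critical value while an
  enclosing range does not.
* The t approximation for Spearman p is anti-conservative at very small
  $n$; use `p_method = "exact"` below $n = 10$.
* Louvain module assignments on near-threshold networks can change with
  the seed; the seed is part of the run configuration and recorded in the
  manifest.
* Absolute abundance units are carried as opaque metadata; no per-gram
  conversion is attempted.
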