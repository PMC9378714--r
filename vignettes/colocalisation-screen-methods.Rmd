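---
title: "Methods: a colocalisation-first protein prioritisation screen"
author: "colocscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a colocalisation-first protein prioritisation screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colocscreen)
```

# The problem

Plasma protein abundances are heritable, and a genetic variant that changes
a protein's abundance (a cis-pQTL, lying near the protein-coding gene) can
serve as an unconfounded instrument for asking whether that protein affects
a disease outcome. The difficulty is linkage disequilibrium (LD): a pQTL
and a disease association may sit in the same region yet be driven by
different causal variants carried on the same haplotypes. `colocscreen`
implements a *colocalisation-first* design: before any causal effect is
estimated, each protein-outcome region must show evidence that the two
association signals arise from one shared causal variant, and must survive
two LD-based robustness guards. Only then is a Wald-ratio
Mendelian-randomisation (MR) estimate computed and the pair assigned a
significance tier.

# Pairwise colocalisation model

For each variant $j$ with effect estimate $\hat\beta_j$ and standard error
$s_j$, the evidence for association is the Wakefield asymptotic Bayes
factor under a normal effect prior $N(0, W)$:

$$\log \mathrm{ABF}_j = \tfrac12\log(1-r_j) + \tfrac{z_j^2 r_j}{2},
\qquad r_j = \frac{W}{s_j^2 + W},\ z_j = \hat\beta_j/s_j .$$

This is the exact marginal-likelihood ratio
$N(\hat\beta_j; 0, s_j^2+W)/N(\hat\beta_j; 0, s_j^2)$; the tests verify it
against numerical quadrature. The effect-size prior standard deviation
$\sqrt W$ defaults to 0.15 for quantitative traits on the standardised
scale and 0.2 on the log-odds scale for binary traits — the conventional
defaults of this method family.

Assuming at most one causal variant per trait in the region, the five
regional hypotheses are H0 (no signal), H1/H2 (only trait 1 / only trait
2), H3 (two distinct causal variants) and H4 (one shared causal variant).
With per-variant prior probabilities $p_1$, $p_2$ (single-trait causal) and
$p_{12}$ (shared causal), the unnormalised hypothesis weights are

$$L_0 = 1,\quad L_1 = p_1 S_1,\quad L_2 = p_2 S_2,\quad
L_3 = p_1 p_2 (S_1 S_2 - S_{12}),\quad L_4 = p_{12} S_{12},$$

with $S_1 = \sum_j b_{1j}$, $S_2 = \sum_j b_{2j}$,
$S_{12} = \sum_j b_{1j} b_{2j}$ over the harmonised shared variant set.
All sums are carried in the log domain via log-sum-exp; $L_3$ is a guarded
difference of exponentials (a negative remainder from cancellation is
clamped to zero with a warning). Defaults $p_1 = p_2 = 10^{-4}$,
$p_{12} = 10^{-5}$. Posterior probabilities are $L_i / \sum_k L_k$, and the
engine is tested to $10^{-10}$ against brute-force enumeration of all
$(Q+1)^2$ causal-configuration pairs.

Robustness to the priors is assessed over a 3×3×3 grid
($p_1, p_2 \in \{10^{-4},10^{-5},10^{-6}\}$,
$p_{12} \in \{10^{-5}, 5{\times}10^{-6}, 10^{-6}\}$); points violating
$p_{12} \le \min(p_1,p_2)$ are skipped and a pair is called robust when
PP(H4) exceeds the candidate threshold at every retained point. PP(H4) is
provably non-decreasing in $p_{12}$ at fixed $p_1, p_2$, which the tests
exercise as a property.

## Robustness guards and tiers

Two guards reject candidate pairs whose data violate the single-causal-
variant assumption even when PP(H4) is high:

* **Instrument representation** — the lead cis-pQTL, or a proxy with
  $r^2 > 0.8$, must be present in the overlapping variant set used for
  colocalisation.
* **Sentinel concordance** — the two traits' regional lead variants
  (smallest p; ties by larger $|z|$, then lower position) must be in strong
  LD, $r^2 > 0.8$, strict. A region with PP(H4) = 0.93 but sentinel
  $r^2 = 0.12$ is rejected; so is 0.79; 0.85 passes.

Surviving pairs are tiered on regional minimum p-values: tier 1 — both
traits genome-wide significant ($p < 5\times10^{-8}$); tier 2 — exactly
one; tier 3 — both strictly between $5\times10^{-8}$ and $10^{-4}$. All
inequalities are strict, so a p-value exactly at a bound falls on the
non-significant side. A pair matching none of the rules (one trait
sub-suggestive without genome-wide significance on the other side) gets
`NA`: the three published rules leave that corner undefined, and we flag
rather than guess.

# Mendelian randomisation

For a candidate pair the lead cis-pQTL provides a single-instrument Wald
ratio $\hat\theta = \hat\beta_{out}/\hat\beta_{exp}$ — the log-odds change
in the outcome per 1 s.d. higher protein abundance — with first-order
standard error $|s_{out}/\hat\beta_{exp}|$, ignoring exposure-side
uncertainty. The first-order form was chosen because at the effect
magnitudes this screen operates on (exposure $|z| \gg 4$) second-order
corrections are negligible, and the published confidence intervals this
design reproduces are numerically consistent with the first-order formula.
Instruments with exposure $|z| < 4$ are flagged weak but reported, because
a screen should report rather than silently drop. CI coverage of the 95%
Wald interval is verified by simulation to lie in the nominal range for
strong instruments.

# Multi-trait colocalisation

`shared_pp()` evaluates a deliberately simplified hypothesis space over
$m \ge 2$ traits: the null, each one-trait-only alternative
($L_t = p_{single}\sum_j b_{tj}$) and full sharing
($L_{share} = p_{shared}\sum_j \prod_t b_{tj}$), with defaults
$p_{single} = 10^{-4}$, $p_{shared} = 10^{-5}$ consistent with the pairwise
priors. For $m = 2$ and matched priors this reproduces the pairwise
posterior with the H3 mass removed — an identity the tests assert.

Cluster discovery is greedy and divisive. A subtlety matters here: in the
three-hypothesis space above, a strongly associated outlier trait driven by
a *distinct* nearby variant cannot lower the full-set sharing posterior,
because the sharing weight competes only against the null and single-trait
weights, which the signal dwarfs either way. The division statistic
therefore extends the space with, for each member of a group of three or
more, an "all-but-one" competitor — the remaining traits share a causal
variant while the excluded trait is separately associated. With these
competitors present, a group containing an outlier scores low, the search
removes the trait whose exclusion maximises the remainder's statistic, and
the outlier is expelled; removed traits are re-clustered among themselves
and singletons are reported unclustered. Each emitted cluster reports its
sharing posterior, the regional association probability, the candidate
causal variant (argmax of the per-SNP shared posterior, ties broken by
position) and the proportion of posterior mass that variant explains.

# Conditional adjustment

Regions with multiple independent signals violate the single-causal-variant
assumption. `conditional_adjust()` removes known lead signals $S$ from the
regional z-scores with the summary-statistics decomposition
$z'_j = z_j - R_{jS} R_{SS}^{-1} z_S$, reconstructing effects as
$z'_j s_j$ with standard errors held fixed — a first-order approximation,
documented as such; with exactly standardised genotypes this equals
ordinary-least-squares residualisation of the association cross-products,
which the tests verify to $10^{-8}$. Lead sets whose LD submatrix has
condition number above $10^8$ are refused with the collinear leads named.

# Fine-mapping with cross-ancestry prior transfer

Under a single causal signal, posterior inclusion probabilities are
$\mathrm{PIP}_j \propto \pi_j \mathrm{BF}_j$. The stepwise two-ancestry
procedure fine-maps the better-powered ancestry under equal priors, then
uses its PIPs — floored at $1/(10Q)$ and renormalised — as priors for the
second ancestry. The floor prevents stage 1 from irreversibly zeroing a
variant that stage 2 could rescue; variants present only in the second
ancestry also receive the floor. The model is deliberately single-signal:
the intended workflow removes secondary signals with
`conditional_adjust()` first, a scope reduction relative to multi-causal
shotgun searches. The scientific payoff is LD-resolution: an ancestry with
shorter LD blocks thins the set of variants co-segregating with the causal
one, so transferred priors concentrate posterior mass on it — the
simulations show the causal variant's stage-2 PIP exceeding its
uniform-prior PIP in the short-block ancestry.

# Synthetic data

The generator exists so every pipeline property can be tested against a
known truth; it emulates the statistical structure the colocalisation model
assumes, not population-genetic realism.

* **Panels** (`simulate_panel()`): haplotypes from a first-order Markov
  copying process — within an LD block each haplotype copies its previous
  allele with probability `rho`, else draws fresh at that variant's
  frequency; blocks are independent; dosages pair consecutive haplotypes.
  Defaults: 2,000 haplotypes, 100 variants, blocks of 20, `rho = 0.9`,
  allele frequencies uniform on (0.05, 0.5). The two-ancestry generator
  uses blocks of 20 vs 5 to mimic European- vs African-ancestry LD decay.
* **Summary statistics** (`simulate_sumstats()`): marginal z-scores drawn
  jointly as $z \sim \mathrm{MVN}(\sqrt{n}\,R\lambda,\ R)$ with $R$ the
  panel LD matrix (eigenvalue-clipped to positive semi-definite when
  needed) and $\lambda$ the standardised joint-effect vector, so the causal
  variant's expected $|z|$ is $\sqrt{n \cdot ve}$. On the standardised
  scale $se = 1/\sqrt n$ exactly; binary traits use the effective sample
  size $n\phi(1-\phi)$ with case fraction $\phi$. Statistics are simulated
  directly at the z level for speed; an individual-level regression path
  exists only as a test oracle at small n.
* **Study conditions**: scenario defaults are a quantitative exposure at
  $n = 10{,}000$ with 1% variance explained (causal $|z| \approx 10$) —
  the regime in which recovery properties are stated. The screen-level
  generator plants protein signals at those conditions and gives binary
  outcomes $n = 40{,}000$ at case fraction 0.5 (effective n 10,000),
  reflecting that disease meta-analyses are far larger than proteomic
  GWAS; distinct-signal (H3) outcome variants are placed in a different LD
  block from the protein's causal variant so their $r^2$ is near zero.

What passing tests therefore show is that the machinery is correct under
its own model: exchangeable Gaussian z-scores, one causal variant per
trait, LD exactly equal to the panel's. They do not show robustness to
imputation error, allele-frequency mismatch between panel and GWAS,
overlapping samples between traits, or multi-causal regions — all known
limitations of single-signal colocalisation in real data.

# Numerical and design choices

* All Bayes-factor arithmetic is log-domain; posteriors sum to 1 within
  $10^{-10}$ by construction and by test.
* Harmonisation matches exact and swapped allele pairs only; no strand
  flips are attempted (silent strand errors are worse than dropped
  variants). Palindromic A/T and C/G variants are dropped when either
  table's minor-allele frequency lies in [0.40, 0.50], configurable, and
  only when both tables carry frequencies.
* Strict inequalities at every published threshold ($r^2 > 0.8$,
  $p < 10^{-5}$, PP > 0.8, tier bounds), so values exactly at a threshold
  are conservative.
* Missing study coverage is treated as full coverage: single-cohort data
  have no meta-analysis structure to be under-covered in.
* LD is genotype (dosage) correlation with pairwise-complete missing
  handling; variants with more than 10% missingness are refused.
* Sentinel ties break by larger $|z|$, then lower position, making every
  screen output a deterministic function of inputs, configuration and
  seed.
* Problem sizes in the test-suite simulations (regions of 80–100 variants,
  panels of 500–1,000 samples, 200 replicates for recovery medians, 50
  end-to-end screen runs) were chosen as the smallest at which the stated
  regimes are comfortably expressed; the p-value/z consistency check and
  recovery medians are insensitive to region size in this range.

# Interfaces

The exported functions are the interface; a typical run is
`read_sumstats()` → `extract_region()` → `harmonise_pair()` →
`study_coverage_filter()` → `abf_vector()` → `coloc()` → guards → tiers →
`wald_ratio()`, or simply `run_screen()` over catalogues of tables, with
`write_report()` for TSV/JSON output. Column presets exist for the two
summary-statistics dialects the screen was designed around
(`column_preset("pgwas")`, `column_preset("covid_hgi_r6")`).
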