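---
title: "Disease signatures, signature reversion, and how this package validates them"
author: "sigrev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease signatures, signature reversion, and how this package validates them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Signature reversion is a computational drug-repurposing strategy: given a
disease-associated gene signature (disjoint sets of genes up- and
down-regulated in tumor relative to control tissue), it searches a reference
of drug perturbation profiles for compounds whose transcriptional effect is
most *inverse* to the disease signature, on the premise that such compounds
may push the diseased expression state back toward normal.

The package implements the full workflow three times over, because the
signature itself can be constructed by different routes that select largely
different genes:

1. **Moderated linear models** (`moderated_lm_de()`): gene-wise linear
   models of `log2(TPM + 1)` on condition plus a source-database covariate,
   with empirical-Bayes variance moderation and Bonferroni adjustment.
2. **Negative-binomial GLMs** (`nb_glm_de()`): count-level models with
   median-of-ratios size factors, dispersion shrinkage and Wald tests,
   Benjamini-Hochberg adjustment, and fold changes shrunk under a
   zero-centered normal prior.
3. **Latent-variable transfer learning** (`project_latent()`,
   `differential_lv()`, `build_tl_signature()`): expression is projected
   onto a sparse non-negative loading matrix learned on a large compendium,
   latent variables are tested for condition association, and the signature
   is harvested from the top-weighted genes of the significant latent
   variables.

Each signature is then scored against every drug of a perturbation
reference by the bi-directional weighted Kolmogorov-Smirnov connectivity
statistic, normalized, ranked, filtered, and finally validated against
orthogonal annotations (clinical-trial membership, viability screens, drug
networks, ontology enrichment).

## The scoring model

For a query set $S$ of size $m$ against a profile of $G$ genes ranked by
decreasing z-score, the running sum gains $|z_i| / \sum_{j \in S} |z_j|$ at
each hit and loses $1/(G - m)$ at each miss; the enrichment score
$ES \in [-1, 1]$ is the signed extremum of largest absolute value (ties of
absolute value, which arise only in degenerate symmetric profiles, resolve
to the extremum reached earliest in the ranking). The bi-directional score
is

$$\mathrm{WTCS} = \begin{cases}
(ES_{up} - ES_{down})/2 & \text{if the signs differ or either is } 0 \\
0 & \text{otherwise,}
\end{cases}$$

so a perfect reverser (up genes at the bottom of the drug's ranking, down
genes at the top) approaches $-1$. WTCS values are normalized within a cell
line by the signed mean of the same-sign scores (NCS), and Tau is the
signed percentile of $|NCS|$ against a bank of random matched-size query
signatures: Tau $= -100$ means the observed negative connectivity is more
extreme than every bank score for that drug. Candidates must satisfy
NCS $< 0$, permutation FDR $< 0.05$ and Tau $< -80$ (all strict), and be
FDA-approved.

### Permutation p-values

The null bank consists of random up/down gene sets of the query's sizes
drawn from the reference universe; the same bank serves the Tau reference
and the permutation null. The one-sided (reversal-tail) p-value is the rank
of the observed WTCS among its per-drug null values. Because WTCS has a
point mass at zero (the same-sign rule) the rank is tie-broken uniformly at
random (seeded): this makes the p-value *exactly* uniform under the null,
and whenever there are no ties — in particular for every drug in the
negative candidate tail — it equals the plain
$(1 + \#\{null \le obs\})/(N+1)$. The trial and viability-screen enrichment
p-values use the same construction on the upper tail.

### The 3-standard-deviation latent cutoff

Latent variables are called significant when the Bonferroni-adjusted
p-value is below 0.05 *and* the absolute effect reaches a data-derived
cutoff: with $u = \bar e + 3s$ and $l = \bar e - 3s$ over the per-LV
effects, the cutoff is $(|u| + |l|)/2$ rounded to two decimals (bounds of
0.27 and −0.23 give 0.25). This rule is meaningful only when the truly
associated latent variables are outliers among many mostly-null ones —
which is how the synthetic generator is configured (see below). The
label-switch validation (`label_switch_validation()`) instead uses the
fixed effect cutoff 0.05, because its purpose is to track the *count* of
significant latent variables under progressive destruction of the
gene-label alignment.

## What the synthetic generator emulates

`simulate_all()` produces every input of the pipeline with planted ground
truth, so each stage can be tested without any external download:

* **Counts**: negative binomial,
  $\mu = \text{baseline} \cdot 2^{\beta_g x + \delta_{g,db}}$ with
  log-normal baselines, dispersion 0.1, and per-gene offsets
  $\delta \sim N(0, 0.25^2)$ for the non-reference database. Exactly
  $\lceil \text{frac\_de} \cdot G \rceil$ genes carry $\beta = \pm$
  `lfc_scale`. Tumor samples come from the first database and controls are
  spread over all of them, mimicking a tumor compendium complemented by an
  external normal-tissue compendium. Gene lengths are log-uniform on
  0.5–10 kb (needed only for TPM).
* **Loadings**: each latent variable has exactly
  $\lceil \text{lv\_sparsity} \cdot G \rceil$ nonzero non-negative weights.
  Active latent variables draw their support from the planted genes of a
  single effect sign (alternating across active LVs), so their projected
  activity separates the conditions without up/down cancellation.
* **Perturbations**: drug profiles are standard normal z-scores; planted
  reversers additionally carry $-$`reverser_strength`$\cdot \mathrm{sign}(\beta_g)$
  on the planted genes. Annotations (trial membership, screen sensitivity)
  are enriched for reversers at configurable odds; reversers are always
  FDA-approved (the candidate filter is restricted to approved drugs) and
  share a fingerprint bit block.
* **Independent substreams**: counts, loadings and perturbations each use
  their own stream derived from the master seed, so changing `n_drugs`
  never perturbs the counts.

Defaults (2000 genes, 40 + 40 samples, 5% planted genes at $|\beta| = 2$,
100 LVs at 2.5% sparsity with 5 active, 100 drugs with 10 reversers at
strength 3, annotation odds 8) were chosen once as a realistic regime: the
number of planted genes of one sign equals an active LV's support size (no
dilution), and active LVs are genuine outliers among 100 LVs, the regime in
which a 3-SD outlier rule makes sense. Standard-normal noise for the
perturbation z-scores is a modeling assumption — the real reference's noise
structure is not published.

What passing tests on this generator do *not* show: robustness to
unmodeled covariates (age, RIN, tissue composition), to the heavy-tailed
and correlated noise of real level-5 profiles, to multi-dose/multi-time
perturbation structure, or to annotation biases of real trial registries.
The generator validates the *machinery*, not the biology.

## Numerical and design choices

* `log2` for the log-TPM transform (fold-change interpretability).
* Bonferroni for the moderated-LM route and the latent tests; BH for the
  NB route — each route's conventional practice.
* Signature selection ranks significant genes by $|log_2 FC|$ in a single
  ranking (no forced up/down balance), walks down skipping genes absent
  from the reference universe, and targets 100 genes within 90–120; ties
  in $|log_2 FC|$ break lexicographically.
* The transfer signature harvests genes round-robin across significant
  LVs ordered by $|$effect$|$, so every significant LV is represented; the
  up/down sign comes from the NB route's shrunken fold changes.
* Projection standardizes each gene across samples first and applies a
  ridge of $10^{-6}$ — numerical regularization only; at ridge 0 and
  orthonormal loadings it reduces to the plain cross-product.
* NCS pools same-sign scores within the cell line; zeros stay zero.
* The reference bank defaults to 1000 matched-size random signatures; the
  permutation p and the Tau percentile reuse one bank.
* The drug-network edge rule keeps the globally largest 10% of unordered
  off-diagonal pairs, ties at the cut included; Leiden communities maximize
  modularity at resolution 1 with a fixed seed; PPI centrality filters
  raw STRING-style scores at score/1000 > 0.7 (strict), betweenness is
  unnormalized, and eigenvector centrality is computed per connected
  component and scaled to maximum 1.
* Wang semantic similarity uses contribution factors 0.8 (`is_a`) and 0.6
  (`part_of`); term grouping is Ward-linkage clustering of 1 − similarity
  cut at 1 − 0.7, with the largest-annotation term as representative
  (lexicographic ties). Hypergeometric enrichment uses BH adjustment
  throughout.
* Degenerate inputs are handled explicitly: empty significant sets return
  empty signatures (not errors), all-zero expression columns and confounded
  designs raise informative errors, constant genes standardize to zero, and
  missing viability entries are excluded rather than imputed.

## Problem sizes used in validation

The test suite exercises most modules on a 500-gene, 12 + 12-sample,
40-drug benchmark. Acceptance-level checks use: 100 random instances
(G ≤ 50) for the enrichment-score oracle; exhaustive oracles on graphs of
≤ 12 (betweenness) and ≤ 8 nodes (community modularity) and DAGs of ≤ 7
terms (Wang similarity); 50 seeded global-null runs (500 genes,
10 + 10 samples, with 100 raw p-values per run and DE route entering the
pooled uniformity check, one reversion p per run, and 60-drug candidate
draws from a 400-drug universe for the enrichment nulls); and 20 seeded
full-size runs of the default study conditions for planted-truth recovery.
`scripts/acceptance.R` repeats the planted-truth analysis over 10 runs plus
one full three-route pipeline run.

## Known limitations

* The NB route reports DESeq2's normal-prior shrunken fold changes; the
  heavier-tailed adaptive shrinkage some workflows use is intentionally out
  of scope, and only the ranking by shrunken $|log_2 FC|$ is consumed
  downstream.
* With a single query signature there is one connectivity score per drug,
  so the NCS normalization group is the whole cell line; multi-query
  normalization conventions are not implemented.
* The label-switch diagnostic declines only weakly under the default
  synthetic conditions: planted signal sits in a fixed 5% of genes, so a
  fully permuted gene alignment still routes some signal into random
  latent-variable supports. On compendium-scale real data the decline is
  much sharper; the small-benchmark tests show the expected clear decay.
* Binary perturbation-reference containers (GCTX/HDF5) are not parsed;
  the plain-text GCT 1.3, GMT and TSV formats are.
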