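---
title: "Methods: taxon resampling, the single-threshold GMYC, and concordance scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taxon resampling, the single-threshold GMYC, and concordance scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Single-locus species delimitation with the generalized mixed Yule-coalescent
(GMYC) model is sensitive to taxon sampling: the number of delimited species
can shift with sample size, and singleton species (delimited species
represented by a single sequence) can inflate richness estimates. This
package provides the machinery to quantify that sensitivity — repeated random
subsampling of an alignment, a self-contained single-threshold GMYC fit on
ultrametric trees, concordance scoring of each delimitation against
user-predefined groups (morphospecies, ecotypes, host races), and ensemble
summaries across subset fractions — together with a synthetic-data generator
that produces trees with known true species labels so every step can be
tested against ground truth.

# The single-threshold GMYC model

## Model

The model assumes an ultrametric gene tree in which branching above an
unknown time threshold $T$ (measured from the tips, the scale on which MCC
tree annotators report node heights) reflects between-species
diversification, and branching below $T$ reflects within-species
coalescence. Cutting the tree at $T$ delimits species: every maximal subtree
whose root height is $\le T$ is one species; a tip whose parent sits above
$T$ is a singleton species.

The tree's $n-1$ branching events are taken root-to-tips. Each event opens
the waiting interval $i$ below it, with duration $x_i$; the final interval
ends at the present, so the $x_i$ sum to the tree depth. During interval
$i$ the state consists of $k_i$ species-level lineages (each delimited
species counts as one species lineage from its speciation event down to the
present — hence $k \equiv 1$ when the whole tree is one species) and
$n_{ij}$ gene lineages inside species $j$. The composite branching rate is

$$
b_i \;=\; \lambda_{\text{div}}\, k_i^{\,p_{\text{div}}}
      \;+\; \lambda_{\text{coal}} \sum_j \bigl(n_{ij}(n_{ij}-1)\bigr)^{p_{\text{coal}}},
$$

with the convention that a factor with no lineages of its class (e.g.
$n_{ij} < 2$) contributes exactly zero at any exponent. Each interval
contributes $\log \rho_i - b_i x_i$ to the log-likelihood, where $\rho_i$ is
the class component of $b_i$ for the class of the event bounding the
interval. An observed event whose class rate is zero makes the
log-likelihood $-\infty$.

The null model is a single branching class over all nodes with rate
$\lambda_0 (n_i(n_i-1))^{p_0}$, $n_i$ the total lineage count. It is exactly
the threshold model evaluated at $T = \text{depth}$ (one species, all events
coalescent), so the maximised threshold model can never fall below the null
— an invariant asserted throughout the test suite.

## Fitting

For fixed exponents both rates have closed-form maxima
$\hat\lambda_c = m_c / E_c$ (events of the class over its accumulated
exposure $\sum_i F_{c,i} x_i$). Substituting them, the profile
log-likelihood **separates** into two independent one-dimensional functions,
one per exponent. Each is maximised on $[0, 10]$ (configurable) by a
deterministic coarse grid (21 points) followed by golden-section refinement
— bounded and derivative-free. The separability makes multi-start 2-D
search unnecessary; the grid stage guards against multimodality.

The likelihood is piecewise constant in $T$ between consecutive node
heights, so the scan evaluates the midpoints between consecutive distinct
internal node heights plus the two boundary partitions (everything-singleton
and one-species). Ties between equally likely thresholds are resolved
deterministically toward the **older** threshold, i.e. fewer species — the
conservative choice for a method whose known failure mode is oversplitting.

The likelihood-ratio statistic $LR = \max(0,\, 2(\ell - \ell_0))$ is
referred to a $\chi^2$ distribution with 3 degrees of freedom by default
(two extra rate-class parameters plus the threshold); both df = 3 and df = 2
conventions circulate, so df is configurable and reported. P-values are
reported, never auto-thresholded, and no multiple-testing correction is
applied across replicate trees (replicates resample the same data; they are
not independent tests).

Per-node support values are Akaike weights: all candidate threshold models
share one parameter count, so a node's support is the summed normalised
relative likelihood of the candidate models in which it is a
species-defining node (the root of one delimited species).

## Numerical choices

* Heights are measured from the tips; trees within a tolerance of
  $10^{-6} \times$ depth of ultrametric are snapped (tips set exactly to 0);
  larger deviations are an error naming the worst tip.
* Tied node heights (including zero-length internal branches) are jittered
  by $10^{-9} \times$ depth with a deterministic order — ties sorted by
  (number of descendant tips, smallest descendant label), which always
  places a parent above its child — so waiting times are strictly positive
  and event order is reproducible.
* Identical tree and configuration give a bit-identical fit.

# Resampling

Subsamples are drawn uniformly **without replacement**; the subset size is
$\lceil \text{fraction} \times n \rceil$ (so 50% of 500 is exactly 250 and a
draw never has zero records; the alternative floor convention is
indistinguishable on the only documented arithmetic case and ceiling was
fixed once). With group representation enabled, the draw is two-phase: one
uniform representative per group present in the source, then the remaining
slots uniformly from the rest — the simplest scheme that preserves the
per-group guarantee. Per-replicate seeds derive from
`derive_seed(base_seed, index)` (a fixed Lehmer-style integer mix), so a
replicate set is reproducible from its manifest, and whole records (never
alignment columns) are sampled.

# Concordance scoring

The scoring unit is the GMYC species (the worked 16-sample example's
arithmetic — 3 y, 2 n, 1 singleton over 6 species — forces this reading;
the per-sample summary table repeats its species' flag). Categories:

* **singleton** — species of one sample, always scored singleton, even when
  it coincides with a one-sample user group;
* **merge** (flag *n*) — species containing two or more user groups;
  type II when at least one constituent group has exactly one sample in the
  analysed data set (subsampling can turn a multi-sample group into a
  dataset singleton), else type I;
* **split** (flag *y*) — species pure for a group that also occurs in
  another species;
* **exact** (flag *y*) — species pure for a group that occurs nowhere else.

From the counts: $m_i = 100\,(y+s)/(y+n+s)$ and $m_e = 100\,y/(y+n)$;
splitting ratios (species/groups) with and without singletons; singleton
percentage; per-group oversplit factors (number of species containing the
group — singleton species included by default, the exclusive variant is an
argument); exact-match incidence (share of groups scored exact) and
per-group exact-match scores averaged across runs. All metrics are kept at
full precision internally; printed values round **half-up** to the field's
reporting precision (integer percentages, 2 d.p. ratios) — the convention
inferred from reported values such as 0.625 → 0.63 and 12.5% → 13%, and the
reason `round_half_up()` exists (base R rounds half-to-even).

# Ensemble summaries

Per fraction and statistic: mean, sample SD ($n-1$), and a t-based 95% CI of
the mean; a single replicate reports `NA` spread. Accumulation-curve tables
are ordered by sample size and carry both the fraction and the absolute
sequence count. A loess smooth (locally quadratic, span 0.75, widening to 1
below seven points) is available for display parity with common plot
smoothers; the raw means and t-CIs are the inferential quantities — the
smoother choice is presentation, and the only requirement imposed on it is
staying within the CI half-width of the raw means. Failed replicate fits
are dropped with their count logged, never imputed.

# Synthetic data: what it does and does not establish

`simulate_species_tree()` grows a Yule tree forward (waiting time
$\mathrm{Exp}(k\lambda)$ at $k$ lineages, a final $\mathrm{Exp}(n\lambda)$
stretch to the present), so the expected root depth is
$\sum_{k=2}^{n} 1/(k\lambda)$ — a closed form the tests check by Monte
Carlo. `simulate_gene_tree()` runs a Kingman coalescent within each species
branch (rate $\binom{n}{2}/\theta$, $\theta$ = `coalescent_scale` × tree
depth = the expected pairwise coalescence depth), hands surviving lineages
to ancestral branches at species-tree nodes, and finishes above the root —
the standard multispecies coalescent with a common $\theta$. Small
`coalescent_scale` (default 0.02, the regime of a clean barcoding marker)
yields monophyletic species with shallow tip clusters — exactly the regime
the GMYC assumes. Singletons are dialled by per-species sample counts.
JC69 sequences come from `phangorn::simSeq`, whose branch-length
normalisation the tests verify against the JC69 expected pairwise
difference.

Recovery tests use a separation ratio of 20 between the shallowest
interspecific divergence and $\theta$, imposed by construction
(per-tree `coalescent_scale` = min species-node height / (20 × depth)).
A green recovery test therefore establishes that the fit finds the true
species count when the model's assumptions hold and the two timescales are
well separated; it says nothing about geographically structured
populations, non-monophyletic species, rate heterogeneity, or trees
inferred with MCMC error — on real data those are exactly the factors the
resampling analysis is meant to probe, not assumptions the package removes.

The fixed 16-sample fixture (`figure1_fixture()`) is a hand-built
ultrametric tree whose partition at its designed threshold realises one
three-group merge, one two-way split, one exact match, one singleton and
one merge involving a dataset-singleton group; the per-group sample counts
(2/2/2 for the merged trio, 4 for the split group, 2 exact, 2+1 for the
type-II merge, 1 singleton) are one concrete realisation — the
species-level classifications, which are all the metrics depend on, are
fixed by the scenario.

# Known limitations

* Only the single-threshold GMYC variant is implemented; multiple-threshold
  fits, Bayesian GMYC, tree inference and branch smoothing are out of scope
  (trees are expected ultrametric on input).
* FASTA record names are matched to tree tips on the first
  whitespace-delimited token.
* The null model is the coalescent-form single class; a pure-Yule null is a
  conceivable alternative but is not currently exposed.
* Likelihood-ratio p-values inherit the usual caveats of boundary/threshold
  testing; treat them as indicative, and prefer the resampling variability
  the package is built to expose.
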