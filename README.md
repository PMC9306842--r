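# gmycsampler

Taxon-resampling sensitivity analysis for single-locus species delimitation
with the generalized mixed Yule-coalescent (GMYC) model.

## What it is for

DNA-barcoding studies routinely delimit "molecular operational taxonomic
units" by fitting the GMYC model to an ultrametric gene tree: branching
above an unknown time threshold *T* is treated as between-species
diversification (Yule-like), branching below *T* as within-species
coalescence, and the maximum-likelihood *T* cuts the tree into putative
species. The delimitation, however, is sensitive to how many sequences were
sampled and to singletons (species recovered from a single sequence), and
practitioners usually also want to know how the molecular species compare
with predefined groups — morphospecies, ecotypes, host races.

`gmycsampler` packages that whole sensitivity workflow for R users:

* **resampler** — draw random subsets of an alignment without replacement
  (size `ceiling(fraction * n)`), optionally guaranteeing at least one
  representative per predefined group, with fully reproducible per-replicate
  seeds and a provenance manifest;
* **gmyc** — a self-contained single-threshold GMYC fit: interval rate
  `b_i = lambda_div * k_i^p_div + lambda_coal * sum_j (n_ij (n_ij-1))^p_coal`,
  analytic rate profiles, deterministic threshold scan, likelihood-ratio
  test against the one-class null (chi-square, df 3 by default), entity /
  cluster / singleton counts, and Akaike-weight node supports;
* **concordance** — score a delimitation against user groups: merges
  (type I/II), splits, exact matches, singletons, percentage match with and
  without singletons, splitting ratios, per-group oversplit factors,
  exact-match incidence and per-group exact-match scores across runs;
* **ensemble** — per-fraction means, SDs and t-based 95% CIs, plus
  accumulation-curve tables for clusters and entities;
* **synthesizer** — Yule species trees, coalescent-within-species gene
  trees with known true labels, JC69 alignments, and a fixed 16-sample
  worked-example fixture.

See the methods vignette (`vignettes/gmyc-resampling-methods.Rmd`) for the
model, its assumptions, and every numerical choice.

## Worked example

The 16-sample fixture realises the canonical scoring scenario: six GMYC
species against eight user groups — one merge of three groups, one group
split in two, one exact match, one singleton, and one merge involving a
group that is a singleton in the data set.

```r
library(gmycsampler)

fx <- figure1_fixture()
m  <- run_metrics(fx$imposed_partition, fx$truth$groups)
m
#> GMYC concordance metrics ( 6 species vs 8 groups )
#>   y = 3  n = 2  singletons = 1
#>   match incl/excl singletons: 67% / 60%
#>   splitting ratio incl/excl: 0.75 / 0.63
#>   singletons: 17%  exact-match incidence: 13%
m$split_factors
#> sp1 sp2 sp3 spA spB spW spY spZ
#>   1   1   1   2   1   1   1   1
```

Reading the numbers: 3 of the 6 species match a single user group ("y"),
2 lump several groups ("n"), 1 is a singleton. Including singletons the
percentage match is (3+1)/6 = 67%; excluding them 3/5 = 60% — the singleton
inflates the match estimate by 7 points. Six species over eight groups
gives splitting ratios 0.75 (5/8 = 0.63 without the singleton, suggesting
the user over-split), only spZ matches exactly (1/8 = 13% incidence), and
spA was oversplit by a factor of 2 — a candidate cryptic species or mere
population structure.

A full simulated round trip — truth, GMYC fit, recovery:

```r
sp <- simulate_species_tree(10, speciation_rate = 1, seed = 8)
h  <- attr(sp, "heights"); hmin <- min(h[11:19])
ts <- simulate_gene_tree(sp, samples_per_species = 5,
                         coalescent_scale = hmin / (20 * max(h)),
                         seed = derive_seed(8, 1))
fit_single_threshold(ts$tree)
#> Single-threshold GMYC fit
#>   tips: 50  threshold T = 0.08098
#>   logL = 307.544  null logL = 281.891
#>   LR = 51.31  df = 3  p = 4.21e-11
#>   entities: 10  clusters: 10  singletons: 0
```

All ten true species are recovered, and the threshold model beats the
one-class null decisively.

A command-line interface mirroring the library
(`resample`, `delimit`, `score`, `summarize`, `simulate`) is available via
`run_cli()` or the `inst/exec/gmycsampler` script.

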