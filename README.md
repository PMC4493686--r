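# funcnet

Functional gene-network integration and differential-expression
meta-analysis for heterogeneous omics evidence.

Inferring what a gene does usually means combining evidence that lives in
incompatible formats and on incompatible scales: expression compendia with
missing values and probe-level identifiers, binary physical-interaction
edge lists, regulatory links, and co-expression scores that differ by
platform. funcnet gives computational biologists a reproducible path from
that heterogeneity to answers:

- **standardize** matrices and networks onto a shared gene namespace from
  user-supplied mapping tables, merging duplicate probes;
- **normalize** expression per gene to z-scores and fill missing values by
  distance-weighted k-nearest-neighbour imputation (k = 10 by default,
  weights ∝ 1/(d + ε) over shared observed samples);
- **build and integrate networks**: per-dataset co-expression networks
  (Pearson r → Fisher z → within-dataset standardization), binary evidence
  lifted to a fixed confidence (2.0 on the z scale), and an integrated
  functional network whose edge weight is the mean z-score over the
  sources that score each pair;
- **query** the integrated network: starting from a set Q of query genes,
  greedily add the k genes with the strongest summed connectivity to the
  growing set, so the returned high-confidence subnetwork has |Q| + k
  genes (ties broken lexicographically, fully deterministic);
- **meta-analyze** case-control datasets: per-dataset Welch log2
  fold-change contrasts `y ± 1.96·√v`, pooled per gene under a
  random-effects model (REML by default, DerSimonian–Laird as the
  closed-form alternative: τ² = max(0, (Q − (k−1))/C)), Benjamini–Hochberg
  FDR across genes, and permutation gene-set enrichment
  (p = (1 + #{null ≥ obs})/(B + 1), B = 1000) on GMT sets;
- **reproduce**: nested key-value metadata with curated overrides, MD5
  provenance per processing step, and a checksum-driven pipeline that
  re-executes a stage only when an input, a configuration, or an upstream
  stage changed.

Everything is testable offline: seeded fixture generators plant
co-expression modules, network clusters and differential effects with
known ground truth.

## Worked example

Integrate an interaction network with a co-expression network built from a
normalized expression matrix, then extract a high-confidence subnetwork
around three query genes:

```r
library(funcnet)

net1 <- gen_interaction_network(n_genes = 100, seed = 7)$network

fix <- gen_expression_dataset(n_genes = 100, n_samples = 20,
                              missing_rate = 0.05, seed = 7)
z <- zscore_rows(fix$matrix)
coexp <- build_coexpression_network(impute_knn(z$zscores)$imputed,
                                    dataset_id = "DS01")

fun <- integrate_networks(list(standardize_edge_weights(net1),
                               standardize_edge_weights(coexp)))
sg <- extract_subgraph(fun, c("g0001", "g0002", "g0003"), k = 7)
tidy(sg)
#> # A tibble: 10 × 4
#>    node  role  add_rank add_score
#>    <chr> <chr>    <int>     <dbl>
#>  1 g0001 seed        NA      NA
#>  2 g0002 seed        NA      NA
#>  3 g0003 seed        NA      NA
#>  4 g0008 added        1      10.9
#>  5 g0004 added        2      12.8
#>  6 g0007 added        3      16.5
#>  7 g0005 added        4      18.9
#>  8 g0009 added        5      20.8
#>  9 g0006 added        6      22.8
#> 10 g0010 added        7      25.4
```

The three query genes sit in a planted 10-gene cluster; the seven added
genes are its remaining members, each row recording the summed edge weight
that gene had to the subnetwork at the moment it was added (`autoplot(sg)`
draws the subgraph). Pooling four study effects under the random-effects
model:

```r
fit <- pool_random_effects(y = c(0.8, 1.1, 0.6, 1.4),
                           v = c(0.04, 0.06, 0.05, 0.08))
fit
#> <rema REML> k=4  mu=0.9415 (se 0.1637)  tau2=0.0516  z=5.750  p=8.91e-09
```

i.e. a pooled log2 fold change of 0.94 (≈1.9-fold), modest between-study
heterogeneity (τ² = 0.05), and strong evidence the effect is non-zero;
`tidy(fit)` returns the per-study rows and `autoplot(fit)` the forest
plot. The full chain — selection, mapping, normalization, networks,
integration, query, meta-analysis — also runs as an incremental pipeline:

```r
ws <- tempfile()
gen_mock_repository(ws, seed = 1)
cfg <- pipeline_config(taxa = 10090,
                       selection = list(patterns = list(
                         list(key_path = "title", regex = "germ-?free"))),
                       meta = list(method = "REML"))
run_pipeline(cfg, ws)     # executes every stage
run_pipeline(cfg, ws)     # executes nothing: all provenance is current
```

A thin command-line wrapper over the same functions ships in
`inst/cli/funcnet.R` (`generate-fixtures`, `plan`, `build`, `integrate`,
`query`, ...).

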