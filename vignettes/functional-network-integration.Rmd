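---
title: "Methods: functional network integration and expression meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional network integration and expression meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcnet)
```

funcnet turns heterogeneous evidence about gene function — expression
compendia, physical interactions, regulatory links — into a single weighted
functional network on a shared gene namespace, and supports two downstream
analyses on top of it: seeded extraction of high-confidence subnetworks
around query gene sets, and random-effects differential-expression
meta-analysis across case-control datasets. This vignette documents the
models, the parameters that matter, and the design decisions taken where
more than one defensible choice existed.

## Expression normalization

Expression matrices arrive as genes × samples TSV tables with missing
cells. The processing chain is fixed in order and selected by a recipe
string (`"log2::zscore::knn10::coexpr"`):

1. **log2** (optional): `x -> log2(x + 1)` for linear-scale intensities.
   The +1 pseudo-count keeps zero intensities finite; data already on a log
   scale skip this step.
2. **z-score**: each gene's vector is centred and scaled to mean 0, sd 1
   over its *observed* entries, with the n−1 sample estimator of the
   standard deviation (the conventional unbiased-variance choice; nothing
   downstream is sensitive to n vs n−1 at realistic sample counts).
   Constant genes become all-zero and are flagged rather than dropped;
   genes observed fewer than 3 times carry too little information to scale
   and are dropped with a count.
3. **kNN imputation** (`knn<k>`, default k = 10): a missing value for gene
   g in sample j is the weighted average of the values at j of the k
   nearest neighbour genes. Distance is the root-mean-square difference
   over the samples both genes observe — dividing by the number of shared
   samples is what makes distances comparable between gene pairs with
   different missingness, which is how we read "relative" Euclidean
   distance. Weights are `1/(d + 1e-6)`, normalized to sum to one; the
   epsilon keeps a zero-distance duplicate from producing an infinite
   weight while still dominating the average (a duplicate neighbour
   reproduces its value to < 1e-4). Candidates must be observed at the
   target column and share at least `min_shared = 3` observed columns —
   with fewer shared columns a distance estimate is mostly noise. If no
   candidate qualifies, the gene's own observed mean (≈ 0 after
   standardization) is used and the cell is flagged as a fallback.
   Distances are computed once from observed entries only; we do not
   iterate imputation, trading a small accuracy margin for determinism and
   a single-pass contract.
4. **co-expression** (`coexpr`): Pearson correlation for every unordered
   gene pair over all samples, Fisher-transformed (`atanh`, with |r|
   clamped below 1 so perfectly correlated pairs stay finite), then
   standardized to mean 0, sd 1 *across all pairs within the dataset*.
   These standardized values are the "normalized co-expression z-scores"
   that integration averages. Pearson + Fisher + within-dataset
   standardization is our concrete realization of that scale; the
   similarity measure is configuration-extensible, and we do not claim
   bit-compatibility with any other toolkit's co-expression scores.

Differential-expression effects (below) are computed from the **mapped,
log2, non-z-scored** matrix: per-gene standardization destroys fold-change
units, so the meta-analysis branch forks off before step 2.

## Gene identifier mapping

Mapping tables are user-supplied two-column TSVs (source id → target id,
many-to-one allowed, many-to-many rejected at parse time — ambiguous probes
must be resolved upstream rather than silently guessed). Expression rows
mapping to the same target gene are merged by element-wise mean over
non-missing values, the unbiased choice when duplicate probes are
exchangeable replicates. Network edges remap endpoint-wise; parallel edges
collapse to the **maximum** weight (strongest evidence, the usual
convention for interaction evidence), and merge-created self-edges are
dropped. Every mapping emits a report (`n_input = n_mapped + n_unmapped`
always holds) whose success flag uses a configurable mapped-fraction
threshold, default 0.5.

## Network standardization and integration

Heterogeneous networks are placed on a common confidence scale before
averaging:

- continuous networks (co-expression, weighted functional evidence) are
  z-standardized across their edge weights;
- binary networks (physical or regulatory edge lists where every present
  edge has the same weight) assign each present edge the constant **2.0**
  — the conventional high-confidence cutoff on the z scale — and leave
  absent pairs unscored.

Integration takes the arithmetic mean of each pair's weight over the
networks that actually score the pair. Averaging over *scoreable* networks
only (rather than treating absence as 0) prevents sparse physical evidence
from being diluted toward zero by the many networks that never measured
the pair; the alternative (`average_mode = "all"`) is available in
configuration. Pairs scored by no network are absent from the result.

## Seeded subgraph extraction

Given query genes Q and a neighbourhood size k, the extractor grows the
set greedily: at each of k steps, every candidate gene v outside the
current set S is scored by `sum over u in S of w(u, v)` (unscored pairs
contribute 0 — the neutral confidence on a z scale), and the top scorer
joins S, with exact lexicographic tie-breaking so results are
deterministic. Early stopping (halt when no candidate scores > 0) exists
but is **off** by default, so the returned subgraph always has
`|Q ∩ V| + min(k, |V| − |Q ∩ V|)` nodes — on any network with ample
candidates, 12 seeds with k = 10 give a 22-gene subnetwork, 11/29/44 seeds
with k = 5 give 16/34/49. Greedy sum-of-weights expansion is our
realization of "k additional high-confidence neighbours"; it is simple,
exactly testable against exhaustive per-step evaluation, and satisfies the
stated output contract. More elaborate probabilistic search schemes would
satisfy the same contract and could replace the scorer behind the same
interface.

## Random-effects meta-analysis

Per dataset, each gene's effect is the Welch contrast
`y = mean(case) − mean(control)` with variance
`v = s²_case/n_case + s²_ctrl/n_ctrl` and normal 2.5%/97.5% bounds
`y ± 1.959964·√v`. We use plain Welch estimates rather than
moderated/empirical-Bayes statistics deliberately: moderation shrinks
per-gene variances toward a prior fit on the whole matrix, which is
valuable at n ≈ 3–4 but couples genes together and is out of scope here;
the pooling layer is agnostic to how `(y, v)` were produced. Degenerate
zero variances are floored at 1e-8 so pooling stays defined on toy data.

Across datasets, each gene is pooled under the additive random-effects
model `y_i = mu + u_i + e_i`, `u_i ~ N(0, tau²)`, `e_i ~ N(0, v_i)`. Two
tau² estimators:

- **DerSimonian–Laird** (closed form): `Q = Σ w_i (y_i − ȳ)²` with
  `w_i = 1/v_i`, `C = Σw − Σw²/Σw`, `tau² = max(0, (Q − (k−1))/C)`. Kept
  both as a user-selectable method and as the hand-checkable oracle.
- **REML** (default): tau² maximizes the restricted log-likelihood
  `−½[Σ ln(v_i+tau²) + ln Σ(v_i+tau²)^{-1} + Σ (y_i−mu(tau²))²/(v_i+tau²)]`
  by bounded one-dimensional search on `[0, 10·max(var(y), max v_i)]` to
  tolerance 1e-8, with an explicit boundary check at 0. A bounded scalar
  search is slower than Fisher scoring but cannot diverge on the small-k,
  small-v inputs this package routinely sees; agreement with an
  independent REML implementation is verified in the test suite.

Pooled `mu = Σ y_i/(v_i+tau²) / Σ 1/(v_i+tau²)`, `se = (Σ 1/(v_i+tau²))^{-1/2}`,
`z = mu/se`, two-sided normal p, Benjamini–Hochberg q across genes
(step-up, via the standard library routine). A single-study gene passes
through with tau² = 0 and is flagged by `k_studies = 1`.

## Permutation gene-set enrichment

Genes are split by the sign of the pooled effect (`mu_hat >= 0` counts as
up, so no gene is lost to an exact zero). For a set and direction the
observed statistic is the mean of `−ln p` over set members in that
stratum; the null is B (default 1000) random same-size subsets of the same
stratum, and `p_perm = (1 + #{null ≥ observed})/(B + 1)`, which is never 0
and never below `1/(B+1)`. Sets with fewer than 3 tested members are
skipped. The statistic, the stratification and the gene-label permutation
unit are this package's documented choices — the enrichment literature
offers many variants and the upstream description pins down only the
permutation count.

## Metadata, provenance and incremental builds

Dataset annotations are nested key-value records serialized as JSON
(portable and diffable, unlike language-native serialized objects), with
curated overrides merged recursively: nested mappings merge key-wise and
the curated value wins at the deepest conflicting key, while scalars and
lists are replaced whole; merged records carry `_curation_applied = TRUE`.
Whole-record replacement was the main alternative; deep merge preserves
automatic annotation that curators did not touch, which is the point of
curation. Selection screens filter by taxonomy id, include/exclude lists,
minimum sample count and case-insensitive regex patterns on dotted key
paths (missing path = pattern fails, not an error).

Provenance is an append-only log of steps with tool version, command and
MD5 digests of every input. MD5 is a provenance fingerprint, not a
security boundary — collision resistance is irrelevant to staleness
detection. The build planner compares recorded digests and configuration
hashes against the current workspace and marks the minimal stale set plus
its downstream closure; the runner executes exactly the stale nodes in
topological order, so an untouched workspace re-runs nothing and a single
mutated input reruns only its chain, byte-identically to a from-scratch
run (all writers emit sorted rows, `%.10g` numbers, LF endings,
locale-independent).

## Synthetic fixtures and what they do not show

All tests run on seeded generators with planted truth:

- **Expression**: an equi-correlated Gaussian factor model — module genes
  are `√rho·f_m + √(1−rho)·ε` so the expected within-module correlation is
  exactly rho (defaults rho = 0.9, 3 modules of 10); per-gene random
  affine distortion checks that z-scoring removes scale and location;
  missingness is MCAR (informative missingness is out of scope).
- **Networks**: stochastic block models, defaults 10-gene clusters with
  in-cluster edge probability 0.9 and weight N(3, 0.5²) against
  cross-cluster probability 0.05 and weight N(0, 0.5²) — tight functional
  modules well above background on a z-like scale.
- **Case-control collections**: six studies of 4 + 4 samples with 10% of
  genes differentially expressed (study-level effects
  `N(mu_de, tau²)`, defaults mu_de = 1, tau = 0.25, sigma = 0.5 on the
  log2 scale), mirroring a small multi-study gnotobiotic-mouse screen.

Passing tests on these fixtures demonstrate algorithmic correctness —
standardization identities, imputation beating gene-mean baselines when
correlated neighbours exist, recovery of planted clusters and effects,
calibrated meta-analysis intervals. They do not demonstrate robustness to
real-platform artefacts: batch effects, informative missingness,
heavy-tailed intensity distributions, probe cross-hybridization, or
correlated (non-exchangeable) study designs all lie outside the generative
models and therefore outside what the test suite can certify.

## Problem sizes and numerical conventions

The test suite and verification scripts use desk-scale problems chosen to
exercise every code path with comfortable statistical margins: networks of
100–250 genes, expression fixtures of 50–200 genes × 12–30 samples,
imputation comparisons over 50 seeded replicates, meta-analysis recovery
over 200 replicates of 20 studies, and enrichment calibration over
hundreds of permutation tests at B = 500–1000. Tolerances follow the
quantity: machine-precision identities are asserted at 1e-9–1e-12,
hand-traced arithmetic at 1e-12, and stochastic recovery properties at the
rates stated above. All text output is locale-independent ('.' decimal
separator, LF endings, UTF-8); all stochastic stages take explicit integer
seeds and are bit-reproducible given them.

## Known limitations

- Identifier mapping takes the target namespace as given; no ortholog
  inference or sequence-based clustering.
- No Bayesian or discriminative weighting of evidence sources during
  integration; all scoreable networks count equally.
- Imputation is single-pass; genes whose neighbours are themselves mostly
  missing fall back to mean imputation.
- The enrichment statistic treats genes as exchangeable within a
  direction stratum; gene-gene correlation inflates its optimism on real
  co-regulated sets, as it does for all gene-label permutation schemes.
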