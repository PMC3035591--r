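---
title: "The Normalized Tree Index: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Normalized Tree Index: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntindex)
```

## The problem

A hierarchical clustering of high-dimensional primary data — classically a
samples-by-genes matrix of microarray log-ratios — organizes the samples into
a binary tree. A biomedical researcher then wants to know which of the many
per-sample annotations (clinical parameters, outcomes, exposures) are
*correlated* with that structure, and how strongly. Internal cluster indices
cannot answer this: they only look at the geometry of the data. What is
needed is an external index that takes a nominal label, measures how
non-randomly its classes are distributed over the tree, and attaches a
significance level, so that dozens of clinical columns can be screened
automatically against one clustering.

`ntindex` implements such an index — the Normalized Tree Index (NTI) — along
with the full pipeline around it: preprocessing and average-linkage
clustering, rule-based binning of ordinal/interval clinical columns to
nominal categories, per-label evaluation with an empirical p-value, and a
ranked screening report.

## The splitting model

The cluster tree is read as the record of a statistical splitting process,
starting at the root where the whole dataset is one cluster. Consider the
$r$-th split: a cluster of $N$ labelled elements (class totals
$n_\lambda$, $\lambda = 1..\kappa$) divides into $l$ subclusters of sizes
$m_i$ with class counts $m_{i\lambda}$. Under the null model that the $m_i$
elements of each subcluster are drawn from the parent by uniform sampling
without replacement, the probability of the observed class distribution
$M = \{m_{i\lambda}\}$ is the multivariate hypergeometric expression

$$p(M; N, n, m) = \frac{\prod_{i=1}^{l} m_i! \big/ \prod_{\lambda=1}^{\kappa} m_{i\lambda}!}
                       {N! \big/ \prod_{\lambda=1}^{\kappa} n_\lambda!}.$$

The splitting score is its negative logarithm,
$S_r = -\ln p(M; N, n, m)$: class-homogeneous splits of large clusters are
improbable under the null and score high; uninformative splits score near 0.
The Tree Index aggregates all $R$ splits by their *population* standard
deviation,

$$TI = \sqrt{\tfrac1R \sum_{r=1}^{R} (S_r - \bar S)^2},$$

so a tree whose label concordance is concentrated in a few decisive,
improbable splits scores higher than one whose scores are uniformly
mediocre. All factorials are evaluated as log-gamma terms
(`lgamma(n + 1)`), never as factorial integers, so parent clusters with
thousands of members are handled without overflow (verified in the tests
against `lchoose` for $N = 4000$).

### Missing labels

Clinical tables are full of missing values, and the index must tolerate
them. Samples with a missing label are excluded from every count
($N$, $n$, $m$, $M$) — the only convention under which the
sampling-without-replacement model remains well-defined. A useful and
non-obvious consequence, asserted in the test suite: given the arrangement
of the *labelled* samples, where the missing-labelled samples sit in the
tree does not change the TI.

### Degenerate splits

After missing-exclusion a split can be degenerate: $N \le 1$, or every
labelled member sits in one subcluster. By the empty-product convention such
splits have probability 1 and score 0. The default (`degenerate =
"include"`) keeps them in $R$, so $R$ remains a pure topology property
($R = d - 1$ for a binary tree over $d$ leaves); `degenerate = "skip"`
removes them from $R$, which changes the magnitude of the index (both modes
are tested). The default is the convention used everywhere else in the
package.

## Normalization: the NTI

The raw TI inflates with the number of classes $\kappa$: more classes mean
more possible tables, smaller probabilities, larger scores. The test suite
demonstrates the inflation directly (mean TI on random labels roughly
doubles from $\kappa = 2$ to $\kappa = 5$). To compare labels with different
$\kappa$, class balance and missingness, the TI is min-max normalized with
Monte-Carlo estimates of its floor and ceiling *for that label*:

* **TI\_min** — the labels are permuted $r$ times over the *fixed* observed
  tree; the smallest TI estimates the floor. The same $r$ draws double as
  the permutation null for the p-value, halving the Monte-Carlo cost.
* **TI\_max** — $r$ *ordered trees* are built: one class-pure subtree per
  class, merged by $\kappa - 1$ random pairwise joins. The internal shape of
  a pure subtree is irrelevant (every within-class split has probability 1,
  hence score 0), so subtrees are random caterpillars; only the join splits
  can score non-zero, and the ceiling search explores their arrangement via
  the random merge order. Missing-labelled samples are appended as one extra
  pure subtree, which provably cannot change the index. The largest TI over
  the draws estimates the ceiling.

$$NTI = \frac{TI - TI_{min}}{TI_{max} - TI_{min}} \in [0, 1].$$

Because both bounds are empirical, the observed TI can overshoot them; the
NTI is then clamped to 0 or 1 and the clamping is flagged in the result
(`$clamped`). Frequent clamping means $r$ was too small. On 4–6 leaf
problems, where everything can be enumerated, the Monte-Carlo floor matches
the exhaustive minimum over all label placements and the ceiling matches the
exhaustive maximum over *all* rooted binary topologies — the ordered-tree
construction does reach the global maximum in every enumerated case
(test suite and acceptance checks).

This normalization is not unbiased in a strict statistical sense — the
distribution of the TI between the bounds is not modelled and E[NTI] under
the null is unknown — but it removes the gross $\kappa$ inflation, which is
what makes cross-label screening meaningful. No correction beyond min-max is
attempted.

## The empirical p-value

With $t$ the observed TI and $t_i$ the TI of the $i$-th permuted label on
the fixed tree,

$$p = \max\left(\tfrac1r \#\{i : t_i \ge t\},\ \tfrac1r\right).$$

Three choices deserve a note:

* **Fixed tree.** Only the labels are randomized. Randomizing the tree as
  well would inflate the search space and answer a different question (is
  there a correlation *and* a significant clustering); the null of interest
  is "this label is unrelated to this clustering".
* **Tail comparator.** "Equal or higher" (`>=`) is the default; a strict
  `>` variant is available (`tail = "gt"`). With `>=` the test is
  conservative under ties. A tolerance of $10^{-9}$ (relative) guards the
  comparison: tied permutations produce the same log-gamma terms summed in
  different orders, and without the guard float round-off can split an
  exact tie (this is visible on small enumerable problems).
* **The 1/r floor.** A tail count of zero yields $p = 1/r$, not 0 — so more
  than 1000 permutations are needed before a rejection at the 0.1% level is
  achievable at all. The default $r = 10000$ comfortably supports all three
  significance levels (5%, 1%, 0.1%, displayed as 1–3 stars with strict
  thresholds).

The p-value is attached unchanged to the NTI: normalization only shifts and
scales the index, leaving tail fractions invariant (asserted exactly in the
tests, on the unclamped transform).

## Preprocessing and clustering

The pipeline reproduces a standard microarray setting. Log-ratios are scaled
into $[-1, 1]$; the default divides the whole matrix by its global maximum
absolute value (`global_maxabs`), reading the scaling as matrix-wide. A
per-gene variant (`per_gene_maxabs`) is offered behind a flag since either
reading is defensible for real cohorts; the choice changes distances, not
the index machinery.

Samples are clustered by average linkage (UPGMA) under the correlation
distance

$$d_{ij} = \frac12 - \frac{\sum_k x_{ik} x_{jk}}{2g} \in [0, 1],$$

implemented exactly as written: an *uncentered, unnormalized* inner-product
dissimilarity, not $1 -$ Pearson correlation. Two consequences are
documented rather than "fixed": the self-distance of a non-saturated
profile is positive ($d(x,x) = 1/2 - \sum x^2/2g$), and 0/1 are attained
only at identical/antipodal sign vectors. The linkage is implemented
in-package with a deterministic tie rule — among equally close pairs, the
lexicographically smallest pair of cluster creation indices merges first —
so degenerate data still yield one reproducible tree; on tie-free inputs the
topology agrees with `stats::hclust(method = "average")` (tested).

## Binning clinical columns

The index is defined for nominal labels only. Ordinal and interval columns
are reduced by per-column rules (`binning_spec`, YAML-loadable via
`load_binning_config`): `interval_bins` cuts numeric values at declared
breaks, `category_merge` merges raw categories, `passthrough` leaves nominal
columns untouched. Bins are left-closed/right-open with the last bin
unbounded above — published category ranges rarely state boundary
membership, so the convention is explicit and switchable per column
(`closed = "right"`). Two ready-made configurations for classic breast
cancer cohorts ship in `inst/extdata/` as executable documentation. Direct
support for ordinal/interval labels without binning is out of scope; the
reduction loses information and encodes the researcher's prior, which is
stated rather than hidden.

## The synthetic-data generator

`simulate_labeled_expression()` emulates the marker-gene class structure the
method targets: $\kappa$ near-evenly sized sample classes, each with mean
shifts of magnitude `effect` (in log-ratio units, random sign) on a random
30% subset of genes, plus i.i.d. Gaussian noise, then the pipeline's own
scaling. Defaults — 40 samples, 100 genes, 2 classes, `effect = 2`,
`noise_sd = 0.5`, 5 null label columns — give a strong but not trivial
signal (effect $= 4\times$ noise SD). The generator feeds the test suite;
it deliberately does *not* model dye bias, batch effects, gene-gene
correlation or heavy-tailed noise, so passing tests demonstrate the
statistical machinery, not robustness to real microarray artefacts.

## Numerical and design choices

* Split order is pre-order from the root, but the TI is order-invariant
  (tested under child rotation and ladderization).
* Population ($1/R$) standard deviation, not the sample form.
* One shared `r` and one RNG stream govern floor, ceiling and p-value in
  `evaluate_label()`; everything is reproducible from `seed`.
* Single-class labels ($\kappa = 1$): TI = 0, envelope degenerate, NTI = 0,
  $p = 1$, with a warning rather than an error — screening should not stop
  on a constant column.
* All-missing columns are skipped with a message.
* Problem sizes in the tests and the acceptance sweep (16–40 samples,
  25–100 genes, $r$ between 60 and 10000 depending on what the check needs)
  were chosen so the full enumerable oracles stay exhaustive and the
  stochastic assertions keep comfortable margins.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_labeled_expression(n_samples = 40, n_genes = 100, seed = 1)
report <- nti_screen(sim$expr, sim$clinical, r = 10000, seed = 1)
report
autoplot(report)                       # ranked NTI bars with stars
res <- attr(report, "results")$signal
autoplot(res)                          # permutation null vs observed TI
```

The planted `signal` column ranks first with NTI near 1 and $p$ at the
$1/r$ floor; the independent `null_*` columns scatter over small NTIs with
non-significant p-values.

## Known limitations

* The NTI's null expectation is not 0 and varies with $\kappa$ and class
  balance; compare labels by p-value as well as by NTI.
* The empirical p-value's resolution is $1/r$; multiple-testing control
  across many labels is off by default (raw p-values are reported, matching
  the screening intent), with Benjamini–Hochberg available via `bh = TRUE`.
* TI\_max assumes the ordered-tree construction reaches the global maximum;
  this is proven here only by exhaustive enumeration up to 6 leaves, though
  no counterexample is known.
* Gene-dimension clustering, alternative linkages/metrics and heatmap
  co-visualization are out of scope.
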