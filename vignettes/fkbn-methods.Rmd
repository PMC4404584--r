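---
title: "Restricted Bayesian network classifiers: models, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restricted Bayesian network classifiers: models, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fkbn)
```

## The problem and the model family

Clinical registry extracts — tens of thousands of patient records, a couple
of dozen mixed categorical/numeric attributes, a categorical outcome such as
cause-specific death — invite two questions at once: *can the outcome be
predicted*, and *which attributes depend on which*. Restricted Bayesian
network classifiers answer both with one object. Every model in the family
factorizes

$$P(c \mid x) \propto P(c) \prod_{i=1}^{n} P(x_i \mid Pa_i, c),$$

where the class $C$ is an implicit parent of every attribute and the
attribute parent sets $Pa_i$ are capped at $K$ members. The cap is the whole
point: it bounds the number of parameters per table and makes estimation
feasible on finite data, while the arcs that *are* kept form a directed
acyclic graph over the clinical variables that can be read as a dependency
map.

The four learners differ only in how they choose $Pa_i$:

* **NB** ($K=0$) keeps every $Pa_i$ empty — the conditional-independence
  baseline.
* **TAN** ($K=1$) connects the attributes with the maximum-weight spanning
  tree under the conditional mutual information
  $CMI(X_i;X_j\mid C)$ and directs it away from a root, so each non-root
  attribute gains exactly one attribute parent. The tree is globally optimal
  among 1-dependence structures, but cannot express higher-order
  dependence.
* **KDB** ($K\ge 1$) fixes a rigid attribute order by $MI(X_i;C)$
  descending and gives the $j$-th attribute its $\min(j-1,K)$ strongest
  predecessors by CMI. The order ignores attribute interactions, so strong
  pairs can be missed when they disagree with the marginal ranking.
* **FKBN** combines the two: stage 1 builds exactly TAN's spanning tree
  (global optimality); stage 2 walks the remaining attribute pairs in CMI
  descending order and adds each as an arc when the receiving node still has
  a free parent slot. Arcs are oriented along the tree's breadth-first
  order, which makes acyclicity structural rather than something to check.
  The default operating point is $K=2$, the smallest cap that goes beyond
  tree-width dependence.

Both information measures are estimated from unsmoothed maximum-likelihood
frequencies, in bits, with $0\log 0$ terms defined as 0. Smoothing is
deliberately *not* applied to the structure-learning weights: add-one mass
would shrink all weights toward a common floor and blur the spanning tree;
its proper scope is the probability tables below.

## Preprocessing

The pipeline assumes schema-declared delimited text: each column is
`categorical`, `numeric`, or the single `class` column, with explicit
missing-value tokens.

* **Imputation** replaces missing categorical values with the training-fold
  mode (ties broken by first occurrence in file order, for determinism) and
  missing numeric values with the training mean. Imputation precedes
  discretization because the mean is defined on the numeric scale.
* **Discretization** is the recursive entropy-minimization scheme with the
  MDL stopping rule: a binary split of a set $S$ of size $N$ with $k$
  classes into $S_1, S_2$ is accepted only when its information gain
  exceeds
  $\log_2(N-1)/N + [\log_2(3^k-2) - (k\,Ent(S) - k_1 Ent(S_1) - k_2
  Ent(S_2))]/N$, and the procedure recurses on accepted halves. Candidate
  cuts are midpoints between consecutive distinct sorted values whose
  adjacent class multisets differ (boundary points) — the standard
  formulation, which provably loses no optima and keeps the search small. A
  column where no split passes the criterion stays a single bin, which is
  the correct degenerate answer for class-uninformative columns.
* **Domains are frozen at fit time.** Numeric bins are half-open intervals
  with unbounded outer bins, so any test-time value lands somewhere.
  Categorical domains carry a reserved `"<unseen>"` level; test-time values
  never seen in training map there rather than aborting, and Laplace
  smoothing guarantees the level nonzero mass. This matters inside
  cross-validation, where small held-out folds routinely contain novel
  levels.
* Within cross-validation both models are re-fitted per training fold;
  anything else would leak held-out information into the fitted statistics.

## Parameter estimation

Probability tables use the Laplace (add-one) estimate. The class prior is
$\hat P(c) = (F(c)+1)/(K+k)$ with $F(c)$ the class frequency, $K$ the
number of training instances and $k$ the number of classes. Conditionals
are ratios of add-one-smoothed joints, which renormalize exactly to

$$\hat P(x_i \mid pa_i, c) = \frac{F(c, x_i, pa_i) + 1}
{F(c, pa_i) + |dom_i|}.$$

Parent sets larger than one use the same "+1 over (count +
number-of-combinations)" pattern on the full combination space. Two
deliberate details:

* Domain sizes in the denominators come from the *declared* domains
  (including the reserved unseen level), not from observed combinations, so
  denominators do not depend on fold composition.
* Prediction accumulates $\log \hat P(c) + \sum_i \log \hat P(x_i \mid
  pa_i, c)$ in log space — at 20+ attributes the direct product underflows
  double precision — then exponentiates and normalizes. Exact posterior ties
  go to the class earlier in the class-domain order.

## Evaluation and comparison

Zero-one loss $\xi(c,\hat c) = 1-\delta(c,\hat c)$ is estimated by
stratified 10-fold cross-validation (stratification reduces variance; the
fold assignment is a deterministic function of the seed). The reported
spread is the sample standard deviation across fold losses.

Algorithms are compared across datasets with Friedman ranks: per dataset,
rank 1 is the lowest loss, ties share the average of the ranks they span,
and the per-algorithm average rank $R_j = \frac1N\sum_i r_i^j$ summarizes
the comparison. Two tie modes exist because "tied" is ambiguous:

* `exact` — ties are exactly equal losses;
* `signtest` — two algorithms tie when an exact two-tailed binomial sign
  test on their paired win counts cannot separate them at $\alpha = 0.05$,
  $p = \min(1, 2\,P[\mathrm{Bin}(m, 1/2) \ge \max(w_a, w_b)])$. The win
  unit is per-instance paired correctness over pooled held-out predictions
  (win = correct where the other is wrong; double-correct and double-wrong
  instances carry no sign information). Non-significance is not transitive,
  and average-rank assignment needs a partition, so tie groups are the
  transitive closure of the pairwise relation.

A display convenience worth stating: printed rank tables round half *up*
(`round_half_up()`), the convention of most published tables, whereas base
R rounds half to even; at one decimal the two disagree on values like 2.25.

## The synthetic-data generator

Real registry extracts are access-restricted, so the package carries its
own generator: a planted $\le K$-parent Bayesian network over categorical
attributes. A uniformly random total order is drawn; each attribute
receives a uniformly random subset of at most $K$ predecessors as parents
(uniform over all such subsets, so parent counts concentrate at $K$ once
enough predecessors exist); the class marginal and every conditional row
are symmetric-Dirichlet draws with a single `sharpness` concentration knob
(lower = sharper rows = stronger dependencies); instances are produced by
ancestral sampling, class first. Every draw derives from one seed, so all
experiments replay exactly.

The generator emulates the *shapes* of the motivating data — registry-like
tables ($10^4$–$10^5$ rows, ~20 attributes, 2–3 classes) and tiny wide
microarray-like tables (tens of rows, many attributes) — and nothing else:
no attempt is made to mimic the marginal distributions, coding schemes or
grouped categories of real clinical variables. Experiments on it
demonstrate correctness and calibration of the machinery, not clinical
performance.

Problem sizes used by the shipped experiments, chosen so the whole suite
replays comfortably on a laptop: parameter recovery fits tables on $10^5$
rows from a 4-attribute binary planted model at concentration 5, a setting
where every parent configuration receives enough mass that the 0.02
absolute tolerance is statistically comfortable rather than marginal;
structure recovery uses the 20-attribute, domain-3, sharpness-0.1 defaults
at $10^3$–$5\times10^4$ rows; the degeneracy experiment uses 20 replicates
of 30 attributes × 40 rows at concentration $10^4$ (near-uniform tables,
i.e. almost no real dependence) — 30 attributes stand in for the
"thousands of attributes" of real microarray tables because the
$O(n^2)$ CMI matrix would otherwise dominate runtime without changing what
the experiment shows.

### What the recovery experiments do and do not show

Parameter recovery (max absolute error of the fitted conditionals against
the planted tables, typically < 0.01 at $10^5$ rows) confirms the counting
and smoothing paths. The degeneracy experiment confirms the observation
that on tiny, weakly dependent data the high-dependence learners collapse
to NB's performance: the CMI weights are then sampling noise, the augmented
arcs carry no signal, and the cross-validated losses of TAN/KDB/FKBN sit
within two standard errors of NB's.

Structure recovery is more instructive for what it does *not* achieve.
FKBN(K=2) on sharpness-0.1 data recovers roughly 60–85 % of planted arcs
as undirected adjacencies at $5\times10^4$ rows, and the rate is largely
flat in sample size. This is an information limit, not an estimation
limit: with near-deterministic conditional rows, a child's dependence on
one parent *marginalized over the other parent* — pairwise CMI, the only
signal any learner in this family uses — is frequently washed out
(XOR-like interactions are the extreme case), while sibling pairs (two
children of a common parent) carry genuinely high CMI and compete for the
capped parent slots. A budget-matched oracle that simply takes the
strongest empirical CMI pairs recovers *fewer* planted arcs than FKBN
does, so the algorithm extracts more than the raw pairwise ranking allows;
the residual gap is intrinsic to pairwise-CMI structure learning under a
$K$-parent cap. Practically: adjacencies the learner reports are well
supported, but absence of an arc is weak evidence of independence.

## Mining the learned DAG

`classify_key_attributes()` partitions attributes by their role in the
attribute-attribute graph: **key** nodes both have an attribute parent and
are themselves parents (they relay dependence — the first variables to
examine when reading the graph), **source** nodes have children but no
attribute parent (the tree root), and the rest are **secondary**.
`local_structure()` extracts the ancestor sub-DAG of a node (everything it
depends on, transitively) or its descendant sub-DAG (everything it acts
on). `to_dot()` renders the annotated graph as deterministic Graphviz DOT
with class arcs dashed, key nodes filled, and CMI arc labels at three
decimals.

## Numerical and design choices

* All entropies and information measures in bits; the choice affects no
  argmax or ordering, only reported magnitudes.
* Every tie anywhere — edge weights, MI order, pair order, modal values,
  posterior argmax — breaks by ascending index or first occurrence, so
  identical inputs give byte-identical outputs.
* Kruskal rather than Prim for the spanning tree: the global edge sort
  makes the treatment of equal weights explicit and reproducible.
* The tree root is the attribute with maximal $MI(X_i;C)$ (ties: lowest
  index), mirroring KDB's use of MI and placing the most class-informative
  attribute ancestral.
* Stage-2 FKBN arcs with zero CMI are skipped: a zero-weight augmentation
  adds parameters without information and would hide the degeneracy
  behaviour on weakly dependent data. Zero-weight *tree* edges are kept —
  a spanning tree is part of the TAN/FKBN contract.
* Structures, models, datasets and matrices all serialize to plain text
  and round-trip losslessly; model files store log-probabilities at full
  precision (`%.17g`).

## Known limitations

* No search over $K$, no score-based (BIC/BDe) structure learning, no
  latent variables, no probability calibration, and no marginalization over
  attributes missing at prediction time (imputation handles missingness
  upstream).
* The sign-test tie mode needs per-instance paired correctness; when only
  published loss tables are available, rank rows must be taken as given
  (the `compare --ranks` path).
* Pairwise CMI cannot see pure interaction effects, with the structure
  recovery consequences described above.
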