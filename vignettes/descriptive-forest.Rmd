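---
title: "Descriptive forests: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptive forests: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(descforest)
```

## The problem

A tabular disease dataset assembled from several environments (different
hospitals, surveys, cohorts) rarely has *one* dominant risk structure.
Each contributing environment tends to have its own primary risk factor,
and a single greedy decision tree induced on the pooled data lets one
factor win the root split; competing factors are fragmented across deep
branches or vanish entirely. The descriptive forest replaces the single
tree with a committee of small trees, one per discovered *main topic*, so
that each latent risk structure is described by its own tree and every
record receives either a topical explanation or an explicit "no risk from
the discovered topics" statement.

The package targets descriptive, dataset-level analysis. Accuracy,
precision and recall are computed on the dataset being described (the
training data, deliberately), as measures of how correct and how complete
the forest's *explanations* are — not as estimates of generalization to
new patients.

## Topic discovery in support--confidence space

Every class association rule (CAR) with the positive class as consequent
is a point $(s, c)$: support $s = P(A \wedge \text{positive})$, confidence
$c = s / P(A)$. The *domain rule* $\varnothing \Rightarrow \text{positive}$
sits at $(p_0, p_0)$, the prevalence. Mining runs with support and
confidence thresholds of zero — the selective pressure comes next, from
the geometry, not from threshold tuning.

The association-rule tree grows breadth-first from the domain rule. A
candidate rule must extend an existing node's antecedent by exactly one
item; it is accepted iff its confidence strictly exceeds that parent's and
the slope of the segment joining the two rule points,
$$\text{slope} = \frac{c_{\text{child}} - c_{\text{parent}}}
                      {s_{\text{child}} - s_{\text{parent}}},$$
is at most $\tau$. With the default $\tau = -1$ a rule is kept only when
its confidence gain at least offsets its support loss; the boundary case
(slope exactly $\tau$) is accepted. When several parents qualify, the
candidate attaches to the parent with the steepest slope, which groups
refinements of a common topic under that topic. Supports and confidences
are compared at full precision; only display is rounded.

$\tau$ is configurable because the criterion is a family: smaller
$|\tau|$ admits more topics, larger $|\tau|$ fewer. $-1$ is the natural
unit-trade-off choice and the package default.

Two relations over the accepted topics matter downstream, and they are
deliberately different:

* **Exclusion/applicability** uses the global strict-subset order: a
  subset topic never claims an instance that one of its matched supersets
  claims, applied transitively (only maximal matched topics vote). The
  same order drives *exclusion training*: a subset topic's tree is trained
  only on the rows its superset topics do not claim. This generalizes
  cleanly when one two-item topic is a superset of two different
  singleton topics.
* **Independent/dependent labels** follow the grown tree's branches: a
  topic is dependent when another topic lies on its own root-to-leaf
  branch. Cross-branch subset coincidences (a singleton in one branch
  that happens to be contained in a two-item topic of another branch) do
  not make a topic "dependent" for reporting purposes, which matches how
  the discovered subgroups read off the interestingness space. Hand-built
  topic sets (no tree) fall back to the subset order.

## Per-topic trees and the least PTS

Each topic is a *boundary node*: `filter_by_topic()` selects its related
instances from the **undiscretized** table (numeric features stay numeric
inside the trees), minus the rows claimed by superset topics. On that
subdataset a C4.5-style tree is induced: multiway splits on categorical
features (one child per schema value, each categorical feature at most
once per path), binary splits on numeric features at midpoints between
adjacent distinct values, split selection by gain ratio, and a split is
admissible only if at least two branches receive `minNumObj` rows or
more. Pessimistic-error pruning (confidence factor 0.25, using the exact
binomial upper confidence limit) is applied bottom-up by default; there
is no subtree raising, so printed sizes from other toolkits are
comparable but not bit-identical.

Structure is generalized with the *prodigality for the tree structure*,
$\mathrm{PTS} = 2n - m$ for $n$ leaves and $m$ total nodes. Every
internal node of a $\geq 2$-ary tree has at least two children, so
$m \leq 2n - 1$ and $\mathrm{PTS} \geq 1$; large PTS means multiway
splits were fragmented into chains — a prodigal, hard-to-read structure.
`minNumObj` is swept over the grid `2..15, 20, 25, 30, 35, 40` and the
least-PTS entry wins. The tie chain is: least PTS, then best stratified
10-fold cross-validated accuracy (fixed seed, default 1, so sweeps are
reproducible), then smaller tree size, then larger `minNumObj`. The last
two links are the package's own determinism completion of the
least-PTS/best-accuracy rule, preferring the more parsimonious tree. A
hill-climbing variant (`climb_minnumobj()`) walks the sorted grid until
PTS worsens; the exhaustive sweep is the reference behavior. Note that
on purely binary feature spaces every tree is strictly binary and PTS is
identically 1, so selection is then driven entirely by the tie chain.

## Voting, ties, and coverage

Applicable trees vote; positive iff Yes strictly outnumbers No. Equal
votes are resolved by a configurable tie policy because two defensible
conventions exist: `"negative"` (the default — read an equal vote as no
risk, favoring precision) and `"best_f_measure"` (let the applicable tree
with the best F-measure on its related instances decide). An instance
matching no topic receives the no-risk outcome, which counts as a
negative prediction in forest-level metrics; per-tree reports instead
count rows outside the tree's boundary as `not_predicted`, so per-tree
counts conserve rows as `tp + tn + fp + fn + not_predicted = N` and the
forest row as `tp + tn + fp + fn = N`.

## Numerical and degenerate-input choices

* Missing values fail any non-trivial item predicate (fail-closed
  membership), and rows with a missing split value descend to the largest
  branch both in training and prediction. Fractional instance weighting
  was deliberately not implemented; the target datasets are near-complete
  after sentinel cleaning (sentinel codes such as a cholesterol of 0 are
  mapped to missing via configuration).
* Leaf label ties break toward the positive class (descriptive recall
  bias); gain-ratio ties break by schema feature order, then smaller
  threshold.
* An antecedent matching no rows has undefined confidence, reported as 0
  with a flag; undefined precision/recall are likewise 0-with-flag rather
  than errors, since degenerate boundaries occur on small tables.
* A topic whose subdataset is smaller than `min_rows` (default twice the
  fold count) is skipped with a warning; folds shrink with a warning when
  a class has fewer rows than folds.
* Supervised discretization is Fayyad--Irani MDLP (recursive
  entropy-minimizing cuts, minimum-description-length stop). A numeric
  feature that receives no cuts carries no class information at this
  resolution and is dropped from mining. The binary
  ("one indicator feature per bin") mode exists for sparse, imbalanced
  datasets where multi-bin items dilute support too fast; attribute
  selection before mining ranks discretized features by information gain
  (the ranker's evaluator is not fixed by the reference description;
  information gain is this package's choice) and keeps the top *k*
  (default 8).
* Mining caps antecedents at length 4 by default: discovered topics in
  practice have at most two items, and the cap keeps zero-threshold
  mining tractable; it is configurable.

## The synthetic generator

`synthetic_spec()` emulates the integrated-dataset setting so the whole
pipeline is testable without external downloads: a mixture of
subpopulations (by default a community stratum and a clinic-referral
stratum in which every risk marker is more frequent), independent feature
draws *within* a stratum, and planted topics that raise the positive
probability of matching rows to the topic's lift (the strongest matched
topic wins; stacking is deliberately not multiplicative so closed forms
stay simple). Because features are independent within strata, the
expected support and confidence of any planted antecedent — and hence its
expected slope — have closed forms (`expected_rule_stats()`), computed by
inclusion–exclusion over the topic match patterns.

The default specification plants `{Sex = M}` (lift 0.35), its superset
`{Sex = M, Smoking = Y}` (0.93), `{RestingBP > 170}` (0.88) and
`{Angina = Y}` (0.68) over seven features including a four-valued
chest-pain code and two pure-noise numeric columns, with base rate 0.02
and 2,000 rows. The closed-form slopes at these values are −2.0, −1.6,
−1.3 and −1.7 (prevalence ≈ 0.46), all safely inside $\tau = -1$, and the
noise columns receive no MDLP cuts — exercising the dropped-feature path.
The mixture is what makes the planted topics co-occur the way clinical
risk factors do; without it, topics over independent features divide the
prevalence among themselves and the slope criterion admits almost
nothing, which is itself an instructive property of the geometry.

What the generator does **not** emulate: real marginal distributions,
survey weights, measurement error, missingness patterns, or label noise
beyond Bernoulli sampling. Passing recovery tests therefore show that the
pipeline finds the structure it is designed to find under clean mixture
sampling — not that it would recover topics from any particular real
dataset.

## Problem sizes used by the test suite

Unit tests run on tables of 4–150 rows with brute-force oracles
(exhaustive antecedent enumeration up to 12 rows × 5 features, exhaustive
split search on 8-row tables, hand-computed MDLP examples). The
end-to-end recovery experiment uses the default 2,000-row specification
across five seeds, checking that all planted topics reappear among the
extracted topics in at least four of five seeds and that the forest's
recall is at least the single least-PTS tree's recall in at least four of
five; these sizes keep the full suite within a few minutes on one core
while leaving the binomial noise on rule statistics an order of magnitude
smaller than the closed-form slope margins.

## Known limitations

* Exact parity with other C4.5 implementations (subtree raising, MDL
  corrections on numeric splits, fractional missing-value weights) is out
  of scope; structural statistics can differ by a few nodes on the same
  data.
* The slope criterion evaluates sample support/confidence without
  significance testing; on small datasets a spurious rule can clear
  $\tau$ by chance, and on purely binary feature spaces PTS cannot
  discriminate structures.
* Voting is unweighted and uncalibrated by design — the output is a
  description with explanations, phrased in "may be at risk" terms, not a
  calibrated probability.
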