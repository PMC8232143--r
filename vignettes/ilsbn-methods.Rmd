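---
title: "Structure learning by DAG-space iterated local search: models, operators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure learning by DAG-space iterated local search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilsbn)
```

## The model and the score

A discrete Bayesian network couples a DAG `G` over variables
`X1, ..., Xn` with conditional probability tables, and represents the
joint distribution as the product of `P(Xi | Pa(Xi))`.  Structure
learning searches for the DAG maximising a score of fit against `N`
complete records.  `ilsbn` uses the BIC: per node, the maximised
multinomial log-likelihood

$$\sum_{\pi}\sum_{x} N(x,\pi)\,\ln\frac{N(x,\pi)}{N(\pi)}$$

minus the penalty $\tfrac{\ln N}{2}\,(r_i-1)\,q_i$, where $r_i$ is the
node's cardinality and $q_i$ the number of parent configurations.
Natural logarithms are used throughout (the base only rescales all
scores uniformly), $0\ln 0 \equiv 0$, and unobserved parent
configurations contribute nothing to the likelihood.  Two readings of
the penalty were possible; we count $q_i$ as the product of the parent
*cardinalities* — all configurations, observed or not, with
$q_i = 1$ for the empty set — because that is the standard BIC parameter
count and the only reading consistent with the empty-set convention.
The score is decomposable, so `score_delta()` prices an Add/Delete move
by re-scoring one node and a Reverse by re-scoring two; `score_cache()`
memoises local scores keyed on the sorted parent set.  A cache belongs
to one dataset; its evaluation counter doubles as the budget currency
for fair algorithm comparisons.

No maximum in-degree is imposed by default; `max_in_degree` in
`search_config()` activates one when parity with degree-capped baselines
is wanted.

## The operators and their guarantees

The package's contribution is a set of compound perturbation operators
that act on the DAG itself while preserving acyclicity, operating on the
edge set viewed as two parallel lists (from-list and to-list):

* **Leaf(X)** reverses every edge whose from-node is `X`.  Afterwards
  `X` has no outgoing edges, so no cycle can pass through it, and any
  cycle avoiding `X` would have existed before: acyclicity is preserved.
  The structural effect measured by SHD lies in `[1, u]` (`u` the
  maximum out-degree), attained at a hub that parents `u` children.
* **Root(X)** is the mirror image on incoming edges, with effect in
  `[1, k]` (`k` the maximum in-degree).
* **Swap(X, Y)** exchanges the to-nodes of one incoming edge of each of
  `X` and `Y` (two deletes plus two adds).  Candidate partners are
  screened against four failure categories: shared parent (the exchange
  is a no-op), parent/child coincidence (would create a self-loop),
  creation of a bidirectional pair, and duplication of an existing edge.
  A surviving exchange can still close a cycle; the repair applies Leaf
  to the from-node of each cycle-generating new edge (detected by a
  reachability test with the edge removed) until the graph is acyclic.
  Leaf rather than Root does the repairing because out-degrees typically
  exceed in-degrees, so Leaf explores the larger neighbourhood.  The
  effect is at least 4 — two adjacencies vanish and two appear — and at
  most `4 + 2u`.

Swap granularity deserves a note: exchanging exactly *one* incoming edge
per node (sampled uniformly when a node has several parents) is the only
granularity consistent with the lower bound of 4; exchanging whole
parent sets would scale with the in-degrees.

**Momentum(m)** draws, `m` times, a node uniformly and one of the three
operators uniformly, and applies it.  Draws where the operator cannot
act (Leaf at a leaf, Swap with an empty whitelist) are resampled up to
ten times and then skipped; the retry bound is our choice where the
procedure leaves the fallback open, and skipped draws are counted on the
returned object.  Node sampling is uniform *with* replacement across the
`m` iterations — repeated hits on the same node weakening the compound
effect is an accepted feature of the design, and nothing in the
procedure requires exclusivity.

## The search drivers

`hill_climb()` is best-improvement steepest ascent over
Add/Delete/Reverse, with moves ordered lexicographically by
`(kind, from, to)` so tie-breaking — and hence the whole trajectory —
is deterministic.  A move counts as improving when its delta exceeds
`tol = 1e-9`, a plain floating-point guard.

`ilsg()` iterates perturb (`pf` basic operations with the repair
conventions: a cycle-closing Add is applied in the opposite direction, a
cycle-closing Reverse is dropped) → hill climb → keep the better
structure, tracking the best ever seen.  After `sr` non-improving
iterations the incumbent is re-randomised while the best-so-far is kept.
Ties keep the incumbent, avoiding pointless cascades.

`ilsm()` nests a short `ilsg()` (budget `inner_iter`, default 5) inside
an outer loop whose perturbation magnitude follows the stride array
`{n/10, n/5, n/2, n}` (rounded, at least 1).  The method's standard tuning sets
`mo = n` Momentum objects, `rs = 20` non-improving outer rounds before
Momentum, and `rh = 5` Momentum applications before a full restart; these
are the defaults.  Two couplings were left open by the procedure and are
resolved as follows: the stride advances one position (capped at the last
entry) each time Momentum fires, since the stride exists to strengthen
the perturbation as the search stagnates; and `rh` counts Momentum
applications since the last improvement of the best score, so a
productive Momentum resets the path to restart.  A restart resets the
stride and both counters.  The inner/outer budget split is likewise
unspecified in the procedure; a bounded inner loop (so that the outer
scheduling actually engages) is ours.

The initial structure is a random DAG.  Its distribution is not fixed by
the method; `random_dag()` draws a uniform random permutation as a
topological order and includes each forward pair independently with
probability `2/(n-1)` (expected `n` edges), a scheme chosen because it
samples only valid DAGs and has a single interpretable knob.

Determinism: all randomness flows through the R session RNG; a `seed` in
`search_config()` makes `ilsg()`/`ilsm()` byte-reproducible, and the CLI
threads one `--seed` through every subcommand.

## Evaluation metrics

`shd()` counts missing plus extra plus incorrectly oriented edges, each
reversal counting one.  `bsf()` is
`0.5 (TP/a + TN/i − FP/i − FN/a)` with `a` the true edge count and
`i = V(V−1)/2 − a` the direct independencies.  The reversal convention
for the confusion counts is not fixed by the metric's definition; we
match edges *directed*, so a reversed edge contributes one FP and one FN
to BSF but only one unit to SHD — the two metrics legitimately differ.
One consequence, verified by exhaustive enumeration over 4-node pairs,
is that BSF's nominal lower bound of −1 (which presumes `FP ≤ i`) can be
undershot by graphs that reverse many true edges; the anchors BSF = 1 at
a perfect match and BSF = 0 for an empty learned graph are unaffected.
The fully connected baseline is likewise convention-dependent and is not
asserted.

## Synthetic data

`sample_dataset()` draws records ancestrally in topological order — the
operational reading of the factorisation.  `random_cpts()` fills a
structure with conditional rows drawn i.i.d. from a symmetric Dirichlet.
Low concentration gives peaked rows, but peaked does not mean
*detectable*: two configurations can peak on the same state, leaving the
parent statistically invisible.  (At concentration 0.1 on a binary
chain, roughly half the draws are of that kind — a property worth
knowing before using Dirichlet CPTs to benchmark edge recovery.)  Where
a dependence of known strength is needed, the shipped `fixture_asia()`
carries fixed, strongly dependent binary CPTs.  Those parameter values
are this package's own synthetic choices, deliberately not the published
parameterisation of the Asia network, so that no numeric claim in the
tests rests on values the package does not ship.  Sampled data are
complete by construction; missing-data mechanisms, continuous variables,
and selection effects present in real datasets are all outside what the
generator emulates, so passing tests speak to the algorithmic machinery,
not to robustness against those phenomena.

## Verification strategy and problem sizes

The acyclicity guarantees of Leaf and Root are checked *exhaustively*:
a compiled bitmask kernel enumerates every DAG on up to 6 nodes
(3,781,503 at n = 6, cross-checked against the known counts) and applies
both operators at every node; the R-level operators are tied to the
kernel by exact-agreement checks on all 4-node DAGs and random samples
at 5 and 6 nodes, plus direct checks on 500 random DAGs of 10–40 nodes.
Swap is verified exhaustively at 4 nodes — every legal
(DAG, node-pair, edge-pair) combination, 216 in all — for acyclicity,
screening cleanliness, and the `[4, 4+2u]` effect interval, with the
no-repair case cross-checked against an independently reconstructed
edge set.  Scoring is validated against an independent monolithic
oracle (built on R's `table()`, sharing no code with the package's
counting path) on 500 random 3–5 variable instances, and against
hand-evaluated closed forms.

Optimisation behaviour is checked at desk scale: fixture-sampled data
with `N = 1000` over 10 seeds, comparing `ilsm()` against restart hill
climbing under an equal delta-evaluation budget; and 3-variable
instances where the global BIC optimum is known by enumerating all 25
DAGs.  These sizes were chosen so the whole suite runs in minutes on a
single core while still exercising every scheduling path (Momentum
firing, stride stepping, restarts); the search budgets
(`max_iter = 40–60`, `inner_iter = 2`) are correspondingly modest and
are stated in each test.

## Known limitations

* Only complete discrete data and the BIC score; no BDeu/MDL/AIC, no
  equivalence-class (CPDAG) search, no ordering-space search, no exact
  solver.
* SHD compares DAGs directly, not equivalence classes: a Markov-
  equivalent reversal counts against the learned graph even though no
  score can distinguish it.
* The score cache is unbounded; at desk scale it stays small, but an
  eviction policy is left as a hook.
* Swap's cycle repair terminates because each Leaf strictly removes the
  cycles through its node, but the repaired structure can drift up to
  `2u` units beyond the minimal exchange — the price of staying inside
  DAG space.
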