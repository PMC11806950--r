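---
title: "Tracing influence paths with tri-variate information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing influence paths with tri-variate information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infotrail)
```

## The problem and the model

Network-inference tools applied to observational data in systems biology
tend to produce dense "haystack" graphs of pairwise associations in which
indirect relationships masquerade as direct ones. `infotrail` solves a
deliberately narrower problem: given one designated *anchor* feature $Y$
(an intervention, a perturbation, an experimental group label), trace how
the information carried by $Y$ percolates through the remaining features.

For a candidate chain $P = (Y, X_1, \dots, X_t)$ of distinct features the
package requires:

1. **anchor DPI**: $I(Y;P_i) > I(Y;P_{i+1})$ for every consecutive pair —
   information about the anchor must dissipate along the chain;
2. **local DPI**: $I(P_{i-1};P_i) > I(P_{i-1};P_{i+1})$ — each hop must be
   a genuine processing step, not a shortcut;
3. the minimal tri-variate interaction information
   $I(P_{i-1};P_i;P_{i+1}) = I(P_{i-1};P_i) - I(P_{i-1};P_i\,|\,P_{i+1})$
   along the chain is **positive and maximal** over all admissible chains
   to the same terminal.

Positive interaction information marks redundant (chain-like) triples;
synergetic triples such as XOR colliders are negative and therefore never
traversed. Both inequalities are *strict*: exact ties — including the exact
equalities produced by deterministic, noiseless copies — zero the edge.
This is a conservative design: the method refuses to orient flows it
cannot order, and noiseless data (where every DPI comparison ties)
deliberately yields an empty result.

## The search

The maxi-min objective is a widest-path problem, but the weight of
appending $X_c$ depends on the two preceding features, so the search runs
on a derived graph whose vertices are *ordered feature pairs*. An edge
$(X_a,X_b) \to (X_b,X_c)$ carries

$$w = \max\{I(X_a;X_b;X_c),\,0\}\;
      [I(X_a;X_b) > I(X_a;X_c)]\;
      [I(Y;X_b) > I(Y;X_c)],$$

with $[\cdot]$ the Iverson bracket. `init_scores()` seeds every pair
$(X_i,X_j)$ with the weight of $(Y,X_i) \to (X_i,X_j)$ (the $a = Y$ case)
and `run_search()` runs Dijkstra's algorithm on the $(\max,\min)$
semiring: always expand the unvisited pair with the best bottleneck score,
relax its successors, never revisit. Score ties at extraction are broken
at random under the run seed, which is part of the configuration — two
runs with the same data and seed are bitwise identical. Improved pairs are
lazily re-queued (no decrease-key structure); this is score-equivalent and
keeps the code simple at the $m \le$ hundreds scale the method targets.

The pair graph has $O(m^2)$ vertices and $O(m^3)$ edges, but only the
$m^2$ initial weights are computed eagerly; relaxation weights are
evaluated lazily and cached, so memory stays $O(m^2)$ and the dominant
cost in practice is the initial scoring sweep (the run log reports the
exact number of edge evaluations). The weight evaluations are mutually
independent, so they could be parallelized; the implementation here is
single-threaded.

Because the anchor-DPI gate forces $I(Y;\cdot)$ to decrease strictly along
any positively weighted pair path, no path can revisit a feature even
though the pair graph formally allows loops like
$A \to B \to C \to B$. The test suite checks this property on every
emitted path, and validates the whole search against an exhaustive
enumeration oracle (which deliberately allows feature revisits, so the
gates must rule them out on their own) on hundreds of small random tables.

A feature may still legitimately appear as *several distinct pair-nodes*
of the final tree — reached in different contexts — which is how
multi-modal agents are represented. `build_tree()` therefore merges paths
by shared pair prefixes, never by feature. Features that terminate their
own path are *leaves*; interior features are *relays*; a feature can relay
in many paths but leaf in at most one.

## Estimators

Two estimators are supported, selected by the `estimator` argument:

* **`mle`** — plug-in (maximum-likelihood) estimates on contingency
  tables. Ordinal columns are first discretized by `discretize()`:
  equal-frequency binning with `bins = 10` by default. The scheme was an
  open choice; equal-frequency was picked for robustness to skew, and the
  type-1 quantile boundaries make tie assignment deterministic. No
  small-sample bias correction is applied — scores are compared against a
  permutation null computed with the same estimator, which absorbs the
  common bias.
* **`kt`** — the Kendall transformation: each ordinal or binary column of
  length $n$ becomes $n(n-1)$ tokens `UP`/`DOWN`/`TIE`, one per ordered
  observation pair in a fixed lexicographic enumeration shared by all
  columns. MI on the tokens is rank-based, hence invariant under strictly
  monotone rescaling of any column (asserted bitwise in the tests). Ties
  are kept as a third token rather than dropped, so the transform length
  is fixed and no information is discarded; the cost grows with $n^2$, so
  KT is intended for the moderate sample sizes typical of the data this
  method targets. Unordered features with more than two categories have no
  total order; they are rejected with a pointer to
  `split_categorical()` (or expanded automatically with
  `auto_split = TRUE`).

All quantities are in nats throughout, including thresholds such as
`min_score`.

## The junction benchmark and its noise level

`gen_junction()` reproduces the canonical two-chain benchmark: binary
chains $Y \to A_1 \to A_2 \to J_A \to A_3$ and
$Y \to B_1 \to B_2 \to J_B \to B_3$, each link a symmetric bit-flip
channel with probability `eps`; $J_A, J_B$ are hidden and replaced by the
four-category pairing $J = (J_A, J_B)$. The correct analysis finds leaf
paths to $A_2, A_3, B_2, B_3$ (and $J$), keeps $A_1, B_1$ as relays only,
and represents $J$ twice — once per branch — exposing its bi-modality.

Two generator choices deserve explanation, because both are forced by the
structure of the problem rather than taste:

**Noise level.** For symmetric channels with per-link correlation
$\rho = 1 - 2\,\mathrm{eps}$, a feature $k$ links from $Y$ carries anchor
MI of order $\rho^{2k}$ (small-information regime), and the two hidden
junction inputs contribute additively to $J$, so
$I(Y;J) \approx 2\,\rho^6$ while $I(Y;A_2) \approx \rho^4$. The edge into
$J$ passes the anchor-DPI gate only if $I(Y;A_2) > I(Y;J)$, i.e.
$\rho^2 < 1/2$, i.e. $\mathrm{eps} > (1-1/\sqrt 2)/2 \approx 0.146$.
Exact enumeration of the network confirms this: at `eps = 0.1` the gate
fails in the population ($I(Y;J) = 0.240 > I(Y;A_2) = 0.222$ nat) and the
junction is unreachable, while at `eps = 0.2` it holds with a 0.020-nat
margin ($0.066$ vs $0.046$). The default is therefore `eps = 0.2`,
derived before any testing, and not a tunable of the benchmark.

**Chain balance.** Features at equal depth carry *exactly* equal anchor
information in the population ($I(Y;A_1) = I(Y;B_1)$), and only that
exact tie makes the strict gate reject cross-chain edges such as
$(A_1, B_1)$. A plain iid sample breaks the tie by noise and manufactures
one spurious cross-chain path of score $\approx I(A_1;B_1) \approx 0.066$
nat — the same order as the true paths, so no threshold removes it.
`gen_junction()` therefore draws $n/2$ rows and appends their $A/B$
mirror images: mirrored rows follow the same distribution (the chains are
exchangeable), but the empirical cross-chain contingency tables become
exactly equal and the population tie is restored in the sample. This is
the regime in which the benchmark topology is identifiable at all; it is
also why `n` must be even.

What the generator does *not* emulate: real data have heterogeneous,
asymmetric noise, non-binary and mixed-type features, latent confounders
other than the single junction, and no exact symmetries. Passing the
benchmark demonstrates that the search recovers a known topology under
the model's own assumptions, not that those assumptions hold in any
particular real dataset.

## Permutation null

`null_distribution()` re-runs the entire pipeline on copies of the data
in which *every* column — the anchor included — has been independently
shuffled, preserving marginals and destroying all joint structure.
Permuting only the anchor would be a cheaper near-equivalent null;
permuting everything is chosen because it matches the notion of "no
structure at all" and costs the same asymptotically. Scores of any paths
detected on the permuted copies are recorded and stratified by path
length, because longer spurious chains are rarer and weaker — confidence
in a detected path generally grows with its length. Percentiles are
empirical, inclusive (type-1 / inverted CDF), exposed per length and
pooled; replicate seeds are derived from the master seed up front, so the
null is reproducible regardless of evaluation order.

## Numerical choices and degenerate inputs

* Strict gate comparisons use exact floating-point `>` with no epsilon:
  the gates are defined with strict inequalities, and an epsilon would
  convert a principled tie-rejection into an arbitrary threshold.
* Plug-in MI and CMI are clamped at 0 against $-10^{-16}$-scale float
  noise; interaction information is *not* clamped (synergy must stay
  negative) except inside the edge weight, where the max-with-0 is part
  of the definition.
* Pruning keeps paths with score $\ge$ the threshold (inclusive), so a
  user-supplied cutoff equal to a reported score keeps that path.
* Empty tables, missing values, absent anchors, single-feature tables and
  noiseless (all-tie) data all fail fast with instructive errors or
  return valid empty results; the serializers emit well-formed empty
  documents for empty trees.
* Missing-value imputation is out of scope by design — rejection with a
  named column beats silent imputation in a method whose output is a
  hypothesis-generating topology.

## Problem sizes used in the checks

The packaged checks run the junction benchmark at $n = 5000$ (20
generator seeds) for topology recovery, $n = 1000$ with 100 permutation
replicates for null calibration, and validate the search against the
enumeration oracle on 200 random tables with up to 5 non-anchor features
and $n \le 500$ — sizes at which exhaustive enumeration is exact yet the
whole suite stays fast. These are the package's own verification
conditions; the algorithm itself has no built-in size limits beyond the
$O(m^2)$ memory of the pair matrices and the $n^2$ growth of the Kendall
transform.

## Known limitations

* The DPI gates assume information genuinely dissipates per hop; feedback
  loops, deterministic relays and exactly synchronized features violate
  this and are (conservatively) not traversed.
* Plug-in MI is biased upward at small $n$; the permutation null — which
  shares the bias — is the intended calibration instrument, not the raw
  scores.
* The KT estimator's $n(n-1)$ blow-up makes it quadratic in observations;
  it is the right tool for ordinal data at moderate $n$, not for very
  large cohorts.
* Paths are anchored at a single $Y$; multi-anchor designs require
  separate runs.
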