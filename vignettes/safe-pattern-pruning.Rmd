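---
title: "Safe pattern pruning: models, bounds, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Safe pattern pruning: models, bounds, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

sppmine fits sparse linear models whose features are *patterns*: the
sub-itemsets, gapped subsequences (or contiguous substrings), and connected
labeled subgraphs of structured inputs.  With binary occurrence indicators
$x_{ij} \in \{0,1\}$ ("instance $i$ contains pattern $j$"), the model is

$$\min_{\beta_0,\beta}\; P(\beta) = L(\beta_0 \mathbf 1 + X\beta)
  + \lambda \sum_j \Bigl(|\beta_j| + \tfrac{\kappa}{2}\beta_j^2\Bigr),$$

with the squared loss $L(v)=\lVert v-y\rVert^2/(2n)$ for regression or the
squared hinge $L(v)=\sum_i \max(1-y_iv_i,0)^2/(2n)$ for classification in
$\{-1,+1\}$.  The intercept is fitted but never penalized.  The catch is that
$j$ ranges over *every* pattern occurring in the data — a set that grows
exponentially with instance complexity — so the design matrix is never
materialized.

## Duality, screening, and pruning

The Fenchel dual maximizes $D(\alpha) = -L^*(-\alpha) -
\sum_j \omega^*_j(X_{:j}^\top\alpha)$.  For both losses
$-L^*(-\alpha)=\alpha^\top y - \tfrac n2\lVert\alpha\rVert^2$ (restricted to
the orthant $y_i\alpha_i\ge 0$ for the squared hinge), and the elastic-net
conjugate is $0$ for $|v|\le\lambda$, $(|v|-\lambda)^2/(2\kappa\lambda)$ for
$\kappa>0$, and $+\infty$ otherwise.  Any primal/dual feasible pair
$(\tilde\beta,\tilde\alpha)$ confines the dual optimum to a sphere of radius
$r=\sqrt{2\gamma\,(P(\tilde\beta)-D(\tilde\alpha))}$ around $\tilde\alpha$,
with $\gamma=1/n$ the Lipschitz constant of $\nabla L$ under the $1/(2n)$
normalization.  Two bounds follow:

* the **screening score** $u_j = |X_{:j}^\top\tilde\alpha| +
  r\,\lVert X_{:j}-\Pi_{\mathbf 1}(X_{:j})\rVert$: if $u_j < \lambda$
  (strictly; ties keep the feature) the optimal coefficient is zero;
* the **pruning score** $v_j = \max\bigl(\sum_{\tilde\alpha_i>0}
  x_{ij}\tilde\alpha_i,\, -\sum_{\tilde\alpha_i<0} x_{ij}\tilde\alpha_i\bigr)
  + r\,\lVert X_{:j}\rVert$: both of its terms can only shrink when the
  support shrinks, and supports shrink monotonically along the enumeration
  tree, so $v_j < \lambda$ eliminates the *entire subtree* below $j$.

A node can fail its own screening test while a descendant is still active,
so only $v$ controls descent; $u$ only decides working-set membership.  The
miner therefore guarantees a superset of the active set after a single
depth-first traversal, with children generated in canonical-key order
(lexicographic item extension; PrefixSpan projected-database extension;
gSpan rightmost-path extension with minimum-DFS-code canonicality), making
the traversal deterministic.

With two reference solutions the dual optimum lies in the intersection of
two spheres and the centering hyperplane.  The package evaluates the exact
maximum of $|X_{:j}^\top\alpha|$ over that lens in $O(n)$ per column: the
sphere whose cap binds gives a single-reference-style bound, otherwise the
maximum sits on the lens boundary, at radius
$r' = \sqrt{r_2^2 - t^2\lVert\delta\rVert^2}$ around the combination point
$t\tilde\alpha^{(1)}+(1-t)\tilde\alpha^{(2)}$, with the column norm taken
after projecting out both the constant direction and $\delta$.  Degenerate
geometries (coincident centers, nested spheres, zero radii) fall back to
the minimum of the two single-reference scores, which is always a valid
bound; disjoint spheres additionally warn, since they indicate an
infeasible reference.  Two-reference *pruning* uses
$\min(v_j(R_1), v_j(R_2))$ — the lens version has no closed form.

## Dual scaling

Optimizers update only the primal, so dual candidates are manufactured from
$\bar\alpha = -\nabla L(X\tilde\beta)$:

* **Centering.** The intercept's conjugate forces
  $\mathbf 1^\top\alpha = 0$; $\bar\alpha$ is projected onto that hyperplane
  ($\bar\alpha - \operatorname{mean}(\bar\alpha)\mathbf 1$).  For the squared
  hinge, a sign-split scaling (positive-class entries multiplied by
  $-\sum_{y=-1}\bar\alpha_i / \sum_{y=+1}\bar\alpha_i$, with the reciprocal
  convention when that denominator vanishes) achieves centering without
  leaving the orthant on which $-L^*$ is finite.
* **Scaling.** For $\kappa = 0$ the box $|X_{:j}^\top\alpha|\le\lambda$ must
  hold over *all* patterns; the centered vector is multiplied by the
  gap-minimizing scalar $\mu = \alpha''^\top y /(n\lVert\alpha''\rVert^2)$
  clipped to $\pm\lambda/\max_j|X_{:j}^\top\alpha''|$ (nonnegative for the
  squared hinge).  Under the $1/(2n)$ loss normalization the $1/n$ factor in
  $\mu$ is what makes $\mu \to 1$ as the primal approaches the optimum.
  The maximum over all patterns is computed exactly by a branch-and-bound
  traversal: the positive/negative-part bound that powers pruning also
  upper-bounds $|X^\top_{:j}\alpha|$ over any subtree.
* For $\kappa > 0$ there is no box constraint and the centered vector is
  used at its natural scale ($\mu=1$).  A box-free "gap-minimizing" rescale
  would ignore the conjugate-penalty term $\sum_j\omega^*_j$ and can loosen
  the bound badly near the optimum, so it is deliberately not applied.

The dual value itself is computed exactly at reference-construction and
certification time: for $\kappa>0$, the conjugate-penalty sum over all
patterns with $|X_{:j}^\top\alpha| > \lambda$ is collected by the same
bounded traversal.  During in-solver dynamic screening the working-set
problem's own gap is used instead; this is sound because the mined working
set provably contains the full active set, hence the working-set dual
optimum coincides with the full dual optimum.  Final convergence is always
re-certified against the exact full-space dual.

## Solver and schedules

Coordinate descent with the elastic-net proximal update: exact coordinate
minimization for the squared loss, and a $1/n$-Lipschitz majorized step for
the squared hinge (step exactness is not needed — only the gap certificate
is).  Defaults follow the package's standard study settings: convergence at
relative gap $\varepsilon = 10^{-4}$ (i.e. $P-D \le \varepsilon\max(1,|P|)$),
dynamic screening at cycles $1,3,5,7,9$ and every 10th cycle thereafter,
$\lambda$ grids log-spaced from $\lambda_{\max}$ to $0.01\lambda_{\max}$
(10 points by default), and the $\kappa$ grid $\{0, 0.01, 0.1, 1, 10,
100\}$.  $\lambda_{\max}$ is the exact tree-searched maximum correlation at
the intercept-only optimum, so the first path point is analytically the
zero model.

At each screening event the current iterate is dual-scaled and the best
dual value seen so far is retained; because coordinate descent is monotone
in $P$, the reported gap sequence is non-increasing by construction — a
deliberate numerical choice that also keeps the screening radius monotone.
With two references, the first $M$ (default 1) screening events maintain
and screen with *both* solutions via the lens bound, after which the
larger-gap solution is discarded and optimization continues seamlessly from
the survivor; $M=0$ means the second reference is used only at mining time.

Two-dimensional paths traverse $(\lambda,\kappa)$ with $\lambda$ outermost,
referencing the previous-$\lambda$ and previous-$\kappa$ optima
(dual-rescaled at the current cell); the $\lambda_{\max}$ column is copied
rather than solved, since the zero model is optimal there for every
$\kappa$.  Cross-validation first solves the full-data path, then screens
each fold/λ subproblem with the full-data optimum at the same $\lambda$
and the fold's optimum at the previous $\lambda$.  Model selection
minimizes mean held-out loss (squared error, or squared hinge for
classification, with 0/1 error also reported); ties break toward the
stronger regularization.

## Identifiability and how results are compared

Binary occurrence columns are frequently identical (a pattern and its
extension can occur in exactly the same instances) or linearly dependent.
All patterns are kept as separate features — the model's dimension counts
patterns, not distinct columns — with these consequences, which the test
suite respects:

* fitted values and the objective value are always identified;
* for $\kappa>0$ the optimum is unique, but the *within-group split*
  across identical columns is the ill-conditioned direction (its error
  scales like $\sqrt{2\,\mathrm{gap}/(\lambda\kappa)}$), so coefficient
  comparisons collapse identical columns to their group sum;
* for $\kappa=0$ the collapsed coefficients are identified exactly when the
  deduplicated equicorrelation set has full column rank; the oracle
  equivalence tests verify that condition and compare coordinates when it
  holds, falling back to fitted-value and objective equivalence when it
  provably cannot hold.

## The synthetic generator and the verification oracle

The generator plants $k$ patterns (default 3, unit effects, $n=200$,
Gaussian noise sd 0.1 — the conditions under which support recovery is
assessed) into random background structure: Bernoulli item draws, uniform
random symbol strings with contiguous pattern insertion (contained under
both sequence modes), and random labeled graphs (spanning tree plus extra
edges) with the planted subgraph attached.  Responses are computed from
*actual containment tests*, so the generating model is exactly the model
class being fitted.  Draws are rejected unless every planted support
fraction lies in $[0.1, 0.9]$ and no planted pattern's column coincides
with one of its own sub-patterns' columns (otherwise the sub-pattern, which
precedes it in canonical order, would absorb the signal).  Classification
labels re-draw the intercept until both classes hold at least 20% of
instances.  What the generator does not emulate: correlated background
structure, label noise in the structures themselves, heavy-tailed effect
sizes, and the scale of real chemistry datasets — passing tests demonstrate
algorithmic correctness, not real-data performance.

The brute-force oracle enumerates every pattern (no pruning, guarded),
builds the dense design, and solves with FISTA plus adaptive restart to a
$10^{-10}$ relative gap — a different algorithm family from the coordinate
descent solver, so agreement between the two is an informative check.  Its
certificate is recomputed from explicit formulas inside the tests, and its
squared-loss solutions are additionally cross-checked against glmnet
(note: glmnet standardizes the response internally, which rescales the
effective L2 strength by the response's standard deviation, and its
coordinate updates can stall on exactly duplicated binary columns — the
cross-check therefore runs on the deduplicated design with the sd-adjusted
parameterization).

## Problem sizes and limitations

The test and acceptance workloads use $n \le 40$ with at most a few
thousand enumerated patterns for oracle-verified checks, and $n = 200$ for
recovery studies — sizes chosen so every property is verified against
exhaustive enumeration in minutes.  Default maximum pattern sizes are 3
items, 10 symbols, and 5 edges (configurable).

Known limitations: sequences and itemsets share the same traversal
machinery but graphs pay an exponential worst case in the minimality check
(fine for small patterns, the intended regime); only two references are
combined (three-sphere intersections have no implemented closed form);
lens-based *pruning* is approximated by the min rule; and the squared hinge
uses majorized coordinate steps, which can need more cycles than exact
minimization at very tight tolerances.
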