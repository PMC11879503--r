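---
title: "Network psychometrics for questionnaire subscales: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network psychometrics for questionnaire subscales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psynet)
```

## The model

psynet treats a battery of questionnaire subscale scores — here eight nodes:
three schizotypy dimensions (cognitive–perceptual, interpersonal,
disorganized), two emotion-regulation strategies (reappraisal, suppression),
and three negative-affect dimensions (depressed mood, anxiety, stress) — as a
system of interacting variables rather than indicators of a latent disease.
The core object is a Gaussian graphical model: an undirected network whose
edge between nodes $i$ and $j$ is their partial correlation given all other
nodes,
$$\rho_{ij\cdot\text{rest}} = -\,\kappa_{ij}\big/\sqrt{\kappa_{ii}\kappa_{jj}},$$
where $\kappa$ are entries of the precision (inverse covariance) matrix. A
missing edge means conditional independence under the Gaussian model.

Because subscale sums are bounded, integer-valued and skewed, dependence is
estimated with Spearman rank correlations (average ranks for ties), and the
correlation matrix is repaired to positive definiteness by eigenvalue
clipping at $10^{-6}$ with rescaling to unit diagonal whenever needed
(rank-based matrices are not guaranteed PD). Whether scores are z-scored
before ranking is immaterial — ranks are invariant to monotone
transformations — so the package ranks raw scores.

The precision matrix is estimated by the graphical lasso: maximize
$$\log\det K - \operatorname{tr}(RK) - \lambda \sum_{i \neq j} |\kappa_{ij}|$$
over positive-definite $K$. The diagonal is not penalized (the convention of
the standard psychometric tooling). The solver is a block coordinate-descent
algorithm written in C++; every fit satisfies the KKT conditions of this
objective to high precision, which the test suite checks against an
independent proximal-gradient optimizer. Entries below $10^{-8}$ in absolute
value are snapped to exact zero and define the edge count $E$.

Model selection follows the extended BIC over a penalty path:
$$\mathrm{EBIC}_\gamma = -2\ell + E\log n + 4\,E\,\gamma \log p,$$
with $\gamma = 0.5$ by default, 100 log-spaced penalties from
$\lambda_{\max} = \max_{i\ne j}|r_{ij}|$ (at which the network is exactly
empty) down to $0.01\,\lambda_{\max}$, ties broken toward the sparser model.
No post-selection refit is applied: reported weights are the penalized
estimates. A consequence worth knowing: within a run of constant $E$, EBIC
decreases as $\lambda$ falls (shrinkage bias recedes), so the selected model
occasionally carries one or two very small spurious edges (|w| ≈ 0.01–0.05).
This is inherent to EBIC-glasso without refit, not a solver artifact — an
independent implementation reproduces it exactly.

## Centrality, predictability, bridges

Strength ($\sum_j |w_{ij}|$) and expected influence ($\sum_j w_{ij}$) read
directly off the weights. Path-based indices use the distance transform
$d_{ij} = 1/|w_{ij}|$: closeness is the inverse of the summed shortest-path
distance to all reachable nodes (reachable counts are recorded for
disconnected graphs), and betweenness is Brandes' fractional count excluding
endpoints. Conventions differ across software; these are asserted against
exhaustive path-enumeration oracles in the tests, so the definitions are
pinned by code, not prose.

Predictability is the $R^2$ of each node regressed on all others — the
variance a node's neighbors explain. For Gaussian data this has the closed
form $1 - 1/(\kappa_{ii}\sigma_{ii})$, which the tests verify. A nodewise
mixed-graphical estimator would be an alternative for strictly categorical
items; with quasi-continuous subscale sums the least-squares $R^2$ keeps the
same interpretation.

Bridge centrality restricts each index to edges crossing the instrument
communities (SPQ / ERQ / DASS, fixed by design rather than detected): bridge
strength and bridge expected influence (1-step) sum absolute and signed
cross-community weights; bridge closeness is the inverse mean distance to
the other communities; bridge betweenness counts shortest paths between
nodes of two different communities passing through the node. Bridge nodes
are selected strictly above the 80th percentile (linear interpolation) of
each index — with ties at the cutoff excluded, all-equal indices select
nothing, which is the conservative reading of a percentile rule.

## Stability and accuracy

Edge accuracy uses the nonparametric bootstrap: resample participants with
replacement, re-run the entire estimator (ranking, repair, path, EBIC), and
take percentile 95% intervals per edge; bootstrapped difference tests
declare two edges (or two nodes' centralities) different when the percentile
interval of their difference excludes zero. Centrality stability uses the
case-dropping bootstrap over the proportion grid 0.10–0.70 by 0.10 plus
0.75: at each drop proportion the correlation between subsample and
full-sample centralities is recorded, and the CS coefficient is the largest
proportion at which at least 95% of replicates still correlate ≥ 0.7. The
conventional interpretability benchmark is CS > 0.5; betweenness typically
fails it and is reported without interpretation. Default replicate counts
are 1000; the tests and the acceptance script run 100–200 replicates, which
is enough to exercise every code path and keeps a desk-scale run in minutes.

## Comparing two networks

The permutation comparison test estimates each group's network, then
repeatedly pools and reassigns participants to groups of the original sizes,
re-estimating both networks per permutation. Network structure is compared
by $M$, the maximum absolute edge difference; global strength by $S$, the
absolute difference of summed absolute weights. P-values use
$(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$, so they are never zero and
the test is exact-level under exchangeability. Edge-level differences are
tested against their own permutation distributions with Benjamini–Hochberg
correction across the $p(p-1)/2$ edges; strength and expected-influence
differences per node are tested the same way. Note the floor: with $B$
permutations the smallest attainable adjusted p is about $28/(1+B)$ for
eight nodes, so edge-level testing needs $B \gtrsim 1000$ to be able to
reject at .05 at all; the package default is 10,000.

Median splits on a total score assign strictly-below to the low group and
strictly-above to the high group, excluding participants at the median. With
discrete totals this exclusion is substantial and bounds the imbalance:
both groups lie in $[n/2 - \text{ties}, n/2]$.

## Directed structure

Beyond the undirected network, a linear-Gaussian Bayesian network is learned
by hill climbing on the decomposable score
$\sum_i [\ell_i(\text{node}_i \mid \text{parents}_i) - \tfrac{k_i}{2}\log n]$
with $k_i = |\text{parents}_i| + 2$ (slopes, intercept, residual variance);
data are z-scored per column, which leaves the learned structure invariant.
The search accepts the best strictly score-improving add/delete/reverse move
until none exists, then, per restart (default 5), perturbs the incumbent
optimum with 10 random legal moves and re-climbs. Local scores are cached by
(node, parent-set) via the scatter matrix, so scoring cost is independent of
$n$ after one cross-product. At three nodes the search provably attains the
exhaustive optimum over all 25 DAGs in the tests.

Learned DAGs are reduced to their Markov equivalence class (CPDAG): keep the
skeleton, keep v-structures directed, close under Meek's rules R1–R3 (R4
only arises with background knowledge, which the package never injects).
Arc confidence comes from bootstrap: each of $B$ row-resamples is re-learned
and converted to a CPDAG; presence is the fraction of resamples containing
the edge in any orientation, and direction the fraction orienting it a given
way among those (undirected CPDAG edges count 0.5 each way, so the two
directions always sum to one). The consensus network retains pairs with
presence ≥ 0.85 oriented where direction > 0.5; pairs at exactly 0.5/0.5
remain undirected and flagged, and the full ≥ 50% listing is kept for
sensitivity reading since published thresholds vary (50/75/85%).

## The synthetic-data generator

Because the study's raw data are not deposited, the generator is the test
bed. It draws latent multivariate-normal vectors with a user-specified
dependence structure — either a precision matrix built from requested
partial correlations (diagonal inflated geometrically by a factor 1.3 when
the request is not jointly positive-definite, with the achieved, shrunken
partials recorded) or a linear-Gaussian DAG — and maps each latent column
through its normal CDF and the inverse CDF of a shifted binomial on the
subscale's score range, with success probability chosen so the mean matches
the published descriptive table exactly in distribution. Sums of yes/no or
Likert items are approximately binomial-shaped, which buys bounded, integer,
skewed scores with one free parameter; SDs and kurtosis are consequently
only approximate (e.g. the cognitive–perceptual SD comes out near 1.4
against a published 2.08 — real items are correlated within scales, which a
binomial cannot encode). The transform is monotone per column, so Spearman
structure survives discretization up to attenuation; dependence is specified
on the latent Gaussian scale and the observed-scale rank correlations are
slightly attenuated versions of it. Group differences are injected only
through precision edges, never marginals, so comparison tests target
structure.

What passing tests on this generator do **not** show: robustness to
item-level measurement error, within-scale item dependence beyond the
subscale sums, demographic confounding, or non-copula dependence. The
generator is a controlled environment for the estimators, not a simulacrum
of children.

## Numerical and design choices

- **Seeding.** One master seed; every stage (simulation, bootstrap,
  case-dropping, each comparison contrast, each DAG fit) draws from a fixed
  substream (`substream_seed`), so disabling or reconfiguring one stage
  never changes another's numbers. The pipeline is byte-reproducible.
- **Solver tolerances.** Outer glasso convergence at relative change
  $10^{-9}$ of the mean absolute off-diagonal; inner lasso an order
  tighter; KKT violations in tests bounded at $10^{-4}$.
- **Degenerate inputs.** Constant columns fail fast with the column named;
  degenerate bootstrap/permutation resamples are redrawn (logged, at most
  10 times); collinear parents in DAG scoring fail naming the node.
- **Problem sizes.** Tests and the acceptance script run at n = 300–2000,
  p = 8, with 100–200 bootstrap replicates and 200–1000 permutations —
  sizes chosen so the full suite exercises every claim at desk scale while
  each simulation retains enough resolution for the property under test.
- **Outlier sensitivity.** The optional re-run excludes participants with
  |z| > 3.29 on any subscale; the rule is a documented stand-in for the
  study's (unavailable) supplementary procedure.

## Known limitations

The EBIC-glasso occasionally admits tiny spurious edges (above); weights are
penalized, hence biased toward zero. Hill climbing explores a tiny fraction
of DAG space at p = 8 and relies on restarts for local-optimum escape; arc
directions from purely observational Gaussian data are identified only up to
the equivalence class, so consensus orientations lean on bootstrap asymmetry
rather than identifiability. The generator's binomial marginals understate
the published SDs. None of these affect the package's contracts, all are
visible in its outputs.
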