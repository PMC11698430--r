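---
title: "Statistical edge filters for weighted network backbones: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical edge filters for weighted network backbones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(netbackbone)
```

## The filtering problem

Given an undirected simple graph with positive edge weights $w_{ij}$, node
degrees $k_i$, strengths $s_i = \sum_j w_{ij}$ and total weight
$T = \tfrac12 \sum_i s_i$, each filter specifies a null model for how weight
could have been placed on edges, and scores each observed edge with the
probability of seeing a weight at least as large under that null. Extraction
then keeps edges with (optionally corrected) $p \le \alpha$; we keep
boundary ties because the removal rule is "drop edges with $p$ *above* the
level". One p-value is computed per edge, so the multiple-testing family
size is $m = |E|$ per network and method.

## The seven null models

**Disparity (`df`).** A node of degree $k$ splits its strength as a uniform
random partition; the one-sided p-value of an incident edge is
$(1 - w/s)^{k-1}$. Degree-1 endpoints have a degenerate null (their single
edge must carry everything) and contribute $p = 1$. The edge p-value is the
minimum over the two endpoints — an edge is kept when *either* endpoint
finds it surprising.

**Pólya urn (`pf`).** The node allocates its $s$ integer weight units
sequentially; each unit lands on an edge with probability proportional to
$1/a$ plus the units already there. The resulting edge weight is
beta-binomial, $W \sim \mathrm{BetaBin}(s,\, 1/a,\, (k-1)/a)$, and the
one-sided p-value is its survival at the observed weight. The reinforcement
$a$ interpolates between regimes: at $a = 1$ and large $s$ the null
converges to the disparity filter (a property the tests check at
$s = 10^4$), while as $a \to \infty$ the urn approaches winner-take-all and
the p-value tends to $1/k$ independently of the weight.

**Marginal likelihood (`mlf`).** All $T$ weight units are placed
independently on node pairs with probability
$q_{ij} = s_i s_j / (2T^2)$, preserving total weight exactly and strengths
on average; $p = P(\mathrm{Bin}(T, q_{ij}) \ge w)$, symmetric in the
endpoints.

**Noise corrected, binomial approximation (`nc`).** The same construction
with $N_t = 2T$ trials and $q_{ij} = s_i s_j / N_t^2$. The null mean
$s_i s_j / N_t$ equals the marginal-likelihood filter's; only the variance
differs (NC's is slightly larger since its success probability is halved),
which is why the two methods agree closely but not exactly, and why the NC
backbone tends to sit inside the MLF backbone. The full Bayesian
posterior-variance variant with its $\Delta$-threshold is out of scope; only
the binomial approximation is implemented.

**Enhanced configuration model (`ecm`).** The maximum-entropy ensemble of
weighted graphs whose expected degree *and* strength sequences match the
observed ones. Each node gets multipliers $x_i > 0$ (degree) and
$y_i \in (0,1)$ (strength); a pair connects with probability
$p_{ij} = x_i x_j y_i y_j / (1 - y_i y_j + x_i x_j y_i y_j)$ and carries a
geometric weight given connection, so the tail is closed form:
$P(W_{ij} \ge w) = x_i x_j (y_i y_j)^w / (1 - y_i y_j + x_i x_j y_i y_j)$.

**Global statistical significance (`gloss`).** Weights are drawn from the
network's empirical weight distribution $\hat P$ over the fixed observed
topology. The default `conditional` mode conditions the null law of an edge
on its endpoints' observed strengths and degrees,
$$p(w \mid s_i, s_j, k_i, k_j) \propto \hat P(w)\, Q^{(k_i-1)}(s_i - w)\,
  Q^{(k_j-1)}(s_j - w),$$
with $Q^{(m)}$ the $m$-fold convolution of $\hat P$ on the integer grid
($Q^{(0)}$ a point mass at 0); the p-value is the normalized tail at the
observed weight. The `marginal` mode is the plain survival
$\Pr_{W\sim\hat P}(W \ge w)$. Marginal-mode p-values are by construction a
monotone decreasing function of weight (rank correlation with weight exactly
$-1$), which makes the mode distinguishable at a glance; the conditional
mode is the default because an unconditioned global survival cannot produce
the moderate weight correlations this family of methods is reported to have.

**Locally adaptive sparsification (`lans`).** Purely empirical: from each
endpoint, the p-value is the fraction of that node's incident edges
*strictly* heavier than the edge; the edge keeps the minimum of the two.
Strict counting is a deliberate choice: it gives every node's strongest edge
a one-sided $p = 0$, so LANS retains at least one edge per node at any
$\alpha > 0$ and never isolates nodes — the signature behavior of this
filter. Counting "equal or heavier" instead would give the top edge
$p = 1/k$ and destroy node preservation; both conventions are exercised in
the tests, strict is used throughout.

## Corrections and extraction

Bonferroni ($\min(1, mp)$) and Benjamini–Hochberg step-up
($\min(1, \min_{j\ge i} m p_{(j)}/j)$) are applied through
`stats::p.adjust`; the corrections return adjusted p-values rather than
reject flags so that similarity analyses can correlate corrected p-values
directly. A backbone's node set is the set of endpoints of retained edges:
nodes that lose all edges are dropped, otherwise the node fraction would be
identically 1 and node-preservation comparisons meaningless.

## Parameters that matter

* `alpha` — significance level, default 0.05 (the conventional level used
  throughout the comparative studies).
* `pf_a` — Pólya reinforcement, dimensionless, default 1 (the
  disparity-limit convention). The comparative studies in the acceptance
  script run PF additionally at $a = 1000$: at $a = 1$ PF nearly duplicates
  DF, so the weight-decoupled behavior PF is known for only appears in the
  strong-reinforcement regime. The parameter is a genuine degree of freedom
  of the method, not of this implementation.
* `gloss_mode` — `conditional` (default) or `marginal`, see above.
* `ecm_tol` (default $10^{-6}$) and `ecm_max_iter` (default 5000) — maximum
  allowed residual on *both* $\max_i |\langle k_i\rangle - k_i|$ and
  $\max_i |\langle s_i\rangle - s_i|$, and the iteration budget.
* Edge betweenness is computed on the unweighted topology (hop counts) by
  default, reading the shortest-path formula literally and avoiding an
  arbitrary weight-to-distance transform; `distance = "inverse_weight"` is
  available. The sum runs over unordered node pairs.
* Weight entropy is the Shannon entropy (bits) of the weight shares
  $q_e = w_e/\sum w$ — scale-invariant, so "entropy preservation" is
  comparable across backbones. (A binned-histogram entropy would depend on
  an arbitrary bin width.)

## Numerical choices

Binomial and beta-binomial survivals are evaluated in log space (regularized
incomplete beta via `pbinom`, log-gamma sums with log-sum-exp for the
beta-binomial), keeping absolute error near machine precision even for
$T \sim 10^4$. GloSS convolutions use FFT (`stats::convolve`) with tiny
negative round-off clamped to zero before normalization; an empty
conditional support yields $p = 1$ with a warning.

The ECM constraint system is solved as the stationarity condition of the
ensemble log-likelihood
$\sum_i k_i \log x_i + \sum_i s_i \log y_i - \sum_{i<j}
\log\frac{1 - y_iy_j + x_ix_jy_iy_j}{1 - y_iy_j}$, which is concave in the
log-parameters: L-BFGS-B from the deterministic start
$x_i = k_i/\sqrt{\sum k}$, $y_i = s_i/(1 + \sum s)$, then a
Levenberg–Marquardt polish of the residuals with an analytic Jacobian. A
naive fixed-point sweep on the same equations oscillates on heterogeneous
instances, which is why the likelihood route is used; the result is
deterministic, with residuals at machine precision on feasible instances up
to $n = 500$ in seconds. Not every network *is* feasible: the observed
$(k, s)$ must lie in the interior of the ensemble's realizable region. A
degree-2 node carrying, say, strength 23 (one very heavy edge under an
i.i.d.-weight generator), or a node adjacent to all others in a small dense
graph, pushes a multiplier to the boundary; the solver detects the pinned
parameter and raises a "saturated constraints" error naming the offending
nodes. The pipeline records such failures per (network, method) and carries
on — extraction-rate accounting is designed around exactly this.

## The synthetic corpus

`gen_heterogeneous()` emulates the salient structure of real study corpora:
heavy-tailed degrees (truncated power law, default exponent 2.5, cutoff
$\sqrt{n \cdot \bar k}$, realized as a simple configuration-model graph),
broad positive integer weights (default: rounded log-normal with
$\mu = \sigma = 1$, clipped to $\ge 1$; Zipf and shifted-Poisson
alternatives), and a single connected component (largest component kept, so
the original network's reachability and component count are 1 and
normalized ratios are well defined). Integer weights by construction let all
seven filters run without rescaling. `gen_planted()` multiplies a seeded
random fraction of edge weights by a boost factor, providing the ground
truth real networks lack.

What the generator does *not* emulate: degree–strength correlations (weights
are i.i.d., whereas real networks often couple hub degree and edge weight),
community structure, clustering above the configuration-model baseline, and
degree assortativity. Passing tests on this corpus therefore demonstrate
correctness of the machinery and the directional behaviors that follow from
the null models themselves — not that any particular real network would
yield the same numbers. One visible consequence: with i.i.d. weights the MLF
and NC backbones coincide almost exactly (their overlap asymmetry is
attained as equality), whereas corpora with degree–weight coupling separate
them further.

Study sizes used by the test suite and acceptance script — 20 corpus
networks of 300 nodes, ECM fits up to 500 nodes, $10^4$–$10^5$ Monte-Carlo
replicates — were chosen so every stage is exercised at a scale where
sampling error is far below the effects being checked, while a full run
stays in the minutes range on a single core.

## Known limitations

* Undirected simple graphs only; directed inputs are rejected rather than
  reinterpreted, because all seven nulls are stated for undirected graphs.
* The integer-weight filters do not rescale real-valued weights themselves;
  `validate_for_method()` flags the issue and leaves the scaling decision
  (a unit choice) to the analyst.
* GloSS conditional mode is exact on the integer grid but its cost grows
  with the maximum strength times the maximum degree (convolution length);
  for very broad weight distributions the marginal mode is the practical
  fallback.
* The NC filter is the binomial approximation only.
* KS distribution ranking compares weight and degree multisets; it says
  nothing about joint structure (e.g. which nodes keep their hubs).
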