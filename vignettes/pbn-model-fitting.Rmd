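---
title: "Fitting probabilistic Boolean networks to steady-state data"
author: "pbnfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting probabilistic Boolean networks to steady-state data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbnfit)
```

## The model

A probabilistic Boolean network (PBN) describes a signalling or regulatory
system as a set of binary nodes $V = (x_1, \dots, x_n)$.  Each non-input node
$x_i$ carries one or more Boolean *predictor functions*
$f_j^{(i)}$ over its parent nodes, together with *selection probabilities*
$c_{ij} \ge 0$, $\sum_j c_{ij} = 1$.  At every time step each node
independently draws one of its predictors according to the $c_{ij}$ and takes
the predictor's output as its next value (the *instantaneously random*,
*independent* PBN).  Picking one predictor per node yields a deterministic
Boolean network; an independent PBN is therefore a mixture of
$\prod_i l(i)$ such *constituent networks*, selected with product
probabilities.  Input nodes have no predictors: their values are fixed
("clamped") to the levels of an experimental condition.

Biologically, the stationary probability that a node is ON is read as the
mean activity of the corresponding molecule in a cell population, normalised
to its maximal observed value.  That interpretation is what makes
quantitative data integration possible: measured activities in $[0,1]$ are
compared against stationary marginals of the model.

Two ingredients make the stationary distribution well defined:

* **Clamping.**  Each experimental condition fixes the input nodes, which
  restricts the Markov chain to one subchain of the full state space.
* **Perturbation.**  With probability $p$ per node and step, a node's bit is
  flipped.  If at least one flip fires, the flips *replace* the network
  update for that step ("flip-wins"); otherwise the network update applies.
  Any $p > 0$ makes the clamped subchain irreducible and aperiodic, hence
  uniquely stationary.  Clamped nodes are never perturbed.  The flip-wins
  construction is the standard way to make a PBN chain ergodic; the
  alternative (flips after the functional update) changes nothing
  qualitatively but would alter exact transition probabilities, so the
  choice is fixed and documented here.

Default $p = 0.001$: large enough for ergodicity and regeneration on
simulation time scales, small enough that stationary marginals stay within
$O(p)$ of their unperturbed limits.

## Rule files

Models are written one predictor per line,

```
NFkB = PI3K & TNFa : 0.8
NFkB = PI3K        : 0.2
```

with operators `&`, `|`, `~`, parentheses and the constants `0`/`1`; the
marker `: ?` declares the selection probability a free parameter to be
fitted, and `#` starts a comment.  Per node the probabilities must either
all be fixed (summing to 1 within $10^{-9}$) or all be free; mixing the two
on one node is rejected rather than silently renormalised.  Rule order is
irrelevant.  Node order — which fixes the state-string rendering — is
inputs first (in order of first reference), then targets in declaration
order, so `"110"` in a three-node model with two inputs means both inputs ON
and the output OFF.

## Exact analysis of small networks

For networks whose non-clamped part has at most $m \le 10$ nodes (the
$2^m \times 2^m$ transition matrix caps at about $10^6$ entries), the chain
is solved exactly:

* `transition_matrix()` assembles
  $P(s,t) = [h \ge 1]\, p^h (1-p)^{m-h} + (1-p)^m \prod_i P(x_i' = t_i \mid s)$
  with $h$ the Hamming distance and per-node mixture probabilities
  $\sum_j c_{ij} f_j^{(i)}(s)$;
* `stationary_distribution()` solves $(I - P^\top)\pi = 0$ with a
  normalisation row by QR (residual tolerance $10^{-10}$, fallback: damped
  power iteration on $(P + I)/2$ to $10^{-12}$).  A chain with more than one
  recurrent class (possible only at $p = 0$) is reported as reducible rather
  than silently resolved;
* `bottom_sccs()` returns the absorbing state sets of the unperturbed chain,
  and `influence()` computes the stationary probability that toggling a
  source bit changes a target's predictor output, weighted by the selection
  probabilities.

The exact path serves two roles: it is the fast objective backend for small
fitting problems (see below), and it is the independent oracle against which
the stochastic estimator is calibrated in the test suite.

## Steady-state estimation from trajectories

For larger models the marginal stationary probability of a node is estimated
from a single growing trajectory using the two-state Markov chain run-length
method (the Raftery–Lewis diagnostic, in its corrected form).  The chain is projected onto the meta-states $\{x_i = 0, x_i = 1\}$;
from a window of the trace the transition rates $\alpha$ (0 to 1) and
$\beta$ (1 to 0) are counted, and two classical quantities follow:

* burn-in
  $m_0 = \max\!\big(0, \lceil \log(\epsilon(\alpha+\beta)/\max(\alpha,\beta))
  / \log |1-\alpha-\beta| \rceil\big)$ — the absolute value matters for
  oscillatory chains with $\lambda = 1-\alpha-\beta < 0$;
* run length
  $N = \lceil \alpha\beta(2-\alpha-\beta)/(\alpha+\beta)^3 \cdot
  (\Phi^{-1}((s{+}1)/2)/r)^2 \rceil$ — the factor in front of the squared
  quantile-to-precision ratio is the variance inflation of an
  autocorrelated binary chain.

Defaults $r = 0.025$, $\epsilon = 0.01$, $s = 0.95$, starting from
$m_0 = 0$, $N = 100$.  The protocol simulates $m_0 + N$ steps, re-estimates
$\alpha, \beta$ from the last $N$ states, recomputes $(m_0, N)$, and extends
the *same* trajectory whenever the new requirement exceeds the previous one;
when it no longer grows, the marginal is the frequency of ON among the last
$N$ elements of the obtained trajectory, where $N$ is the requirement the
trajectory was actually extended for (the final, not-larger recomputation
only certifies stopping — discarding data down to the smaller window would
throw away most of what the protocol itself demanded).  One trajectory
serves all measured nodes of a condition; each node keeps its own window.

Degenerate windows are handled explicitly, because the formulas require
$\alpha, \beta \in (0,1)$:

* a **constant** window doubles the trajectory, giving up after 10 doublings
  (the node is then reported as effectively frozen at this perturbation
  level);
* a rate estimated at **0** means the rare direction has simply not been
  observed yet — with $p > 0$ no direction is impossible — so the trajectory
  keeps doubling up to the safety cap (`max_length`, default $10^7$; a
  self-maintaining node mixes at rate $p$ and honestly needs of the order of
  $1/p^2$ steps at the default precision);
* a rate estimated at **1** can be structural (a deterministic exit, e.g. a
  constant-0 node that always relaxes from a perturbed ON state): it is
  accepted once its source meta-state has been visited at least 20 times,
  and treated as undersampled before that.

Reproducibility: trajectories consume the RNG stream in a fixed order (flip
indicators for all non-clamped nodes, then one draw per updatable node, in
node order), so a seed pins the whole trajectory bit for bit, and extension
continues the same stream.  The initial state is uniform over the
non-clamped bits; the burn-in absorbs the initialisation transient.

Two properties of this estimator are worth keeping in mind when reading the
test suite.  First, its guarantee — $|\hat\pi - \pi| \le r$ with probability
$s$ — presumes the two-state projection is approximately Markov.  Networks
with hidden slow modes (metastable attractors that the projected node does
not see directly) mix on time scales the window never samples, and the
method then underestimates the required run length; the calibration test on
random networks therefore checks a 90% coverage floor rather than the
nominal 95%.  Second, by construction the realised standard error of one
estimate is close to $r / \Phi^{-1}((s{+}1)/2)$ (about $0.013$ at the
default $r$), so the difference between two independent runs at $r = 0.025$
and $r = 0.01$ carries noise of the same order; what the method does
guarantee is that tightening $r$ does not *shift* the estimate, and the
corresponding test asserts the mean change over replicate pairs.

## Fitting selection probabilities to data

An optimisation problem combines a rule template with free parameters, a set
of experimental conditions (clamps plus measured node activities in
$[0,1]$), and a mode:

* **discrete** — every candidate rule is either selected or not; the
  selected rules of a node share the probability mass equally ($1/k$ for $k$
  selected).  A candidate that de-selects all rules of a node is scored
  $+\infty$ rather than repaired.  Up to $2^{20}$ candidates are enumerated
  exhaustively; beyond that a small generational bit-string genetic search
  (population 50, tournament selection, uniform crossover, per-bit mutation
  $1/k$, elitism) takes over.
* **continuous** — the optimiser explores the box $[0,1]^k$ and each node's
  raw weights are normalised to the simplex, $c_j = u_j / \sum u$.  This
  decode treats all predictors of a node symmetrically (the alternative
  "last = 1 − rest" breaks symmetry and was rejected); an all-zero node
  falls back to uniform weights with a warning.  The optimiser is
  differential evolution, rand/1/bin with $F = 0.8$, $CR = 0.9$ and
  population $\max(20, 10k)$ — conventional defaults, not tuned; the
  objective, not the optimiser, is the contract, and `fit_pbn()` keeps the
  optimiser behind a minimise-over-budget interface.

The objective is the sum of squared errors
$\sum_{\text{conditions}} \sum_{\text{measured nodes}}
(\hat\pi - \text{data})^2$, with marginals obtained either from the exact
chain (`backend = "exact"`, solved at $p = 0$, the limit in which the
bundled data are defined) or from the two-state estimator
(`backend = "simulation"`, one shared trajectory per condition, with
per-condition seeds derived deterministically from the global seed so runs
are reproducible and parallelisable).  Every evaluated candidate is retained
with its decoded parameters and cost, which is what the ensemble statistics
consume.  No model-size penalty is applied: parsimony is read off the
fitted probabilities instead (a rule whose weight collapses to 0 is
dispensable).

`resimulate()` re-evaluates a fitted parameter set per condition and node.
With the simulation backend a fresh seed gives slightly different estimates;
the wobble is bounded by a few precision widths $r$, which is also asserted
in the tests.

## Ensemble statistics and identifiability

`top_k()` selects the $K$ lowest-cost samples (default 500, ties broken by
evaluation order) and `summarise_ensemble()` reports per-parameter mean,
population standard deviation (divide by $K$ — a deliberate, documented
choice; with $K = 500$ the distinction from the sample SD is cosmetic),
minimum and maximum.  A tight cluster (small SD against the mean) marks an
identifiable, sensitive parameter; a wide spread marks a parameter the data
do not constrain — the bundled two-condition variant of the PIP3 case study
reproduces exactly this contrast, with the individual weights free to slide
along the ridge $c_{\mathrm{PI3K}} + c_{\mathrm{PTEN}} = 0.6$.  No formal
hypothesis test is attached to this readout; it is a screening statistic.

## Bundled case studies and synthetic data

Three generator functions rebuild the worked inference problems from code;
nothing is downloaded and no binary data ships with the package.

* `case_study1()` — rule identification: five candidate gates for one output
  (OR, AND, each input alone, constant 0) against four input combinations.
* `case_study2()` — weight inference: PIP3 regulated by PI3K (activator,
  generating weight 0.6) and PTEN (inhibitor acting through `PI3K & ~PTEN`,
  weight 0.4), four input combinations.
* `case_study3()` — weighted signal flows with inhibitors on an eight-node
  toy pathway; branch weights NFkB = (0.7, 0.3) from PI3K/TNFa and
  ERK = (0.6, 0.4) from Raf/NFkB.  An inhibitor at 70% efficacy is realised
  *inside* the fixed network: the inhibited node carries predictors
  `source & ~inhibitor : 0.7` and `source : 0.3`, so under inhibition its
  stationary activity is 30% of the source signal — the unique PBN encoding
  whose marginals equal the proportional-reduction arithmetic (e.g. NFkB
  under both ligands plus PI3K inhibition: $0.3 \cdot 0.7 + 0.3 = 0.51$).
  Six conditions cover single ligands, both ligands, each inhibitor, and an
  unstimulated control.

All measured values are computed as exact stationary marginals of the
generating model at $p = 0$, so the bundles are self-consistent with the
oracle by construction, and fitting them back is a genuine
parameter-recovery experiment.  What these fixtures deliberately do *not*
emulate: measurement noise, normalisation artefacts, condition-specific
(local) parameters, or multi-level activities.  Passing recovery tests
therefore demonstrates correctness of the machinery — objective, decoding,
optimiser, estimator — not robustness to noisy data.

`random_pbn()` generates property-test inputs: 2–10 nodes, one to three
predictors per node over random parent sets of at most three nodes
(self-loops and feedback allowed), uniformly random truth tables, Dirichlet(1)
selection probabilities, materialised as sum-of-minterms rule text so that
serialisation round-trips exactly.

`table5_data()` embeds the printed steady-state table of a published
large-scale apoptosis benchmark (three output nodes, six conditions, four
value columns) for cost arithmetic only; the underlying 96-node model is out
of scope by design.

## Problem sizes used by the checks

The test suite and the reproduction script run entirely on exact
oracle-sized problems: calibration uses 200 seeded runs on random three- to
six-node networks; the continuous inference checks use differential
evolution budgets of 5,000 cost evaluations (2,000 in the quicker unit
tests); the precision-tightening check uses 12 replicate pairs per node.
These sizes give comfortable statistical margins for every asserted bound
while keeping a full run in the minutes range on one core.

## Known limitations

* The two-state run-length method can underestimate the required trajectory
  length when the projected chain hides slow modes (see above); diagnostics
  (`alpha`, `beta`, `N`, `total_length`) are returned so suspiciously short
  runs can be spotted.
* Exact analysis is capped at 10 non-clamped nodes by default; beyond that
  only the stochastic estimator applies.
* One global parameter vector is shared across all conditions; per-condition
  (local) parameters are not supported.
* Boolean, two-level logic only; graded activities enter only through
  selection probabilities and measured values, not through multi-valued
  node states.
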