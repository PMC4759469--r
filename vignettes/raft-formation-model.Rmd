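---
title: "Degree-capped random graph models of raft formation in swarming bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-capped random graph models of raft formation in swarming bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmraft)
```

## The model

Swarming bacteria such as *Proteus mirabilis* begin collective surface
motility only after the local density of differentiated swarmer cells
crosses a threshold. Swarmer cells are elongated and assemble side by side
into *rafts*: chains in which each cell touches at most two neighbours.
`swarmraft` models the build-up to that threshold as a random graph process:
cells are a fixed set of $N$ vertices, pairwise interactions are undirected
edges, and a hard degree cap of 2 restricts every connected component to a
simple path (an open chain) or a simple cycle. Reaching the density
threshold is identified with the first appearance of a connected component
of at least $m$ cells; its *hitting time* is
$\tau = \min\{t \ge 0 : G_t \text{ has a component of size} \ge m\}$.

Three update rules are implemented, all starting from the edgeless graph:

* **Model 1** (`step_model1`): at each timestep one ordered pair $(i, j)$ is
  drawn uniformly from $\{1..N\}^2$; the edge is created unless $i = j$, it
  already exists, or either endpoint has degree 2. At most one edge appears
  per step, so the edge set grows monotonically and $|E_t| \le t$.
* **Model 2** (`step_model2`): each timestep sweeps all unordered pairs in a
  uniformly shuffled order; every pair passing the same three checks
  receives an independent Bernoulli($P$) draw, with degrees updated
  immediately so an edge accepted earlier in the sweep can block a later
  candidate.
* **Model 3** (`step_model3`): a Model 2 sweep followed by a death sweep in
  which each cell independently, with probability $p_D$, loses all its
  incident edges (its adjacency row and column are zeroed). The cell itself
  keeps its vertex slot and may re-form edges later, which keeps $N$
  constant; with deletions the process is no longer monotone, so Model 3 is
  a purely stochastic simulation outside the analytical theory.

Models 1 and 2 are monotone graph processes: components can only grow, so
the threshold property is monotone and $\tau$ is a proper stopping time.
Cycle components are permitted — the update rules allow a chain to close on
itself — and are counted toward the giant component; decompositions and
snapshots carry an `is_cycle` flag so their contribution can be examined
separately. Whether closed loops of cells function as rafts biologically is
outside what the graph formalism can decide.

## Closed-form hitting-time theory

Within a dense clump of $n$ cells where any pair can interact, let edges
appear with per-pair probability $c/n$ for an edge intensity $c$. The
threshold relation $m \ge (1 - e^{-c})\,n$ ties the reachable component
scale to the intensity; the minimal physically realistic intensity for a
threshold fraction $m/n$ is

$$c_{\min} = \left|\ln\left(1 - \tfrac{m}{n}\right)\right|,
  \qquad q = \frac{c_{\min}}{n},$$

and the (unnormalized) probability of first assembling the threshold chain
at discrete time $t$ is

$$P(t) \propto t\,q\,(1-q)^{t-1},$$

a unimodal, gamma-shaped curve. Treating $t$ as continuous, its derivative
$q(1-q)^{t-1}\{1 + t\ln(1-q)\}$ vanishes at the mode

$$t_{\text{mode}} = \frac{-1}{\ln(1-q)},$$

which grows without bound as $n$ increases at fixed ratio $m/n$. The
cumulative form sums the curve over integer steps; since
$\sum_{t\ge1} t\,q\,(1-q)^{t-1} = 1/q$ in closed form, `hitting_cdf`
normalizes by $1/q$ by default so the cdf is a proper distribution function
(the unnormalized cumulative sum is available via `normalized = FALSE`).

```{r theory}
c_min(6, 10)
t_mode(6, 10)
```

Two conventions deserve note. First, the threshold relation as written is
satisfied for $c \le c_{\min}$ while the hitting law requires
$c \ge c_{\min}$ for realizability; `threshold_ok` implements the relation
literally and `c_min` anchors the hitting law, and the two meet exactly at
the boundary. Second, the sign of $\ln(1 - m/n)$ is negative, so the
absolute value is applied throughout — a negative intensity has no physical
meaning.

The relation between the theoretical per-step probability $q = c_{\min}/n$
and the simulation parameter $P$ of Model 2 is deliberately left open: the
package exposes both and they can be compared empirically, but no
equivalence is claimed — the theory describes a dense clump of $n$ cells,
the simulation a population of $N$ cells with a per-sweep Bernoulli rate.

## Gamma matching

The hitting curve resembles a gamma density, which motivates relating gamma
parameters $(A, k, \theta)$ fitted to empirical hitting times back to the
threshold. Writing $C = |\ln(1 - m/n)|/n$ (identical to $q$), the matching
of first-order (linear-in-$t$) terms between the scaled gamma density and
$t\,C(1-C)^{t-1}$ gives

$$C \approx \frac{t^k}{2A\,\Gamma(k)\,\theta^{k+2} + t^k},$$

with $(k-1)!$ realized as $\Gamma(k)$ so non-integer shapes are admitted.
In the small-shape regime $k \ll 1$ one may set $t^k \approx 1$, making the
recovered threshold $m = n(1 - e^{-nC})$ approximately independent of $t$;
`threshold_from_gamma` warns when $k > 0.1$, where that approximation
degrades. The matching places the scale constant $A$ on one side of an
equation whose two sides are each known only up to proportionality; the
package adopts the convention in which $A$ multiplies the
$\Gamma(k)\theta^{k+2}$ term, the form that is exactly consistent with the
inversion formula `solve_A` uses,
$A = (1/C - 1) / (2\Gamma(k)\theta^{k+2})$. The tests re-derive the
matching numerically (Taylor coefficients of $e^{-t/\theta}$ by finite
differences against the limit of the hitting side) to confirm the
reconstruction rather than trusting a printed layout. Negative $A$ is
accepted with a warning: it can arise from fits and is treated purely as a
scale constant, never as a density normalizer.

```{r gamma}
A <- solve_A(60, 100, k = 0.01, theta = 2)
threshold_from_gamma(A, k = 0.01, theta = 2, n = 100)
```

The worked normalization for *P. mirabilis*: a swarmer:swimmer ratio of
1:1.5 in a consolidation layer ready to swarm corresponds to a majority
fraction $m/n = 1.5/2.5 = 0.6$, i.e. $m = 60$ in a clump of $n = 100$. The
empirical $(k, \theta)$ values behind published normalizations of this kind
are strain-specific and not reproducible here; the round-trip above uses a
synthetic small-shape pair and recovers the threshold exactly.

`fit_gamma` fits shape and scale by maximum likelihood
(via `MASS::fitdistr`), estimates $A$ by least squares between the
empirical histogram density and the scaled gamma curve, and reports a
Kolmogorov–Smirnov statistic. Censored hitting times (replicates that never
reached the threshold) are never imputed: they are dropped with the
censoring fraction recorded on the fit object.

## Exact small-system oracle

For $N \le 5$ the Model 1 chain is solved exactly: all labelled
degree-capped graphs are enumerated (41 states for $N = 4$), the uniform
ordered draw induces a row-stochastic kernel with entries in units of
$1/N^2$, and the expected hitting time follows from the standard
absorbing-chain linear system, with the distribution of $\tau$ by forward
iteration. Labelled states — not isomorphism classes — are enumerated,
because the simulator acts on labelled cells. The oracle is the ground
truth against which the simulator's state distribution and mean hitting
times are tested.

## Numerical and design choices

* **Sweep realization.** A literal pair-by-pair Model 2 sweep costs
  $O(N^2)$ per timestep. The package instead draws the Binomial number of
  successes among the pairs eligible at sweep start, selects that many
  candidate pairs uniformly, and resolves them in random order with full
  rule checks. Because edges are only added within a sweep, eligibility
  only shrinks, and the construction is distributionally identical to the
  literal sweep while costing $O(\text{successes})$.
* **Model 1 jump-chain embedding.** In any state with $M$ eligible pairs, a
  Model 1 step adds an edge with probability $2M/N^2$ and otherwise changes
  nothing. `run_process` samples the Geometric waiting time to the next
  addition and then the added pair uniformly among eligible pairs — exactly
  the same finite-time law with $O(N)$ events instead of $O(t_{\max})$
  steps. The exported `step_model1` remains the literal one-draw rule, and
  the exact-oracle tests certify the equivalence of the two routes.
* **Model 3 ordering.** Within a timestep the edge sweep runs first, the
  death sweep second; a trajectory records the post-death state.
* **Component tracking.** While edges are only added, an incremental
  union–find tracks the giant component in O(α) per edge; after deaths the
  decomposition is rebuilt. The exported `connected_components` delegates
  to igraph and verifies the path-or-cycle corollary of the degree cap.
* **Reproducibility.** Per-replicate seeds are derived from the
  configuration seed by one `sample.int` call, so any (config, seed) pair
  reproduces byte-identical trajectories on the same platform.
* **Degenerate inputs.** `t_max = 0` yields the length-1 trajectory of the
  empty graph; a single-cell population is a fixed point of every rule;
  `m = 1` hits at $t = 0$; `m = n` is accepted by the threshold relation
  but rejected by the hitting law, whose logarithm diverges there.
* **Average degree** is $2|E|/N$ (each undirected edge counted once from
  the symmetric adjacency), consistent with the saturation limit 2.

## What the simulations do and do not emulate

The generator captures the interaction-graph skeleton of a consolidation
layer: exchangeable cells, a bounded number of side-by-side contacts,
stochastic contact formation, and (Model 3) loss of contacts on cell death
at constant population size. It deliberately omits spatial embedding,
motility, flagellar dynamics, chemotaxis, cell elongation, explicit birth
events, and any weighting of interactions — so agreement of the simulated
curves with the closed-form theory shows internal consistency of the graph
model, not validity of those omitted mechanisms for a real swarm plate.
Timestep meanings also differ across models (one candidate pair per step in
Model 1, a full sweep per step in Models 2–3), so times are compared across
models only qualitatively.

A structural property worth knowing when designing experiments in silico:
once a Model 2 population saturates (no eligible pair remains), the
component structure no longer depends on $P$ — the embedded sequence of
edge additions is the same uniform greedy chain for every $P$, and $P$ only
sets its speed. Component-size snapshots therefore discriminate between
interaction probabilities only while the process is still growing; at a
snapshot time far beyond both saturation times, statistics such as the mean
component size coincide in distribution across $P$ and only replicate noise
remains. The package's own component-size checks at `t = 500` show exactly
this: the ordering across $P$ is sharp while at least one population is
still growing and degenerates to a tie between saturated ones.

## Problem sizes used in the checks

The packaged tests run Model 1 degree saturation at $N = 1000$ over 10
replicates (up to $5\times10^5$ steps, or until no eligible pair remains);
the exact-oracle comparison on $N = 4$ with $10^5$ simulated replicates;
Model 2 component-size snapshots at $t = 500$ with $N = 200$ and 10
replicates per interaction probability in
$\{10^{-6}, 10^{-5}, 10^{-4}, 10^{-3}, 10^{-2}\}$; Model 3 at $N = 200$,
$P = 10^{-4}$, death rates $\{0.001, 0.01, 0.1\}$ (the death-rate grid is
this package's documented choice) to $t = 10{,}000$ over 3 replicates; and
gamma recovery on $10^4$ draws from $\Gamma(3, 2)$. These sizes were chosen
so the full suite runs comfortably at a desk while keeping Monte-Carlo
error well inside each check's tolerance.

## Known limitations

* The theory layer is a proportional lower bound on the hitting
  probability, not a normalized likelihood; only the cdf is normalized, by
  the closed-form total mass.
* Model 1 can stall just short of full saturation (for instance a single
  open cell, or one isolated 2-cell component whose ends are already
  linked), so the average degree limit 2 is approached within a tolerance
  rather than attained exactly.
* The mapping between Model 2's per-sweep $P$ and the theory's per-step
  $q$ is not pinned down; quantitative comparisons between the two layers
  should be made through hitting-time distributions, not parameters.
* Only a degree cap of 2 is supported; the cap is a named internal
  constant, but no other value is exercised or tested, because chains are
  the structure of interest.
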