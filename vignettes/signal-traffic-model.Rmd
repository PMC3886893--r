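---
title: "The signal-traffic queueing model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The signal-traffic queueing model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsignal)
```

## The model

`netsignal` treats a directed, unweighted brain network as a communication
system. Discrete *signal units* — an abstraction of the capacity of one
region to influence another — are created by a Poisson process with rate
$\lambda$; each unit draws a uniformly random source node and a uniformly
random destination node (distinct from the source) and is injected at the
source. Routing is an unbiased random walk: when a node finishes serving a
unit, the unit hops instantaneously to one of the node's out-neighbours,
chosen uniformly. A hop that lands on the unit's destination removes it
from the network immediately — the destination absorbs on arrival, before
any queueing, so a unit's transit time ends at the hop instant.

Every node is a single server with exponential service times at rate
$\mu$. A unit arriving at a busy node joins a queue served in
last-come-first-served (LIFO) order without preemption: the newest waiter
is served next, but the unit in service is never interrupted. The queue is
a finite *push-out* buffer of capacity $K$: an arrival at a full queue is
accepted and the *oldest* waiting unit is ejected and dropped. With
$K = 0$ the arriving unit is itself the only queue candidate and is lost
immediately; the in-service unit is never ejected.

The observables are the node contents $X_i(t) = c_i(t) + q_i(t)$
(in-service plus queued units), the total network load
$N(t) = \sum_i X_i(t) + \sum_{ij} X_{ij}(t)$ (channel contents $X_{ij}$
are identically zero because hops are instantaneous, but the term is kept
in the accounting for completeness), and per-unit records: for every node
visit, the waiting time $W$ and service time $S$, so that a delivered
unit's transit time is $T = \sum_{\text{nodes visited}} (W + S)$.

All stochastic draws are produced by inverse-transform sampling from a
seeded uniform stream (exponential variates as $-\log(U)/\text{rate}$,
discrete choices as $\lfloor U k \rfloor$), so a given (network,
configuration, seed) triple reproduces a bit-identical trace.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `lambda` | external arrival rate (units per time unit) | — | the load dial; `arrival_mode = "global"` reads it as one network-wide rate with uniform random sources, `"per_node"` as a per-node injection rate (total $\lambda n$) |
| `mu` | service rate per node | 1 | fixing $\mu = 1$ measures time in mean service times; load is controlled through $\lambda$ alone |
| `buffer_size` | queue capacity $K$ (server slot excluded) | 5 | node contents are bounded by $K + 1$; capacity changes results quantitatively, not qualitatively (`sweep_parameter("buffer_size", ...)` documents this) |
| `t_end` | horizon (time units) | 2e6 | publication scale; reduced in all tests (see below) |
| `t_transient` | warmup discarded from statistics | 4e4 | `detect_transient()` re-estimates it by the ensemble-average method |

The model has two operating regimes. Below a load threshold the total
network load $N(t)$ fluctuates around a finite mean; raising $\lambda$
increases blocking and utilization monotonically until buffers saturate.
Under the global arrival mode, 100-node networks at
$\lambda \in [0.05, 0.2]$ sit well below saturation (mean utilization
under 0.2); the per-node mode at the same numerical rates produces heavy
congestion. Both modes are exposed because the appropriate normalization
depends on what the arrival process is taken to represent.

## Statistics

`node_stats()` reports, per node over the post-transient window: exact
time-weighted utilization, blocking (ejections over arrivals, reported as
missing — never zero — for nodes with no arrivals, so cross-node means are
unbiased), and mean contents by piecewise-constant integration.
`edge_throughput()` counts traversals per directed edge and, given a
rich-club membership, stratifies edges into rich/feeder/local classes.
`network_stats()` aggregates utilization and blocking and reports
throughput (delivered units) and mean transit time (delivered units only —
dropped units cannot contribute a transit time). `path_stats()` compiles
per source–destination pair delivery counts and mean delays with
per-source and per-target marginals; undelivered pairs hold missing
values.

All time-averages use exact event integration. The
`interpolate_uniform()` pathway (linear interpolation onto a uniform grid)
reproduces the resampling preprocessing used by event-driven simulation
toolchains; its error is bounded by the largest inter-event jump and it is
retained for fidelity, not used by the exact statistics.

## Surrogates and synthetic networks

Degree-matched controls come from two edge-switching procedures. Both
exchange the targets of two randomly chosen edges,
$(A{\to}B, C{\to}D) \Rightarrow (A{\to}D, C{\to}B)$, rejecting swaps that
would create a self-loop or duplicate edge, so every node's in- and
out-degree is preserved exactly.

* `maslov_rewire()` accepts every legal swap; the default effort is 10
  accepted swaps per edge.
* `latticize()` accepts a swap only if it strictly decreases
  $\sum_{\text{edges}} |o(\text{source}) - o(\text{target})|$, where $o$
  is the node order index. The default node ordering is the input order
  and the distance is non-circular $|i - j|$; this is one of several
  defensible latticization costs, and it is documented rather than claimed
  canonical. Convergence is declared after $10 m$ consecutive rejections.

Scenario networks: `ring_lattice(n, k)` (each node connected to its $k$
nearest successors and predecessors), `small_world()` (a ring lattice with
a fraction — default 10% — of edges displaced by degree-preserving swaps,
so the small-world network stays exactly degree-matched to its lattice
control; a classic retarget variant is available behind `method`), and
`rich_club_synthetic()` (block densities `p_local = 0.05` for
periphery–periphery pairs, `p_feeder = 0.20` for club–periphery,
`p_rich = 0.80` for club–club; 20 club nodes out of 100 by default). The
block densities were chosen to give an unambiguous planted club — a large
degree gap and a strong density gradient — while keeping the periphery
sparse; they are generator defaults, not estimates of any empirical
network.

What the generator does *not* emulate: empirical connectomes have spatial
embedding, community structure beyond a single club, reciprocity biases,
and correlated in/out degrees with in–out asymmetry per node. Passing
tests on planted networks therefore validate the machinery, not any claim
about a particular brain network.

## Rich-club detection

`rich_club_coefficient()` strips all nodes with degree $\le k$ and returns
the directed density of the survivors, $\phi(k)$; survivors are nodes with
degree strictly greater than $k$ (the standard convention; the inequality
and the use of total degree are documented and switchable via
`degree_type`). `rich_club_profile()` computes $\phi(k)$ from the lowest
to the second-highest degree and normalizes by the mean over degree-
matched rewired nulls, $\phi_{\mathrm{norm}}(k) = \phi(k) / \langle
\phi_{\mathrm{null}}(k)\rangle$, reporting the null mean and SD per
threshold so that profiles computed with a reduced null count (default
100; raise towards 10000 for publication work) remain interpretable.
Membership can be assigned by degree thresholds (two nested levels, a
conservative RC1 inside a liberal RC2) or supplied as explicit node lists
when an external assignment exists.

## Verification strategy

The simulator is checked against three independent computations rather
than against itself:

1. **Closed form.** On the two-node bidirectional network every unit makes
   exactly one hop, so each node is an M/M/1/($K{+}1$) queue at arrival
   rate $\lambda/2$. The push-out buffer shares its occupancy chain with
   the classical block-on-arrival queue, and by PASTA the ejection
   fraction equals the stationary probability of a full system, so
   utilization, blocking and mean contents all have exact expressions
   (`mm1k_metrics()`).
2. **Exact CTMC.** `stationary_node_contents()` enumerates the full state
   space — for every node the ordered stack of destinations of the units
   it holds — builds the generator matrix by brute force and solves for
   the stationary law. This is feasible only for a few nodes (the
   three-node complete network with $K = 2$ has 3375 states) and exists
   purely as an oracle.
3. **Analytic decomposition.** `predict_stats()` composes the absorbing
   random-walk traffic equations (expected visits from the fundamental
   matrix $(I - Q)^{-1}$, averaged over all source–destination pairs) with
   the finite-buffer queue formulas per node. It treats nodes as
   independent and ignores blocking-induced flow thinning, so it is exact
   on the two-node fixture, accurate at low load (mean relative
   utilization error around 1% when predicted blocking is under 1%), and
   degrades monotonically as $\lambda$ rises — which is itself asserted in
   the tests.

## Numerical choices and degenerate inputs

* Simultaneous events: hops are instantaneous, so a service completion, the
  consequent arrival (and possible ejection) elsewhere, and the promotion
  of the next waiter all occur at one instant, processed depth-first in
  causal order. Distinct timestamps are almost surely unique because all
  durations are continuous.
* `blocking` at a node with no in-window arrivals is missing, not zero.
* A network that is not strongly connected is simulatable as long as every
  node keeps in- and out-degree at least one: units that can never reach
  their destination are eventually pushed out of some buffer. The
  analytic model excludes unreachable pairs from the traffic equations and
  reports the excluded count.
* `latticize()` and `maslov_rewire()` return the current state with a
  warning flag when no legal swap can be found within the attempt budget
  (e.g. the two-node cycle, where every candidate swap is a self-loop).
* Ensemble comparisons average Welch t-statistics, degrees of freedom and
  p-values across surrogate realizations and apply Benjamini–Hochberg
  control across nodes within one metric family; tests are two-sided.
  Averaging across realizations is the reporting convention adopted here;
  a pooled-permutation scheme would be a reasonable alternative but is not
  the default.

## Problem sizes used by the test-suite

The packaged tests run the model at desk scale: horizons of $5 \times 10^3$
to $5 \times 10^4$ time units with warmups of 500–2000, 8–24 replicate
seeds per comparison, 100-node synthetic networks, and 60–100 rich-club
nulls. These sizes were chosen so that every Monte-Carlo comparison has a
meaningful standard error while the whole suite stays interactive;
publication-scale runs (two-million-unit horizons, hundreds of runs,
thousands of nulls) use the same code paths through `sim_config()` and
`run_scenario()` unchanged.

## Known limitations

* Routing alternatives (shortest-path, greedy, packet-switched) and
  hierarchical source/destination biases are out of scope; the model is
  diffusive and message-switched by construction.
* The analytic model is a low-load decomposition; it is an oracle for the
  simulator, not an exact solver of the interacting network.
* Directional contrasts between a planted rich-club network and its
  degree-matched surrogates (which family delivers more, faster) are
  *realization-dependent* at the default generator settings: analytic
  per-edge flows show rich-club edges carrying more traffic than local
  edges in only a minority of realizations, because the planted ER-block
  construction keeps visit rates nearly proportional to degree. Such
  contrasts on empirical connectomes rest on structure (in/out asymmetry,
  communities, spatial embedding) that the planted generator deliberately
  lacks, and the corresponding directional tests document this rather than
  assert it away.
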