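# netsignal

Discrete-event simulation of signal traffic and congestion on directed
brain networks.

## What this package is for

Graph statistics describe what a connectome *is*; they say little about
what it *does* when information actually flows over it. `netsignal`
superimposes a communication system on a directed, unweighted network —
typically an anatomical brain network, or a synthetic control for one —
and measures how topology shapes global information flow: which regions
run hot, where signals get lost, how fast messages travel, and how much of
the traffic is carried by the densely interconnected "rich club" of hub
nodes. It is aimed at researchers in network neuroscience and, more
generally, anyone studying congestion phenomena on directed graphs.

## The model

Signal units are generated by a Poisson process with rate λ; each unit
receives a uniformly random source and destination (source ≠ destination)
and performs an unbiased random walk over the directed edges. Every node
is a single server with exponential service at rate μ, a non-preemptive
LIFO queue, and a finite push-out buffer of capacity K: an arrival at a
full queue ejects the *oldest* waiting unit, which is dropped. A hop that
lands on the unit's destination removes it immediately. With node contents
X_i(t) = c_i(t) + q_i(t) (in service + queued) the model reports, after
discarding a warmup transient:

* **utilization** — fraction of time a node's server is busy,
* **blocking** — ejections ÷ arrivals at a node,
* **node contents** — time-average of X_i(t),
* **throughput** — units delivered source → destination,
* **transit time** — T = Σ (W + S) over the nodes a delivered unit
  visited.

Around the simulator sit the pieces needed to use it scientifically:
degree-preserving randomized and latticized surrogate generators,
ring-lattice / small-world / planted rich-club synthetic networks,
rich-club coefficient profiles φ(k) and φ_norm(k) against degree-matched
nulls with rich/feeder/local edge stratification, an analytic steady-state
model (absorbing random-walk traffic equations + finite-buffer queue
formulas) used to verify the simulator, an exact brute-force CTMC oracle
for tiny networks, and an ensemble comparison framework (Welch t with
Satterthwaite df, Benjamini–Hochberg FDR, Fisher r-to-z scenario
similarity).

## Worked example

```r
library(netsignal)

net <- rich_club_synthetic(n = 100, n_rc = 20, seed = 1)
net
#> directed_network: 100 nodes, 1309 edges

cfg <- sim_config(lambda = 0.15, mu = 1, buffer_size = 5,
                  t_end = 1e4, t_transient = 1e3, seed = 42)
trace <- run_simulation(net, cfg)
trace
#> sim_trace: 1480 units (1195 delivered, 256 dropped, 29 in network) over 10000 time units

network_stats(trace)
#>   mean_utilization mean_blocking throughput mean_transit_time created dropped
#> 1        0.1696462  0.0005892266       1091          154.1967    1329     235
```

So at λ = 0.15 the network delivered 1091 units in the post-transient
window; the average delivered unit spent 154 time units in the network
(about 144 node visits at μ = 1), and roughly one arrival in 1700 caused a
buffer ejection. The most congested nodes are the high in-degree hubs:

```r
ns <- node_stats(trace)
head(ns[order(-ns$mean_contents),
        c("node", "in_degree", "utilization", "blocking", "mean_contents")], 3)
#>    node in_degree utilization    blocking mean_contents
#> 14  n14        40   0.5027201 0.007645260     0.9670080
#> 12  n12        36   0.4989460 0.003369272     0.9004946
#> 10  n10        33   0.4698597 0.007095553     0.8943524

cor(ns$in_degree, ns$mean_contents, method = "spearman")
#> [1] 0.9650711
```

The planted rich club is visible as a normalized rich-club coefficient
above 1 at high degree thresholds:

```r
prof <- rich_club_profile(net, n_null = 100, seed = 7)
subset(as.data.frame(prof), k %in% c(20, 40))
#>     k       phi null_mean     null_sd phi_norm
#> 13 20 0.4931034 0.4536322 0.008512961 1.087012
#> 33 40 0.8052632 0.6826053 0.017702216 1.179691
```

and the analytic model reproduces the simulated per-node utilization
almost exactly at this load:

```r
pred <- predict_stats(net, cfg)
cor(pred$node$utilization, ns$utilization)
#> [1] 0.9990905
```

A thin command-line front end over the same functions lives in
`inst/cli/netsignal.R` (`generate`, `simulate`, `richclub`, `predict`).

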