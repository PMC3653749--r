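---
title: "Token-flow perturbation analysis of signalling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Token-flow perturbation analysis of signalling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spnperturb)
```

## The model

`spnperturb` simulates signal propagation through a curated signalling map
as discrete token flow on a Petri net, and asks which molecules change
significantly when one seed molecule is knocked down or overexpressed
in silico.

The network is a directed bipartite graph. *Species* nodes are places that
hold a non-negative integer number of tokens; the token count at a species
proxies its expression/activity level. *Reaction* nodes are transitions.
Edges follow the SBML reaction roles: reactant edges (species to reaction),
product edges (reaction to species) and modifier edges (species to
reaction), the last representing catalysis — a kinase that enables a
phosphorylation without being consumed by it. A map that distinguishes a
molecule's active and inactive forms represents them as two species sharing
a name; mass then flows through the inactive-to-active conversion while the
catalyst acts through a modifier edge.

The simulator is nonparametric: no rate constants, no kinetic laws. All
dynamics come from repeated stochastic firing:

* **Firing.** When reaction $j$ fires, let $m$ be the minimum token count
  over its reactant places. A count $k \sim \mathrm{Uniform}\{0,\dots,m\}$
  is drawn, removed from every reactant place and added to every product
  place. Modifier places gate the firing without being consumed: an
  activating modifier must hold at least `modifier_threshold` tokens
  (default 1), an inhibiting modifier blocks the reaction when it does.
  A reaction whose reactant places were all stripped away (possible after
  an aggressive subnetwork cut; such reactions are flagged by the
  extraction report) moves nothing.
* **Time step.** Per time point, every reaction fires exactly once, in a
  fresh uniformly random permutation. The random order is what represents
  the nondeterministic interleaving of simultaneously enabled transitions;
  firing each transition once per block makes the length of a run
  well-defined.
* **Sources and sinks.** A species with no incoming product edge is a
  source — the beginning of a path — and receives 100 tokens at time zero
  (an arbitrary reference level; the scale cancels in the comparison of
  scenarios). A species with no outgoing reactant or modifier edge is a
  sink; at the end of each time step it loses
  $d \sim \mathrm{Uniform}\{0,\dots,v\}$ of its own $v$ tokens, mirroring
  the uniform movement rule and preventing tokens from piling up at
  zero-out-degree nodes (biologically: self-regulation / turnover of
  terminal molecules). Two readings of the sink rule are possible — decay
  bounded by the sink's own tokens or by an upstream node's; we bind it to
  the sink's own count, which is what the anti-build-up rationale requires.
  Sources are seeded at time zero only and are not replenished; nothing in
  the procedure requires an inflow, and an unreplenished source makes the
  control scenario exactly comparable to the perturbed ones.

## Scenarios and the screen

A scenario is an initial token assignment: sources at 100, the seed species
at 100 (control), 10 (down-regulation/knockdown) or 500
(up-regulation/overexpression), everything else at 0. Each scenario is
simulated as an ensemble of `n_runs = 500` independent runs over
`n_timepoints = 20` steps, recording per species $i$ and time point the
ensemble mean $\mu_i$ and unbiased sample variance $\sigma^2_i$.

Significance is assessed at the final (most stable) time point with the
two-sample statistic

$$ t_i \;=\; \frac{\mu_{i,c}-\mu_{i,p}}
  {\sqrt{\sigma^2_{i,c}/n+\sigma^2_{i,p}/n}}, \qquad n = 500, $$

comparing $|t_i|$ with the critical value $t_{0.05,500} = 1.965$. Two
numerical conventions matter here:

* **Degrees of freedom for p values.** The default is $2n-2 = 998$ (two
  ensembles of $n$ runs enter the statistic); the significance *call*
  nevertheless uses the fixed critical value 1.965 by default. Both are
  overridable in `test_config()`.
* **Degenerate species.** A species whose count never varies in either
  ensemble (e.g. a pure catalyst that never gains or loses tokens) has zero
  variance in both; its $t$ is 0 for equal means and signed infinity
  otherwise. Such rows are flagged in the `degenerate` column and retained,
  never dropped.

No multiple-testing correction is applied by default — each $|t|$ is
compared directly with the critical value; `test_config(bonferroni =
TRUE)` is available. Species annotated `inactive` are excluded from the
reported table (`active_only = TRUE`) but kept in the raw result: the
screen targets each molecule in its active state.

## Subnetwork extraction

Before simulating, `extract_seed_subnetwork()` trims the map to the part
that can interact with the seed: the strongly connected component
containing the seed (computed on the bipartite graph *with* reaction nodes
— a species-only projection would change the components), augmented with
every node weakly connected to that core, i.e. its ancestors and
descendants. We use this deterministic, parameter-free definition of the
augmentation (rather than any heuristic overlap clustering): it is exactly
the set of nodes connected to the core in at least one direction, it is
reproducible, and it is testable against a brute-force reachability
oracle. Everything else — isolated clusters that can neither affect nor be
affected by the seed — is removed; the removal set is reported, and
reactions that lose all reactant or all product places in the cut are
flagged.

## Reproducibility and RNG

All randomness flows from one integer. An ensemble seeds a private stream
with `rng_seed` and draws one sub-seed per run, so run $i$ is reproducible
standalone (`simulate_run(..., run = i)`) and identical configurations give
bit-identical summaries; the three scenario ensembles of `spn_perturb()`
use `rng_seed`, `rng_seed + 1`, `rng_seed + 2`. The global RNG state of the
caller is saved and restored around every simulation.

## The synthetic generator

`generate_network()` produces test networks with the structural features
the analysis assumes — a seed inside a planted strongly connected cycle,
upstream sources feeding it, downstream species and sinks fed from it,
optional modifier edges, and an optional planted isolated component.
Construction is layered (upstream → core → downstream, acyclic within
layers, modifier sources restricted so they cannot close new cycles), which
makes the planted core provably *the* strongly connected component of the
seed and the planted isolated nodes exactly the removable set; both are
returned as ground truth, so extraction can be tested against construction
rather than against itself. The generator makes no attempt to mimic the
degree distribution of any particular curated map; its job is structural
coverage, not statistical realism. Consequently, passing tests demonstrate
correctness of the algorithms on networks with these motifs, not biological
validity on real maps.

`crkl_motif()` is a fixed six-species miniature of a seed-centred
subnetwork, labelled after the CRKL neighbourhood in rheumatoid-arthritis
signalling: ABL1 (source) catalyses, through an activating modifier edge,
the feedback reaction that re-activates the seed CRKL; mass flows
CRKL → PXN → RAPGEF1, branching to the sinks RHOQ and RAP1B and feeding
back to CRKL. The feedback cycle gives the seed a non-trivial strongly
connected core and retains circulating mass, so the final-time screen
operates on non-degenerate counts; ABL1 itself never gains or loses tokens
and is the canonical degenerate row.

## Numerical and testing choices

* Trajectories on the motif decay toward zero (sinks drain, sources are
  not replenished), so "stabilisation" is measured as the per-step change
  of each node's mean being under 5% of that node's trajectory maximum
  over the last five of twenty steps — a relative-to-current-value
  criterion is ill-defined near zero.
* The simulator's correctness is checked against an exhaustive
  Markov-chain enumeration oracle (exact distribution propagation over all
  firing orders, all uniform draws and all sink losses) on miniatures of
  up to 3 species and 3 tokens, with ensembles of $10^5$ runs agreeing
  within 3 Monte-Carlo standard errors; the type-I error of the screen is
  calibrated on 200 control-vs-control replicates of 100-run ensembles
  (per-species rejection counts inside the exact 99% binomial interval
  around 5%). These sizes keep the full suite in the minutes range while
  leaving the Monte-Carlo slack far below the effects the screen is meant
  to detect.
* Variance uses the unbiased $n-1$ estimator; the $t$ denominator divides
  by $n$ = `n_runs` as the statistic is written.

## Limitations

* Token semantics are purely ordinal: means are relative to the arbitrary
  100-token source level and comparable only across scenarios of the same
  network, never across networks or to measured expression.
* Inhibiting-modifier semantics (block at/above threshold) are the
  package's convention; curated maps encoding inhibition differently need
  their edges mapped accordingly.
* The firing schedule (every reaction once per block) is one convention
  for "any enabled transition may fire"; alternatives (e.g. sampling with
  replacement) would change time scales but not the control-vs-perturbed
  design.
* GraphML is the only ingest format; CellDesigner/SBML sources must be
  exported to GraphML with species/reaction node kinds and typed edges
  (the attribute names are configurable via `graphml_attrs()`).
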