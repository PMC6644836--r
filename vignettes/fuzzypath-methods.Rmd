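---
title: "Modeling drug perturbation of reaction pathways with fuzzypath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling drug perturbation of reaction pathways with fuzzypath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzypath)
```

## The modeling problem

Curated pathway databases describe biology as *biochemical reactions*: an
event with one or more inputs, optional catalysts, activators and
inhibitors, and one or more outputs. Complexes (all subunits required) and
entity sets (interchangeable members, e.g. isoforms) add structure on top.
A reaction wiring diagram alone cannot answer the question a pharmacologist
actually asks — *what happens to the pathway's outputs when this drug
inhibits that kinase?* — because real pathways contain feedback loops whose
dynamic consequences are not readable by eye.

`fuzzypath` answers that question in four steps:

1. **Compile** the reaction description into a Boolean network.
2. **Simulate** the network with constrained fuzzy logic: states are
   continuous in [0, 1], updates are synchronous, and traces settle into
   fixed points or cycle attractors.
3. **Perturb**: map a drug's binding-assay evidence (KD/Ki/IC50/EC50 in nM)
   to an inhibition or activation strength and gate the targets' transfer
   functions with it.
4. **Score**: compare the perturbed and reference simulations per entity
   with a relative impact score computed from the areas under the
   fuzzy-value-versus-time curves.

Around this core the package carries the standard companion analyses of
drug-target work: evidence-table reading and filtering, binomial-test
pathway enrichment with Benjamini–Hochberg FDR, and overlay of drug edges
onto a functional-interaction subnetwork of frequently mutated genes.

## Boolean compilation

Each entity becomes one Boolean variable. A reaction becomes an AND over
its inputs, catalysts, the activator term and the *negated* inhibitor term,
driving its output. When a role (activators, inhibitors, outputs) has two or
more members, an *accessory variable* keeps the relation simple: activators
and inhibitors are ORed into an accessory that enters the AND as one
literal, and multiple outputs are fed from an output accessory through one
ASSIGN each. A role with a single member is wired directly — the semantics
are identical, which the test suite proves by brute-force truth-table
enumeration against the flat formula.

```{r}
net <- build_network(make_typical_reaction())
writeLines(vapply(net$relations, fuzzypath:::format_relation, character(1)))
```

Complexes compile to AND over their subunits, entity sets to OR over their
members; nesting resolves through the inner container's own variable. An
entity produced by several reactions combines its producing relations by OR
at evaluation time: any producing reaction suffices, and the compilation
stays one-relation-per-reaction.

All iteration is in lexicographic id order, so compilation is deterministic
down to byte-identical serialization.

### Root inputs and initial values

Default initial values follow the rule: entities that reactions *use* (as
input, catalyst, activator or inhibitor) start at 1.0 if they are either
never produced as an output or sit on a directed cycle of the
entity→reaction→entity graph; every other variable starts at 0.0. The
"used role" reading includes catalysts and regulators deliberately: a
simulation in which regulators start inactive never leaves the ground
state. Cycle membership is decided on strongly connected components of the
bipartite entity/reaction graph. The non-root default of 0.0 is the
conservative unexcited state; any variable can be overridden through
`sim_config(initial_values = ...)`.

## Fuzzy simulation

Semantics are Gödel fuzzy logic — min for AND, max for OR, `1 - x` for
NOT — the standard choice in the constrained-fuzzy-logic lineage of logic
modeling toolkits. These operators map [0, 1] into [0, 1], so all states
remain valid for any valid start; restricted to {0, 1} with identity
transfers they reproduce exact two-state Boolean dynamics, which the suite
checks step-for-step against an independent Boolean simulator.

Updates are synchronous: every variable is recomputed from the previous
step's state. A per-variable *transfer function* is applied to the combined
relation value before it becomes the next state: identity by default, or a
normalized Hill function `f(x) = x^n (1 + k^n) / (x^n + k^n)` (defaults
`n = 3`, `k = 0.5`) anchored at f(0) = 0 and f(1) = 1.

Stopping rules (all defaults, all overridable via `sim_config()`):

* **convergence** when the maximum change between consecutive steps drops
  below `1e-6`;
* otherwise an **iteration cap** at the larger of 100 and 1.2 × the number
  of variables.

### Attractors and trace expansion

Deterministic synchronous networks settle into fixed points or cycle
attractors; networks with feedback loops typically oscillate.
`detect_attractor()` finds the smallest period and earliest start such that
rows repeat to the end of the trace, requiring two full periods of evidence
and matching rows at tolerance `1e-9` — below the convergence tolerance,
above float noise. A trace that terminated by numerical convergence without
an exact row repeat is treated as a period-1 attractor at its last row.

Because impact scores are AUC ratios, they depend on how long the attractor
is replayed. `expand_trace()` therefore replays the attractor cycle in
blocks of 20 time steps and stops when the monitored per-variable quantity
changes by less than 0.01 between consecutive expansions, or at 1000 total
steps. In the two-trace (reference/perturbed) case the monitored quantity
is the relative impact score itself — the expansion exists to stabilize
it — and both traces are extended in lockstep so AUCs are always compared
over equal step counts. For a single trace, where no score is defined, the
per-variable mean fuzzy value (AUC divided by steps) plays the same role.

## Drug perturbation

The affinity-to-strength map takes the *minimum* supporting assay value
across all assay types for a drug-target pair:

* `0.999` below 1 nM,
* `0.99` below 10 nM,
* `0.99 - 0.196 * (log10(v) - 1)` below 1e6 nM,
* `0` at or above 1e6 nM,

clipped to [0, 0.999]. The logarithm is base 10; that choice is forced by
continuity — `log10(10) = 1` makes the third branch meet the second exactly
at the 10 nM boundary, where a natural log would leave a 0.25 jump.

A strength *s* gates its targets after their transfer function, at every
step: inhibition multiplies the value by `(1 - s)`; activation moves it to
`v + s(1 - v)`. Both forms preserve [0, 1] and reduce to a no-op at
`s = 0`. One boundary case needs a decision: a target that no relation
drives (a held root input, such as a receptor the pathway file never
produces). Gating a held value per step would compound into a geometric
decay to zero for *any* positive strength, destroying the dose response, so
such targets are instead clamped once to `initial × (1 - s)` (respectively
the activated analog) from the first step onward. Step 0 always shows the
unperturbed initial state.

A drug targeting a protein that sits inside complexes or sets perturbs the
protein-level variable; containers feel the perturbation through their own
AND/OR relations, matching the compilation structure.

The per-entity **relative impact score** is

```
score = (perturbation_AUC - reference_AUC) / (perturbation_AUC + reference_AUC)
```

with AUC the sum of a variable's values over time steps (rectangle rule,
unit step width) and 0/0 defined as 0. Scores live in [-1, 1] and negate
under swapping the traces. Note the score's known sensitivity when the
reference AUC is close to zero: a tiny absolute increase then reports as a
score near +1.

## The feedback-loop generator

`make_feedback_loop_pathway(n)` builds the motif the simulator is designed
to expose: an entry reaction (ligand input, kinase catalyst) feeds a
rotation loop of `n` reactions whose final reaction regenerates the loop
entry and emits an output complex; the output, gated by a modulator
catalyst, produces a feedback entity that inhibits the first loop reaction.
The single negation in the cycle makes it a delayed negative feedback, so
under synchronous update the compiled network oscillates rather than
converging. With all defaults the output's attractor is a 0/1 cycle; three
interventions reshape it in ways that mirror the behavior of real
signaling loops:

* lowering the **modulator's** initial value to 0.5 caps the feedback
  inhibitor at 0.5, raising the floor of the oscillation from 0 to 0.5;
* **inhibiting the kinase** (e.g. strength 0.95) throttles the loop entry
  and collapses that floor toward `1 - s`;
* both together give the perturbed-versus-reference geometry in which the
  drug's impact is much larger when the modulator is partially active — the
  situation in which mutation status qualitatively changes a drug's
  predicted effect.

The generator's defaults (`loop_reactions = 4`, modulator override 0.5 in
the examples, inhibitor strength from a 16 nM KD) are fixed study
conditions, not tuning knobs.

## What the synthetic data does and does not show

All fixtures are generated in code: pathway JSON, drug tables (log-uniform
assay values over [0.1, 1e6] nM across KD/Ki/IC50/EC50, at least two rows
per covered pair), the 12-gene-set enrichment fixture with fixed sizes
(406, 202, 207, 246, 8, 8, 4, 90, 94, 95, 6, 12) and kinase memberships, and
the mutation/FI fixture (18 drugs, 14 of them on one hub receptor, one drug
bridging two disjoint-pathway kinases). Passing tests on these fixtures
shows that the compilation, simulation, scoring and filtering machinery
implement their definitions exactly, and that the qualitative loop
phenomena (periodic attractors, floor collapse, direction of impact scores)
emerge from the mechanisms they are supposed to emerge from. It does *not*
show that any particular curated pathway will reproduce published attractor
values: those depend on the full curated reaction structure, which is why
exact literature score values are out of scope here.

Synthetic tables are statistically unrealistic on purpose — affinities are
log-uniform, not drug-like; mutation counts are a small hand-laid panel.

## Enrichment and network overlay

Pathway enrichment uses the upper-tail binomial test
`P(X >= k), X ~ Binomial(n, s/N)` (computed through `pbinom`, which works
on the log scale internally) and Benjamini–Hochberg FDR across sets
(through `p.adjust`); the test suite checks both against independent
oracles (exhaustive enumeration for n ≤ 12; the closed-form step-up). The
background size `N` is an explicit parameter — results depend on it, and
the default 20000 is a documented genome-scale placeholder, not a
recommendation. Results are sorted by p-value with ties broken by pathway
name.

The network overlay keeps genes mutated in at least `min_samples` samples
(default 5), keeps FI edges with both endpoints surviving, and adds drug
nodes with edges to network genes whose minimum assay value is at or below
`max_nM` (default 100, inclusive — as is every assay threshold in the
package). Drug nodes are a distinct node class in the exported
node-attribute table; rendering is out of scope.

## Numerical choices and degenerate inputs

* Assay thresholds are inclusive (`<=`); histogram bins are half-open
  `[lo, hi)` with the final bin closed.
* p-scale activity values convert to nM as `10^(9 - p)` only behind an
  explicit flag — units are never guessed.
* An entity that is both input and catalyst of one reaction contributes a
  single literal (idempotent AND).
* Reactions must have at least one input and one output; files violating
  this are rejected at read time rather than patched.
* Malformed evidence rows are routed to a rejects report with reasons, not
  dropped silently.
* Empty queries, empty pathways and empty networks are valid and produce
  empty, well-formed results.

## Problem sizes used in the shipped checks

The test suite works at desk scale: brute-force truth tables up to 2^12
assignments, 100 random reactions and 100 random networks of at most 12
variables, 1000 random trace pairs for the score properties, and loop
pathways of 2–6 reactions. These sizes are where the independent oracles
(exhaustive enumeration, a pure Boolean simulator) are exact, which is the
point of the exercise; the implementation itself has no small-size
assumptions.

## Known limitations

* Asynchronous update schemes and multi-valued logics beyond the fuzzy
  extension are not implemented; the iteration-cap stopping rule
  presupposes a global synchronous step.
* Parameters are not learned from data; initial values and transfer
  parameters are user configuration.
* The impact score saturates near ±1 when one AUC is near zero (see above).
* Mutation effects on drug binding are not modeled; a drug's strength is a
  property of the (drug, target) pair only.
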