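---
title: "Contextualizing prior-knowledge networks by Boolean attractor matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextualizing prior-knowledge networks by Boolean attractor matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolprune)
```

## The problem

Prior-knowledge networks (PKNs) of gene regulation are inclusive by
construction: they merge signed, directed interactions reported across many
cell types, tissues and experimental conditions. A dynamical model built
directly on such a network rarely reproduces the behaviour of any one
biological context, because a fraction of its edges is simply not active
there. `boolprune` addresses this by *contextualization*: given a PKN and a
Booleanized expression profile of two stable phenotypes (for instance, the
initial and final states of a cellular transition), it searches for the
edge-subsets of the PKN whose Boolean dynamics reproduce both phenotypes as
stable states. Pruning removes edges only — every gene remains in the model.

## The Boolean model

Each gene `i` carries a binary state `x_i`, and the network state is updated
synchronously: every node reads the current state and writes the next one at
the same time. Update rules are derived from the (pruned) network with the
inhibitor-dominant convention: *a node is active iff at least one of its
retained activators and none of its retained inhibitors are active*. In the
polynomial encoding used by the engine (AND as product, OR as
`x + y - xy`, NOT as `1 - x`), this is

    x'_i = OR(activator states) * (1 - OR(inhibitor states))

Two boundary conventions matter and are deliberate:

* **Nodes whose regulators are all pruned away evaluate to constant 0.** An
  empty activator OR is 0. This follows the strict reading of "at least one
  of its activators", and it removes a degenerate optimum: if unregulated
  nodes instead held their state, deleting every edge would make all states
  fixed points and score perfectly.
* **Input nodes hold their state.** Nodes with in-degree 0 in the *original*
  PKN represent external stimuli or unmeasured regulators; their state is an
  experimental boundary condition, not something the model should relax to 0.
  The flag is recorded from the PKN at rule-construction time and inherited
  by every subnetwork, so pruning cannot turn a regulated gene into an input.
  Set `inputs_hold_state = FALSE` to force the strict rule everywhere.

If both an activating and an inhibiting edge between the same pair survive
pruning, the source appears in both regulator sets and inhibition dominates —
a direct consequence of the rule.

A trajectory is iterated until the state repeats: an immediate repeat is a
**fixed point**, a repeat of an earlier state is a **cycle** (detected by
exact state hashing over the canonical sorted node order, any period),
and a trajectory exceeding `max_steps` (default 1000) is **truncated** and
treated like a cycle at scoring time. The bundled three-node demonstration
system (`toy_boolean_system()`), whose bespoke functions include an AND gate
and a bare negation, exercises the polynomial encoding and cycle detection;
PKN-derived models always use the OR-of-activators rule, which is why that
system ships as explicit update functions rather than as a network.

## Fitness

Each phenotype is imposed as an initial state, relaxed to its attractor, and
compared with itself at the attractor. With `N_p` phenotypes and `N_g`
scored genes,

    f = 1 - (sum_i h_i) / N_p,     h_i = (1/N_g) sum_j |phi_ij - alpha_ij|

where `h_i` is the normalized Hamming distance between phenotype `i` and the
attractor reached from it. `f = 1` means every phenotype is an exactly
matching fixed point; any cyclic or truncated trajectory scores the whole
subnetwork 0, since the method models stable phenotypes as point attractors
and defers oscillatory behaviour. `N_g` counts the genes with known
phenotype values present in the network — during cross-validation that is
the training subset, and genes measured but absent from the PKN are excluded
with a warning.

Network nodes without a known phenotype value are filled by an *init
policy*: `"zero"` (default; deterministic and reproducible) or `"random"`
(Bernoulli(0.5) per evaluation from the seeded stream). The central
assumption inherited by the whole approach is that a state in the basin of
an attractor is closer to that attractor than to any other; it is an
assumption about biological networks, not something the code enforces.

## The estimation-of-distribution optimizer

The search space is the power set of the PKN's edges. The optimizer is a
univariate estimation-of-distribution algorithm (EDA):

1. draw `population_size` subnetworks, each edge kept with probability
   `initial_edge_probability` (default 0.5, the maximum-entropy choice);
2. score the population and select the `selection_number` best; ties are
   broken toward fewer edges (parsimony matches the pruning intent), then by
   a lexicographic hash of the edge set, making runs reproducible;
3. estimate each edge's inclusion frequency in the selected group, and
   sample the next generation edge-by-edge from those frequencies (an edge
   is kept when the uniform draw is ≤ its frequency, so a draw exactly at
   the frequency keeps it);
4. append the `elitism_number` best-ever networks unchanged (stored
   deduplicated; the population is padded with fresh samples when fewer
   distinct elites exist) and repeat for `max_iterations` generations.

Defaults — population 30, selection 10, 100 iterations, elitism 5 — follow
the standard configuration of the validation protocols; 5 is the top of the
recommended elitism range (at most half the selection number, to keep
degrees of freedom in the search). One global seed drives every draw of a
run, and derived seeds give each cross-validation split its own stream, so
results are bit-reproducible.

**Frequency smoothing.** Raw selection frequencies freeze an edge the moment
it appears in all (or none) of the selected subnetworks; on small
instances whose perfect subnetworks are rare, the search can collapse onto a
local optimum within a handful of generations and spend the remaining budget
re-sampling one network. The estimated frequencies are therefore shrunk by
the rule of succession — sampled frequency `(count + 1)/(selection_number + 2)`,
i.e. `e = 1/(selection_number + 2)` in `f -> (1-2e)f + e` — which keeps
every edge explorable while elitism guarantees nothing good is lost and the
best-so-far trace stays monotone. `smoothing = 0` restores raw frequencies.

The frequencies are estimated from the selected group alone (not selected
plus elites), and interruptibility is provided by the `on_iteration`
callback, which sees the best-so-far and mean fitness after every completed
generation.

`random_search_baseline()` is the control for the validation logic: the same
loop with scoring and elitism, but each new generation drawn from the
initial density instead of the estimated frequencies. It evaluates exactly
as many subnetworks as the EDA, so the comparison isolates the contribution
of distribution estimation.

## Evaluation protocols

* **Cross-validation** (`cross_validate()`): the phenotype genes are split
  at random into training and validation sets; optimization sees only the
  training genes (they alone are scored and they alone seed the initial
  states — held-out genes are filled by the init policy). Every network of
  the final population is then re-scored on the full profile, still with the
  held-out states withheld from the initial conditions, which makes the
  full-profile score a measure of *prediction* of the missing values.
  Pooling ten splits of a population of 30 yields 300 scores per training
  size. With the full profile as training set the pathway reduces exactly to
  plain optimization.
* **Optimized vs random** (`compare_to_baseline()`): a two-sided Welch
  t-test on the pooled score samples. Degenerate inputs take the limits of
  the statistic (both samples constant: p = 1 on equal means, p = 0
  otherwise) so pipelines stay total.
* **Sensitivity** (`sensitivity_missing()`, `sensitivity_wrong()`): the
  training signal is degraded either by withholding genes (removed from
  scoring and from the initial states) or by bit-flipping their states in
  every phenotype; the resulting populations are evaluated against the
  original full profile. For complementary phenotype pairs, flipping every
  gene merely swaps the two phenotypes' roles and reproduces the standard
  run — a useful algebraic check.

## Perturbation simulation

Perturbations are instant state changes: the listed genes are set to the
requested values and the state is then freely updated — nothing is clamped.
Flipping an input node is persistent (inputs hold state); flipping a
regulated node is transient and may decay. The reached attractor is
classified against the expected target phenotype as `stayed_initial`
(equal to the unperturbed initial state's own attractor), `transition_matched`
(match fraction at or above the threshold), `other_attractor`, or
`cyclic_or_truncated`. The match threshold is an experimental input, not a
constant: exact match is appropriate when the target profile is fully
specified, looser fractions (0.75, 0.5) when it is not.
`perturbation_response_rate()` aggregates the matched fraction over a
population of contextualized networks — only a fraction of equally
well-scoring networks is expected to show the right response, and that
fraction is itself informative about the population's topological diversity.

Sustained knockouts (re-imposing the perturbed value at every step) are a
non-goal; only instant flips are simulated.

## Synthetic benchmark instances

`generate_planted()` builds instances that emulate the published validation
design — a curated network that explains the phenotypes, blindly expanded
with literature-mined interactions, some of which are inconsistent with the
context:

1. a phenotype vector over `n_nodes` genes is drawn so that both states
   occur, and (with two or more inputs) both occur among the inputs;
2. the **true network** is wired so that the vector *and its bitwise
   complement* are fixed points by construction: every regulated node gets
   one activator sharing its phenotype state, preferentially one already
   wired (inputs first) so that regulation cascades outward from the
   external inputs, plus optional extra consistent edges (same-state
   activations, cross-state inhibitions) up to `n_true_edges`;
3. the complementary fixed points become the `initial`/`final` phenotypes —
   matching the Booleanization of a two-condition differential comparison,
   where the profiles are complementary by construction;
4. **spurious edges** are proposed at random with the true network's
   activation:inhibition balance, never targeting inputs (an edge into an
   input would silently change the input set recorded from the PKN), and an
   addition is rejected whenever the expanded PKN would still hold both
   phenotypes as exact fixed points.

The construction guarantees the invariants the tests rely on: the planted
network scores exactly 1, the full PKN scores strictly below 1, and on
backbone-only instances flipping the inputs provably drives the transition
to the complementary phenotype. Two scale tiers are used: a small tier
(8 nodes, 12 PKN edges) whose `2^12` subnetworks can be enumerated
exhaustively as an oracle, and a medium tier (36 nodes, 238 edges) matching
the scale of a T-helper-cell transdifferentiation network, used to exercise
performance.

What the fixtures do **not** emulate: realistic degree distributions and
network motifs of curated GRNs, bespoke logic functions (AND gates between
co-activators), noise or thresholding artifacts in the Booleanization of
expression data, and systems with more than two attractors of interest.
Passing the planted-instance tests therefore demonstrates the correctness
of the machinery and the optimizer's ability to remove inconsistent edges —
not that any particular biological PKN will be contextualized correctly.
Exports of published supplementary networks (SIF) and phenotype tables
(TSV) can be loaded with `read_network()` / `read_phenotypes()` to
reproduce full biological analyses.

## Numerical and reproducibility choices

* Canonical node order is the sorted gene-name order everywhere; state
  hashing is exact bit-vector equality over that order, so cycle detection
  is platform-independent.
* Gene identifiers are opaque, case-sensitive strings; no symbol
  normalization is attempted.
* All stochastic components run off one integer seed per run; derived seeds
  (a fixed integer-linear scheme kept below 2^31) give independent streams
  to cross-validation splits.
* Problem sizes in the test-suite and in `scripts/acceptance.R` are the two
  fixture tiers above with the standard 30/10/100 configuration and ten
  runs per protocol.

## Limitations

Only the topology is optimized, never the logic functions: an inhibition
pruned from the model may be a real interaction that is simply not dominant
in this context. Cyclic attractors are detected but not scored, so
oscillatory processes are out of scope. Synchronous updating is the only
scheme implemented. Pruning assumes the PKN is complete enough — missing
interactions cannot be invented. And the contextualized population is
typically degenerate: many distinct subnetworks explain the same two
phenotypes, and their responses to perturbations can differ; convergence of
independent runs to similar topologies is the practical indicator that
predicted responses can be trusted.
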