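---
title: "Finding phenotype attractors by hierarchical partition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding phenotype attractors by hierarchical partition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoattract)
```

## The model class

A synchronous Boolean network assigns every node $x_i \in \{0,1\}$ an
update rule $x_i^* = f_i(x_{j_1}, \dots, x_{j_k})$, applied to all nodes
simultaneously at each discrete time step. Two rule families are
supported: logic rules over `&`, `|`, `!` with parentheses, and threshold
(sign) rules $x^* = \mathrm{sgn}(c_0 + \sum_j c_j x_j)$ with integer
weights, where a strictly positive sum gives 1 and a sum of zero gives 0.
The strict-positivity convention is forced by how sign rules behave in the
published cancer-pathway models: a rule `sgn(Caspase8 + Caspase9)` with
`Caspase8` silenced must equal 1 exactly when `Caspase9 = 1`.

An *attractor* is a cyclic state sequence closed under the update map,
with all states distinct within one period; a period-1 attractor is a
point attractor. Attractors are stored in *canonical rotation* (the
rotation with lexicographically minimal concatenated bit-string, which is
unique because states within a minimal period are distinct), making set
comparison of attractors well defined. State strings follow the node
declaration order of the model file, and sub-network states follow the
sub-network's own member order, so printed tuples are reproducible.

## The procedure

The pipeline asks one question: *which attractors of the network hold a
given phenotype constantly active (or inactive) under a given
environment?* It exploits the fact that the answer only requires exploring
the part of the state space consistent with the phenotype.

**Step 1 — external condition.** Environment values (stimuli, clamped
perturbations) are substituted into all rules by partial evaluation, using
constant folding only (`0 & e -> 0`, `1 & e -> e`, `1 | e -> 1`,
`0 | e -> e`, `!!e -> e`, `!0 -> 1`, `!1 -> 0`; threshold terms fold into
the offset, and a threshold whose achievable sum can no longer cross zero
folds to a constant). Rules that fold to constants fix their targets
(secondary-external nodes); this iterates to a fixpoint, which takes at
most $|V|$ rounds because the fixed set only grows. No logic minimisation
beyond these identities is attempted — residual rules stay auditable, and
a semantically constant but syntactically irreducible rule (say
`a | !a`) simply stays in the residual network, where the attractor
machinery resolves it anyway.

Clamps are treated as *assertions about the attractor*, not as rule
replacement: a clamp that contradicts the node's own rule under
propagation yields "no attractor", the same answer a full search over the
original network would give after filtering. Models whose inputs are meant
to be freely clamped should give them identity self-loops (`A, A`), the
usual convention.

**Step 2 — phenotype condition.** The phenotype rule, after Step-1
substitution, is inverted: every assignment of its remaining inputs that
makes it equal the required value becomes one independent branch (for the
typical conjunction of literals the assignment is unique; enumeration and
branching is the conservative generalisation for other shapes, and final
attractors are de-duplicated across branches). The phenotype node itself
is fixed and removed from the residual network. Marker values are
propagated like Step 1, with one addition: a node held constant must have
its rule body equal that constant at *every* time step, so
literal-decomposable bodies propagate backwards (a single literal pins its
node; a conjunction required to be 1 pins every conjunct; a disjunction
required to be 0 pins every disjunct). Bodies that are not
literal-decomposable — general logic or threshold sums — are emitted as
*constraint equations/inequalities* over residual nodes and enforced on
every row of every candidate trajectory. This is exactly the behaviour
visible in the published examples: a caspase chain pins
`(Caspase9, Cytoc/APAF1) = (1, 1)` through a single positive literal while
the upstream threshold survives as `0 < -AKT + p53 - BCL_2 - Bcl_XL`, and
logic models keep pairs like `MAX | AKT = 1`, `!AKT & p53 = 0`.

**Step 3 — hierarchical partition (HPFP).** The residual rules induce a
dependency graph (edge regulator → target per syntactic reference). Its
SCCs are layered into categories by longest path over the condensation:
category 1 = zero in-degree; category $n$ = all incoming edges from
categories below $n$, at least one from $n-1$. The longest-path layering
is the unique assignment satisfying both conditions (induction over the
condensation), and both are re-checked property-style in the test suite.
SCC labels $V_{n,k}$ order components within a category by smallest member
declaration index; singleton SCCs with self-loops are ordinary SCCs.

**Step 4 — local attractors and concatenation.** Categories are resolved
in order. Each SCC is driven by the joint periodic trajectory of the
already-resolved nodes restricted to its inputs — the *period is never
minimised mid-pipeline*, so all components share one clock and phase
bookkeeping stays trivial. Local attractors are the cycles of the product
map $(t, s) \mapsto (t+1 \bmod P,\ \mathrm{step}(s \mid \mathrm{signal}(t)))$,
found exhaustively from every SCC state at driver phase 0. Every product
cycle has length a multiple of the driver period and therefore passes
through phase 0, so phase-0 starts find all cycles, and starting points
within a cycle that differ by a driver period give the same joint
attractor up to rotation. Rotating the driver likewise cannot change the
local attractor set; `phase_shift_check()` verifies this on demand and a
paranoid all-phase mode is available. Each choice of local attractor
extends a branch: trajectories are unrolled to the lcm of the periods and
bound column-wise (row $i$ = every component's state at time $i$).
Constraints are checked as soon as all their nodes are resolved — early
pruning is safe because condensation edges never point backwards.

**Step 5 — assembly and verification.** Completed branches are widened by
the fixed columns (constants have period 1, so the period is unchanged),
periods are then minimised by a divisor check (the lcm can overcount when
a downstream component locks onto a shorter cycle), cycles are
canonicalized and de-duplicated, and every attractor is re-verified by
stepping it under the *original* update rules; the pipeline refuses to
emit anything that fails. Minimality of the reported period follows from
determinism: repeated states within a period would contradict the divisor
check.

## Correctness claim and how it is tested

For any network small enough for full search, the emitted set equals
$\{A \in \mathrm{bruteforce}(G) :$ every externally clamped node and every
phenotype marker of some satisfying assignment holds its value in every
state of $A\}$, compared as canonical-rotation sets. The test suite runs
this equivalence on hundreds of seeded random (network, scenario) pairs of
up to 12 nodes, alongside per-stage oracles: truth-table evaluation
against the vectorised step, a semantic constant-propagation fixpoint on
rule families where it coincides with syntactic folding, a
reachability-matrix SCC oracle, an exhaustive-path layering oracle, and a
product-space brute force for driven SCCs. The randomized suite
deliberately uses small networks — the full-search oracle, not the
pipeline, is the bottleneck — so passing tests demonstrate algorithmic
correctness, not scalability limits.

## Tunable parameters

* `cap` (default 20): maximum SCC size for exhaustive local search; the
  premise of the method is that simplification leaves small SCCs
  (published case studies: at most 4–7 nodes), so hitting the cap is
  reported as a distinct outcome naming the oversized component rather
  than silently burning CPU. 2^20 product states is the practical ceiling.
* `max_branches` (default 10000): bound on simultaneously open
  local-attractor combinations during concatenation.
* `value` (default 1): required phenotype value; 0 asks for attractors
  with the phenotype constantly off.
* `all_phases` (default off): paranoid re-enumeration of local attractors
  from every driver phase; must return (and in tests does return) the
  same set as phase-0 enumeration.

## The synthetic-data generator

`generate_network()` emulates the structural features the pipeline
exercises: identity self-loop input nodes (clampable environment),
moderate in-degrees (uniform 1..3 by default, the typical range in curated
logic models), three rule families (random truth tables as DNF,
conjunction/disjunction of literals, unit-weight threshold rules), an
optional planted phenotype sink whose rule is a conjunction of literals
(the canonical marker shape), and an optional planted hierarchy — a DAG of
rings with chosen sizes per layer — whose HPFP is known by construction.
Scenarios clamp 0–3 input nodes and require the sink at 1. A single
integer seed drives all randomness; identical specs generate identical
fixtures. What the generator does *not* emulate: the degree heterogeneity,
long feedback spans and giant SCCs of real curated pathway maps
(50–100 nodes with components of 37–68 nodes). Passing the randomized
suite therefore validates the algorithm's correctness contract, while
behaviour on real models is exercised only at the scale of the built-in
fragments.

## Numerical and design choices

* Deterministic everywhere: SCC order by smallest member declaration
  index, initial local states in numeric bit-code order, cycle anchors at
  driver phase 0, output attractors sorted by canonical key. Identical
  inputs give byte-identical machine outputs.
* Bit-packed integer encodings index the product space and the full state
  space; column 1 is the least significant bit.
* Threshold fold-to-constant uses the min/max achievable sum over
  residual 0/1 assignments — exact for the sign test, no approximation.
* A branch whose marker assignment contradicts a clamped or derived value
  is reported as an infeasible branch with the offending node named, not
  as an exception; "no attractor exists" is a first-class result
  (exit status 3 in the CLI wrapper).
* Parsing accepts `sgn(...)` and `sgn[...]`; serialisation emits
  `sgn(...)`, and the parser/serialiser round-trip is the identity on the
  canonical dialect (property-tested).

## Known limitations

* Synchronous semantics only; asynchronous update schemes have different
  attractor structure and are out of scope.
* Only attractors in which the phenotype markers are *constant* are found
  — that is the definition of consistent phenotype activation used here.
  Attractors where the phenotype node stays on while its markers oscillate
  are outside the contract (and outside the published definition).
* Basins of attraction are not computed (the simplification discards the
  off-phenotype part of the state space); the brute-force oracle reports
  basin sizes incidentally for small networks.
* Threshold bodies are never inverted into marker assignments during
  backward propagation; they always become constraint inequalities. This
  matches the published derivations and keeps inversion decidable by
  inspection, at the cost of a slightly larger residual network when a
  threshold is in fact uniquely invertible.
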