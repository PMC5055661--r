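# phenoattract

Phenotype-constrained attractor search for synchronous Boolean networks.

## The problem

Boolean networks are the workhorse parameter-free formalism for large
biomolecular regulatory systems: each node carries a 0/1 state and a logic
rule (`Proliferation* = p70 & MYC & !p21`) or a threshold rule
(`Cytoc/APAF1* = sgn(-AKT + p53 - BCL_2 - Bcl_XL)`, where `sgn` maps a
strictly positive weighted sum to 1), and all nodes update synchronously.
The converged behaviours of such a model — its **attractors**, i.e. cycles
`s(0) -> s(1) -> ... -> s(p-1) -> s(0)` of the update map — correspond to
cell phenotypes. Finding them by full state-space search needs 2^N
trajectory traces and is hopeless beyond roughly 20 nodes, and
SCC-partitioning of the raw network rarely helps because signalling
networks are dominated by one huge strongly connected component.

`phenoattract` finds **all attractors that realise one phenotype of
interest**, which is usually what the analysis needs, at a fraction of the
cost:

1. **External condition.** Environment clamps (stimuli, microenvironment,
   perturbations) are substituted into the rules; every rule that folds to
   a constant fixes its target ("secondary-external" nodes), to a fixpoint.
2. **Phenotype condition.** The phenotype rule is inverted into the marker
   values that keep it constantly on (for `p70 & MYC & !p21 = 1`, exactly
   `(p70, MYC, p21) = (1, 1, 0)`); these are propagated the same way, also
   backwards through literal rules. A fixed node whose own rule still
   depends on free nodes leaves a **constraint equation/inequality**
   (e.g. `MAX | AKT = 1`, `0 < -AKT + p53 - BCL_2 - Bcl_XL`) that every
   admissible attractor state must satisfy.
3. **Hierarchical partition (HPFP).** The residual network is decomposed
   into SCCs layered into categories: category 1 = zero in-degree in the
   condensation; category n receives inputs only from lower categories,
   at least one from n-1.
4. **Local attractors.** Each SCC is small after simplification; its
   attractors under the periodic drive of already-resolved upstream nodes
   are found by exhaustive search in the (driver phase, state) product
   space.
5. **Concatenation.** Local attractors are concatenated row by row on a
   shared clock (the joint period is the lcm of the component periods),
   filtered by the constraints, widened by the fixed values, and every
   resulting cycle is verified under the original update rules.

For networks small enough to brute-force, the emitted set provably equals
the full-search attractor set filtered by the phenotype condition; the test
suite checks this equivalence on hundreds of random models.

## Worked example

A small mitochondrial-apoptosis fragment with threshold rules. `Caspase8`
is silenced by the environment; we ask for all attractors with apoptosis
committed:

```r
library(phenoattract)

net <- network_from_rules(c(
  Caspase8      = "Caspase8",
  AKT           = "AKT",
  p53           = "p53",
  BCL_2         = "BCL_2",
  Bcl_XL        = "Bcl_XL",
  `Cytoc/APAF1` = "sgn(-AKT + p53 - BCL_2 - Bcl_XL)",
  Caspase9      = "Cytoc/APAF1",
  Apoptosis     = "sgn(Caspase8 + Caspase9)"))

res <- find_phenotype_attractors(net, external = c(Caspase8 = 0),
                                 phenotype = "Apoptosis")
res
#> Phenotype attractor search: Apoptosis = 1
#>   original network: 8 nodes, largest SCC 1
#>   marker-assignment branches: 1 (1 feasible)
#>   branch 1 HPFP: 1 categories, 4 SCCs, max SCC size 1
#>   1 global attractor(s):
#>     period 1: [00100111]
```

What happened: with `Caspase8 = 0` the phenotype rule reduces to
`sgn(Caspase9)`, so the marker is `Caspase9 = 1`; the literal chain
`Caspase9* = Cytoc/APAF1` pins `Cytoc/APAF1 = 1` as well, and that node's
threshold rule survives as the constraint inequality

```r
format(res$simplified$branches[[1]]$constraints[[1]])
#> [1] "0 < -AKT + p53 - BCL_2 - Bcl_XL"
```

which only the residual assignment `(AKT, p53, BCL_2, Bcl_XL) = (0, 1, 0, 0)`
satisfies — hence the single point attractor `00100111` in declaration
order `(Caspase8, AKT, p53, BCL_2, Bcl_XL, Cytoc/APAF1, Caspase9,
Apoptosis)`. The attractor is verified against the original rules before it
is returned, and `write_attractors(res$attractors)` renders it as a
one-row-per-time-step table.

Model files use the plain-text `targets, factors` convention
(`read_network()` / `write_network()`); scenarios are small YAML files
(`read_scenario()`); `cmd_run()` — or the `inst/scripts/phenoattract`
wrapper — runs the whole pipeline on files and writes report, HPFP export,
attractor tables and a summary. Exit statuses distinguish "no attractor
exists" (a scientific result) from errors. `brute_force_attractors()` and
`generate_network()` provide the validation oracle and random/structured
test fixtures.

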