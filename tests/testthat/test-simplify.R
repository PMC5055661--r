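test_that("partial evaluation substitutes fixed values and folds constants", {
  thr <- parse_network("A, sgn(Caspase8 + Caspase9)\nCaspase8, Caspase8\nCaspase9, Caspase9")$rules$A
  folded <- partial_evaluate(thr, c(Caspase8 = 0L))
  expect_equal(folded$op, "thr")
  expect_equal(folded$coef, c(Caspase9 = 1L))

  conj <- network_from_rules(c(p70 = "p70", MYC = "MYC", p21 = "p21",
                               P = "p70 & MYC & !p21"))$rules$P
  expect_equal(partial_evaluate(conj, c(p21 = 1L)),
               list(op = "const", value = 0L))
  expect_equal(partial_evaluate(conj, c(p70 = 1L, MYC = 1L, p21 = 0L)),
               list(op = "const", value = 1L))

  # threshold folds to a constant when no residual assignment can flip the
  # sign test
  t2 <- parse_network("A, sgn(x - y - z + 2)\nx, x\ny, y\nz, z")$rules$A
  expect_equal(partial_evaluate(t2, c(x = 1L)), list(op = "const", value = 1L))
})

test_that("partial evaluation is sound on every completion (random sweep)", {
  for (seed in 1:30) {
    synth <- random_case(seed, n_min = 5L, n_max = 7L)
    net <- synth$network
    for (nd in net$nodes) {
      body <- net$rules[[nd]]
      vars <- expr_vars(body)
      if (length(vars) == 0L) next
      nfix <- seed %% (length(vars) + 1L)
      fixed <- if (nfix > 0)
        stats::setNames(as.integer(seq_len(nfix) %% 2L), vars[seq_len(nfix)])
      else integer(0)
      folded <- partial_evaluate(body, fixed)
      expect_length(intersect(expr_vars(folded), names(fixed)), 0L)
      for (a in all_assignments(setdiff(vars, names(fixed)))) {
        expect_equal(ref_eval(folded, as.list(a)),
                     ref_eval(body, c(as.list(fixed), as.list(a))))
      }
    }
  }
})

test_that("constant propagation reaches the re-substitution fixpoint", {
  # empty seed fixes only nodes whose rules are already constant
  net <- network_from_rules(c(A = "0", B = "A | C", C = "C"))
  res <- propagate_constants(net, integer(0))
  expect_equal(res$fixed, c(A = 0L))
  expect_setequal(names(res$residual_rules), c("B", "C"))

  # on literal/threshold rule families syntactic folding coincides with
  # semantic constancy, so the closure must match the semantic fixpoint
  for (seed in 1:15) {
    fam <- if (seed %% 2L) "literal" else "threshold"
    synth <- random_case(seed, n_min = 6L, n_max = 10L, n_inputs = 2L,
                         family = fam)
    net <- synth$network
    seeds <- synth$scenario$external
    if (length(seeds) == 0L)
      seeds <- stats::setNames(1L, synth$inputs[1])
    got <- propagate_constants(net, seeds)
    expect_true(got$feasible)
    expect_identical(got$fixed[order(names(got$fixed))],
                     ref_fixpoint(net, seeds)[order(names(ref_fixpoint(net, seeds)))])
    # conservation: residual + fixed = all nodes, disjointly
    expect_setequal(c(names(got$fixed), names(got$residual_rules)), net$nodes)
    expect_equal(anyDuplicated(c(names(got$fixed),
                                 names(got$residual_rules))), 0L)
  }
})

test_that("propagated values are sound: they hold in every matching attractor", {
  for (seed in c(4L, 11L, 23L, 35L)) {
    synth <- random_case(seed, n_min = 6L, n_max = 9L, n_inputs = 2L)
    net <- synth$network
    seeds <- stats::setNames(c(1L, 0L), synth$inputs[1:2])
    got <- propagate_constants(net, seeds, invert_literals = TRUE)
    if (!got$feasible) next
    oc <- brute_force_attractors(net)
    for (a in phenotype_filter(oc, seeds)) {
      for (n in names(got$fixed)) {
        expect_true(all(a$states[, n] == (got$fixed[[n]] == 1L)))
      }
    }
  }
})

test_that("clamping against a constant rule is reported as inconsistent", {
  net <- network_from_rules(c(A = "1", B = "A"))
  res <- propagate_constants(net, c(A = 0L))
  expect_false(res$feasible)
  expect_equal(res$conflict_node, "A")
})

test_that("phenotype rule inversion recovers the printed marker values", {
  # conjunction of literals: unique satisfying assignment
  conj <- network_from_rules(c(p70 = "p70", MYC = "MYC", p21 = "p21",
                               P = "p70 & MYC & !p21"))$rules$P
  asg <- invert_phenotype_rule(conj, 1L)
  expect_length(asg, 1L)
  expect_equal(asg[[1]][c("p70", "MYC", "p21")],
               c(p70 = 1L, MYC = 1L, p21 = 0L))

  # nested negated disjunction with one input already fixed
  cacc <- network_from_rules(c(
    FOS = "FOS", CYCLIND1 = "CYCLIND1", P21 = "P21", CASP3 = "CASP3",
    P = "(FOS & CYCLIND1) & !(P21 | CASP3)"))$rules$P
  asg2 <- invert_phenotype_rule(cacc, 1L, fixed = c(FOS = 1L))
  expect_length(asg2, 1L)
  expect_equal(asg2[[1]][c("CYCLIND1", "P21", "CASP3")],
               c(CYCLIND1 = 1L, P21 = 0L, CASP3 = 0L))

  # threshold body: sgn(Caspase9) = 1 iff Caspase9 = 1
  net <- mini_scp_network()
  asg3 <- invert_phenotype_rule(net$rules$Apoptosis, 1L,
                                fixed = c(Caspase8 = 0L))
  expect_length(asg3, 1L)
  expect_equal(asg3[[1]], c(Caspase9 = 1L))

  # non-conjunctive bodies branch over all satisfying assignments
  disj <- network_from_rules(c(a = "a", b = "b", P = "a | b"))$rules$P
  expect_length(invert_phenotype_rule(disj, 1L), 3L)
  expect_length(invert_phenotype_rule(disj, 0L), 1L)

  # unsatisfiable requirement yields the infeasible (empty) result
  expect_length(invert_phenotype_rule(conj, 1L, fixed = c(p21 = 1L)), 0L)
})

test_that("constraints are emitted for fixed nodes with unfolded rules", {
  # logic pair as in the proliferation derivation
  net <- network_from_rules(c(
    MAX = "MAX", AKT = "AKT", p53 = "p53",
    E1 = "MAX | AKT", E2 = "!AKT & p53"))
  cons <- derive_constraints(net, c(E1 = 1L, E2 = 0L))
  expect_length(cons, 2L)
  expect_equal(vapply(cons, format, character(1)),
               c("MAX | AKT = 1", "!AKT & p53 = 0"))

  # equation form 0 = f2(x5, x7) for a node fixed at 0
  net2 <- network_from_rules(c(x5 = "x5", x7 = "x7", x3 = "x5 & x7"))
  cons2 <- derive_constraints(net2, c(x3 = 0L))
  expect_equal(format(cons2[[1]]), "x5 & x7 = 0")
  expect_equal(cons2[[1]]$relation, "eq")

  # threshold rule fixed at 1 becomes a strict inequality
  cons3 <- derive_constraints(mini_scp_network(), c(`Cytoc/APAF1` = 1L))
  expect_equal(cons3[[1]]$relation, "gt0")
  expect_equal(format(cons3[[1]]), "0 < -AKT + p53 - BCL_2 - Bcl_XL")
})

test_that("the apoptosis chain pins the caspase markers and keeps the sign inequality", {
  net <- mini_scp_network()
  sm <- build_simplified_model(net, external = c(Caspase8 = 0L),
                               phenotype = "Apoptosis", value = 1L)
  expect_length(sm$branches, 1L)
  br <- sm$branches[[1]]
  expect_true(br$feasible)
  fx <- br$fixed_values
  # marker from the inverted sign rule, then backward through the single
  # positive literal Caspase9* = Cytoc/APAF1
  expect_equal(fx[["Caspase9"]], 1L)
  expect_equal(fx[["Cytoc/APAF1"]], 1L)
  expect_equal(unname(br$provenance["Cytoc/APAF1"]), "secondary-phenotype")
  # the threshold rule is not literal-decomposable: it stays as an
  # inequality over the residual regulators
  expect_length(br$constraints, 1L)
  expect_equal(format(br$constraints[[1]]), "0 < -AKT + p53 - BCL_2 - Bcl_XL")
  expect_setequal(names(br$residual_rules), c("AKT", "p53", "BCL_2", "Bcl_XL"))

  # end to end: the inequality admits exactly one residual assignment
  res <- find_phenotype_attractors(net, c(Caspase8 = 0L), "Apoptosis")
  expect_length(res$attractors, 1L)
  a <- res$attractors[[1]]
  expect_equal(a$period, 1L)
  st <- stats::setNames(as.integer(a$states[1, ]), a$nodes)
  expect_equal(st[c("AKT", "p53", "BCL_2", "Bcl_XL")],
               c(AKT = 0L, p53 = 1L, BCL_2 = 0L, Bcl_XL = 0L))
})

test_that("conflicting external and phenotype-derived values are diagnosed", {
  # the phenotype rule folds to the wrong constant under the clamp: the
  # inversion has no satisfying assignment, so there are no branches at all
  net <- network_from_rules(c(A = "A", B = "B", P = "A & B"))
  sm <- build_simplified_model(net, external = c(A = 0L), phenotype = "P")
  expect_length(sm$branches, 0L)
  res <- find_phenotype_attractors(net, c(A = 0L), "P")
  expect_length(res$attractors, 0L)
  expect_false(res$feasible)

  # a marker assignment whose sustaining rule contradicts another marker is
  # reported as an infeasible branch naming the node, not as an exception
  net2 <- network_from_rules(c(B = "!C", C = "C", P = "B & C"))
  sm2 <- build_simplified_model(net2, phenotype = "P")
  expect_length(sm2$branches, 1L)
  expect_false(sm2$branches[[1]]$feasible)
  expect_equal(sm2$branches[[1]]$conflict_node, "B")
  res2 <- find_phenotype_attractors(net2, phenotype = "P")
  expect_length(res2$attractors, 0L)
})

test_that("scenario files round-trip through YAML", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  sc <- list(external = c(ERK = 1L, DNA_damage = 0L),
             phenotype = "Proliferation", value = 1L)
  write_scenario(sc, tmp)
  back <- read_scenario(tmp)
  expect_equal(back$external, sc$external)
  expect_equal(back$phenotype, "Proliferation")
  expect_equal(back$value, 1L)
})
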