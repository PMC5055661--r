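test_that("branch extension unrolls both tables to the lcm of the periods", {
  b <- new_branch()
  scc1 <- list(id = "V1,1", members = c("x1", "x2"))
  la1 <- list(members = c("x1", "x2"), states = sstr(c("10", "01")),
              period = 2L)
  b <- extend_branch(b, scc1, list(la1))[[1]]
  expect_equal(b$period, 2L)

  scc2 <- list(id = "V2,1", members = c("x3", "x4"))
  la2 <- list(members = c("x3", "x4"),
              states = sstr(c("01", "00", "00", "10")), period = 4L)
  b <- extend_branch(b, scc2, list(la2))[[1]]
  # the old column repeats with period 2, the new with period 4
  expect_equal(b$period, 4L)
  expect_equal(as.integer(b$states[, "x1"]), c(1L, 0L, 1L, 0L))
  expect_equal(as.integer(b$states[, "x3"]), c(0L, 0L, 0L, 1L))

  # merging a point attractor leaves the period unchanged
  la3 <- list(members = "x5", states = sstr("1"), period = 1L)
  b3 <- extend_branch(b, list(id = "V3,1", members = "x5"), list(la3))[[1]]
  expect_equal(b3$period, 4L)
  expect_true(all(b3$states[, "x5"]))
})

test_that("row-wise concatenation over periods 2,4,6,1,1 has period 12", {
  g <- concatenate_attractor_table(worked_example_locals())
  expect_equal(g$period, 12L)  # lcm(2, 4, 6, 1, 1)
  expect_equal(ncol(g$states), 11L)
})

test_that("constraint filtering keeps exactly the satisfying branches", {
  # no constraints: everything passes
  b <- extend_branch(new_branch(), list(id = "V1,1", members = "x1"),
                     list(list(members = "x1", states = sstr("1"),
                               period = 1L)))
  expect_length(filter_by_constraints(b, list()), 1L)

  # derived point values satisfy the proliferation equations:
  # (p38, p53, GADD45, MTK1) = (0,0,0,0) gives PTEN* = 0, AKT* = 1,
  # MAX* = 0, hence MAX | AKT = 1 and !AKT & p53 = 0
  net <- network_from_rules(c(
    p38 = "p38", p53 = "p38", GADD45 = "GADD45", MTK1 = "MTK1",
    PTEN = "p53", AKT = "!PTEN", MAX = "p38"))
  point <- stats::setNames(rep(0L, 4), c("p38", "p53", "GADD45", "MTK1"))
  branch <- new_branch()
  for (m in c("PTEN", "AKT", "MAX")) {
    sig <- periodic_signal(cbind(branch$states,
                                 matrix(point == 1L, nrow = 1L,
                                        dimnames = list(NULL, names(point)))),
                           c(branch$nodes, names(point)))
    las <- driven_attractors(m, net$rules[m], sig)
    expect_length(las, 1L)
    branch <- extend_branch(branch, list(id = m, members = m), las)[[1]]
  }
  got <- stats::setNames(as.integer(branch$states[1, ]), branch$nodes)
  expect_equal(got[c("PTEN", "AKT", "MAX")], c(PTEN = 0L, AKT = 1L, MAX = 0L))
  cons <- derive_constraints(
    network_from_rules(c(MAX = "MAX", AKT = "AKT", p53 = "p53",
                         E1 = "MAX | AKT", E2 = "!AKT & p53")),
    c(E1 = 1L, E2 = 0L))
  full <- branch
  full$states <- cbind(full$states, p53 = rep(FALSE, nrow(full$states)))
  full$nodes <- c(full$nodes, "p53")
  expect_length(filter_by_constraints(list(full), cons), 1L)

  # a planted violated constraint prunes the branch
  bad <- derive_constraints(
    network_from_rules(c(AKT = "AKT", E3 = "!AKT")), c(E3 = 1L))
  expect_length(filter_by_constraints(list(full), bad), 0L)
})

test_that("HPFP enumeration reproduces the attractors of the residual network", {
  # layered fixture: rings in a planted hierarchy
  for (seed in 1:8) {
    spec <- generator_spec(seed = seed, phenotype = FALSE,
                           layers = list(2L, c(2L, 3L), 2L))
    net <- generate_network(spec)$network
    hp <- hpfp_partition(net$rules)
    branches <- enumerate_hpfp_attractors(hp, net$rules)
    got <- assemble_full_attractors(branches, integer(0), net)
    want <- brute_force_attractors(net)$attractors
    expect_equal(attractor_set_keys(got), attractor_set_keys(want))
  }
  # free random networks under the null scenario (no fixed nodes)
  for (seed in 1:15) {
    synth <- random_case(seed + 500L, n_min = 5L, n_max = 9L)
    net <- synth$network
    hp <- hpfp_partition(net$rules)
    branches <- enumerate_hpfp_attractors(hp, net$rules)
    got <- assemble_full_attractors(branches, integer(0), net)
    want <- brute_force_attractors(net)$attractors
    expect_equal(attractor_set_keys(got), attractor_set_keys(want))
  }
})

test_that("an empty residual network yields one empty branch of period 1", {
  hp <- hpfp_partition(list())
  branches <- enumerate_hpfp_attractors(hp, list())
  expect_length(branches, 1L)
  expect_equal(branches[[1]]$period, 1L)
  expect_length(branches[[1]]$nodes, 0L)

  # widening by the fixed values yields a single point attractor, as when
  # propagation fixes the entire network
  net <- network_from_rules(c(A = "1", B = "A"))
  atts <- assemble_full_attractors(branches, c(A = 1L, B = 1L), net)
  expect_length(atts, 1L)
  expect_equal(atts[[1]]$period, 1L)

  # zero branches produce the empty attractor list
  expect_length(assemble_full_attractors(list(), c(A = 1L, B = 1L), net), 0L)
})

test_that("verification accepts emitted cycles and rejects corrupted ones", {
  net <- network_from_rules(c(x1 = "x2", x2 = "x1", x3 = "x1 & x2"))
  oc <- brute_force_attractors(net)
  cyc <- Filter(function(a) a$period == 2L, oc$attractors)[[1]]
  expect_true(isTRUE(verify_global(cyc, net)))

  corrupted <- cyc
  corrupted$states[1, "x3"] <- !corrupted$states[1, "x3"]
  bad <- verify_global(corrupted, net)
  expect_false(isTRUE(bad))
  expect_true(attr(bad, "fail_at") >= 1L)

  # a duplicated cycle is rejected for non-minimal period
  doubled <- as_attractor(cyc$states[c(1, 2, 1, 2), ], cyc$nodes,
                          canonicalize = FALSE)
  nonmin <- verify_global(doubled, net)
  expect_false(isTRUE(nonmin))
  expect_equal(attr(nonmin, "fail_at"), 0L)
})

test_that("pipeline output equals the phenotype-filtered brute force (sweep)", {
  for (seed in 301:360) {
    synth <- random_case(seed, n_min = 5L, n_max = 10L)
    res <- find_phenotype_attractors(synth$network, synth$scenario$external,
                                     synth$scenario$phenotype,
                                     synth$scenario$value)
    want <- expected_phenotype_attractors(synth)
    expect_equal(attractor_set_keys(res$attractors),
                 unique(attractor_set_keys(want)),
                 info = paste("seed", seed))
  }
})
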