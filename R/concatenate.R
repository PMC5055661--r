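# --- Steps 4-2 and 5: concatenation into global attractors -----------------

# Unroll two periodic tables to their common period (lcm) and bind columns.
# Row i of each table is the state at time i-1 on the shared clock.
merge_periodic <- function(a, b) {
  P <- lcm2(max(1L, nrow(a)), max(1L, nrow(b)))
  ia <- ((seq_len(P) - 1L) %% nrow(a)) + 1L
  ib <- ((seq_len(P) - 1L) %% nrow(b)) + 1L
  cbind(a[ia, , drop = FALSE], b[ib, , drop = FALSE])
}

#' Start an empty concatenation branch
#'
#' The seed of the sequential concatenation: no resolved nodes, a single
#' row (period 1) on the shared clock.
#'
#' @return a branch state of class `bn_branch`
#' @export
new_branch <- function() {
  structure(list(nodes = character(0),
                 states = matrix(logical(0), nrow = 1L, ncol = 0L,
                                 dimnames = list(NULL, character(0))),
                 period = 1L, choices = character(0)),
            class = "bn_branch")
}

#' Extend a concatenation branch by the local attractors of one SCC
#'
#' Produces one successor branch per local attractor. Both the existing
#' joint trajectory (period P) and the chosen local attractor (product
#' period q, phase-anchored at 0) are unrolled to lcm(P, q) rows — row i
#' holds every resolved component's state at time i — and bound together.
#' For SCCs driven by the branch itself q is a multiple of P, so the new
#' period is q.
#'
#' @param branch a branch state (from [new_branch()] or a previous call)
#' @param scc the SCC record being resolved (needs `id`, `members`)
#' @param locals list of `bn_local_attractor` for this SCC, phase-aligned to
#'   the branch trajectory
#' @return list of successor branches
#' @export
extend_branch <- function(branch, scc, locals) {
  lapply(locals, function(la) {
    st <- merge_periodic(branch$states, la$states)
    colnames(st) <- c(branch$nodes, la$members)
    structure(list(nodes = c(branch$nodes, la$members),
                   states = st, period = nrow(st),
                   choices = c(branch$choices,
                               sprintf("%s:p%d", scc$id, la$period))),
              class = "bn_branch")
  })
}

# evaluate a constraint on every row of a trajectory matrix
constraint_holds <- function(constraint, states) {
  env <- vector("list", ncol(states))
  names(env) <- colnames(states)
  for (j in seq_len(ncol(states))) env[[j]] <- states[, j]
  v <- eval(constraint$compiled, env)
  if (length(v) == 1L) v <- rep(v, nrow(states))
  all(as.integer(v) == constraint$value)
}

#' Keep only branches whose trajectory satisfies the constraints
#'
#' A constraint (equation or threshold inequality) must hold at every time
#' step of a candidate attractor: a node fixed in the attractor has a
#' constant value at all times, so its unfolded rule body must equal that
#' value at all times.
#'
#' @param branches list of branch states
#' @param constraints list of `bn_constraint` whose referenced nodes are all
#'   resolved in every branch
#' @return the surviving branches
#' @export
filter_by_constraints <- function(branches, constraints) {
  if (length(constraints) == 0L) return(branches)
  for (con in constraints) {
    unresolved <- if (length(branches))
      setdiff(expr_vars(con$body), branches[[1L]]$nodes) else character(0)
    if (length(unresolved))
      stop("internal error: constraint on node ", con$node,
           " references unresolved node(s): ",
           paste(unresolved, collapse = ", "))
  }
  Filter(function(b) all(vapply(constraints, constraint_holds, logical(1),
                                states = b$states)),
         branches)
}

#' Enumerate all global attractors of the HPFP
#'
#' Depth-first product over categories in order (and SCCs within a
#' category): each SCC is driven by the current branch trajectory restricted
#' to its input nodes, its local attractors are enumerated exhaustively, and
#' every choice extends the branch. Constraints are checked as soon as all
#' of their nodes are resolved (early pruning; later SCCs never feed
#' earlier-resolved nodes, so this cannot change the final set). An empty
#' residual network yields one empty branch of period 1.
#'
#' @param hpfp a `bn_hpfp`
#' @param rules the residual rules backing the HPFP
#' @param constraints list of `bn_constraint` (over residual nodes)
#' @param cap exhaustive-search cap on SCC size
#' @param max_branches abort if the number of open branches exceeds this
#' @param all_phases paranoid phase mode, passed to [driven_attractors()]
#' @return list of completed branches (each covering all residual nodes)
#' @export
enumerate_hpfp_attractors <- function(hpfp, rules, constraints = list(),
                                      cap = 20L, max_branches = 10000L,
                                      all_phases = FALSE) {
  branches <- list(new_branch())
  checked <- rep(FALSE, length(constraints))
  for (scc in hpfp_sccs(hpfp)) {
    nxt <- list()
    for (b in branches) {
      sig <- periodic_signal(b$states[, scc$inputs, drop = FALSE],
                             nodes = scc$inputs)
      las <- driven_attractors(scc$members, rules, sig, cap = cap,
                               all_phases = all_phases)
      nxt <- c(nxt, extend_branch(b, scc, las))
    }
    branches <- nxt
    if (length(branches) > max_branches)
      stop("more than ", max_branches,
           " open branches while concatenating local attractors; ",
           "raise `max_branches`")
    if (length(branches) == 0L) break
    resolved <- branches[[1L]]$nodes
    for (ci in which(!checked)) {
      if (all(expr_vars(constraints[[ci]]$body) %in% resolved)) {
        branches <- filter_by_constraints(branches, constraints[ci])
        checked[ci] <- TRUE
        if (length(branches) == 0L) break
      }
    }
    if (length(branches) == 0L) break
  }
  if (length(branches) && any(!checked))
    branches <- filter_by_constraints(branches, constraints[!checked])
  branches
}

#' Widen HPFP branches to full-network attractors
#'
#' Each branch trajectory is widened to all original nodes by inserting the
#' fixed constant columns (constants have period 1, so the period is
#' unchanged), the period is then minimised, the cycle canonicalized, and
#' duplicates across branches dropped. Every emitted attractor is verified
#' under the original update rules; a verification failure is a pipeline
#' bug and raises an error.
#'
#' @param branches completed branches from [enumerate_hpfp_attractors()]
#' @param fixed named 0/1 vector of all fixed node values
#' @param network the original `boolean_network`
#' @param verify verify each attractor against the original rules
#' @return list of `bn_attractor` over the full node set
#' @export
assemble_full_attractors <- function(branches, fixed, network, verify = TRUE) {
  out <- list()
  seen <- character(0)
  for (b in branches) {
    leftover <- setdiff(network$nodes, c(b$nodes, names(fixed)))
    if (length(leftover))
      stop("internal error: nodes neither fixed nor resolved: ",
           paste(leftover, collapse = ", "))
    full <- matrix(FALSE, nrow = b$period, ncol = length(network$nodes),
                   dimnames = list(NULL, network$nodes))
    for (n in names(fixed)) full[, n] <- fixed[[n]] == 1L
    for (n in b$nodes) full[, n] <- b$states[, n]
    att <- as_attractor(full, network$nodes, canonicalize = TRUE)
    key <- attractor_key(att)
    if (key %in% seen) next
    seen <- c(seen, key)
    if (verify) {
      ok <- verify_global(att, network)
      if (!isTRUE(ok))
        stop("internal error: assembled attractor fails verification at ",
             "time index ", attr(ok, "fail_at"))
    }
    out[[length(out) + 1L]] <- att
  }
  out
}

#' Find all attractors of a network that realise a phenotype
#'
#' The complete pipeline: fix the environment (external condition), fix the
#' phenotype marker values (phenotype condition, one branch per satisfying
#' marker assignment), hierarchically partition the residual network into
#' SCC categories, exhaustively enumerate each SCC's local attractors under
#' the periodic drive of upstream components, concatenate them subject to
#' the residual constraints, re-attach the fixed values, and verify every
#' resulting cycle under the original update rules.
#'
#' @param network a `boolean_network`
#' @param external named 0/1 vector clamping the environment nodes
#' @param phenotype name of the phenotype node
#' @param value required phenotype value (default 1)
#' @param cap exhaustive-search cap on SCC size (default 20)
#' @param max_branches cap on open concatenation branches
#' @param all_phases paranoid phase mode for local-attractor search
#' @param verify verify every emitted attractor against the original rules
#' @return object of class `phenotype_attractors`: list with `attractors`
#'   (list of `bn_attractor`, deduplicated across phenotype branches),
#'   `simplified` (the `bn_simplified_set`), `hpfp` (per feasible branch),
#'   `summary` (Table-style counts), `feasible`
#' @export
#' @examples
#' net <- network_from_rules(c(
#'   p70 = "p70", MYC = "MYC", p21 = "p21",
#'   Proliferation = "p70 & MYC & !p21"))
#' res <- find_phenotype_attractors(net, phenotype = "Proliferation")
#' res$attractors
find_phenotype_attractors <- function(network, external = integer(0),
                                      phenotype, value = 1L,
                                      cap = 20L, max_branches = 10000L,
                                      all_phases = FALSE, verify = TRUE) {
  sm <- build_simplified_model(network, external, phenotype, value)
  atts <- list()
  hpfps <- list()
  branch_counts <- integer(0)
  for (i in seq_along(sm$branches)) {
    br <- sm$branches[[i]]
    if (!br$feasible) {
      hpfps[i] <- list(NULL)
      branch_counts[i] <- 0L
      next
    }
    hp <- hpfp_partition(br$residual_rules)
    hpfps[[i]] <- hp
    bs <- enumerate_hpfp_attractors(hp, br$residual_rules, br$constraints,
                                    cap = cap, max_branches = max_branches,
                                    all_phases = all_phases)
    branch_counts[i] <- length(bs)
    atts <- c(atts, assemble_full_attractors(bs, br$fixed_values, network,
                                             verify = verify))
  }
  # de-duplicate across phenotype branches, deterministic order
  keys <- vapply(atts, attractor_key, character(1))
  atts <- atts[!duplicated(keys)]
  atts <- atts[order(vapply(atts, attractor_key, character(1)))]
  feas <- vapply(sm$branches, function(b) b$feasible, logical(1))
  # original-network SCC size for the summary table
  full_sccs <- strongly_connected_components(dependency_graph(network$rules))
  summary <- list(
    n_nodes = length(network$nodes),
    max_scc_original = if (length(full_sccs)) max(lengths(full_sccs)) else 0L,
    n_external_phenotype = length(external) +
      length(unique(c(phenotype,
                      unlist(lapply(sm$branches,
                                    function(b) names(b$marker_assignment)))))),
    branches = length(sm$branches),
    feasible_branches = sum(feas),
    hpfp = lapply(hpfps, function(h) if (is.null(h)) NULL else hpfp_summary(h)),
    n_attractors = length(atts))
  structure(list(attractors = atts, simplified = sm, hpfp = hpfps,
                 summary = summary, feasible = any(feas)),
            class = "phenotype_attractors")
}

#' @export
print.phenotype_attractors <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Phenotype attractor search: %s = %d\n",
              x$simplified$phenotype, x$simplified$value))
  cat(sprintf("  original network: %d nodes, largest SCC %d\n",
              s$n_nodes, s$max_scc_original))
  cat(sprintf("  marker-assignment branches: %d (%d feasible)\n",
              s$branches, s$feasible_branches))
  for (i in seq_along(x$hpfp)) {
    h <- x$summary$hpfp[[i]]
    if (is.null(h)) next
    cat(sprintf("  branch %d HPFP: %d categories, %d SCCs, max SCC size %d\n",
                i, h$n_categories, h$n_sccs, h$max_scc_size))
  }
  if (length(x$attractors) == 0L) {
    cat("  no global attractor realises the phenotype\n")
  } else {
    cat(sprintf("  %d global attractor(s):\n", length(x$attractors)))
    for (a in x$attractors)
      cat(sprintf("    period %d: %s\n", a$period, format(a)))
  }
  invisible(x)
}

#' Concatenate already-known local attractors on a shared clock
#'
#' Table-based concatenation: given the local attractors of the SCCs of an
#' HPFP (each as a cyclic state sequence, phase-aligned at time 0), unroll
#' each column set to the least common multiple of the periods and bind the
#' rows into a single global trajectory — row i of the table is the state of
#' every component at time i. The returned attractor's period is the lcm,
#' reduced if the combined sequence repeats earlier.
#'
#' @param locals list of local attractors: each either a
#'   `bn_local_attractor` or a list with `members` and `states`
#' @return a `bn_attractor` over the union of the members (period minimised,
#'   canonical rotation NOT applied so that row 1 remains time 0)
#' @export
concatenate_attractor_table <- function(locals) {
  states <- matrix(logical(0), nrow = 1L, ncol = 0L)
  nodes <- character(0)
  for (la in locals) {
    m <- la$states
    mode(m) <- "logical"
    if (is.null(dim(m))) m <- matrix(m, ncol = length(la$members))
    states <- merge_periodic(states, m)
    nodes <- c(nodes, la$members)
  }
  colnames(states) <- nodes
  d <- minimal_period(states)
  as_attractor(states[seq_len(d), , drop = FALSE], nodes,
               canonicalize = FALSE)
}
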