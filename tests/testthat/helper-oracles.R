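# independent reference implementations used as oracles; these deliberately
# avoid the package's evaluation and search code paths

# arithmetic-style expression evaluator: and = x*y, or = x+y-xy, not = 1-x
ref_eval <- function(expr, values) {
  switch(expr$op,
    const = expr$value,
    var = as.integer(values[[expr$name]]),
    not = 1L - ref_eval(expr$x, values),
    and = ref_eval(expr$lhs, values) * ref_eval(expr$rhs, values),
    or = {
      a <- ref_eval(expr$lhs, values); b <- ref_eval(expr$rhs, values)
      a + b - a * b
    },
    thr = {
      s <- expr$offset
      for (n in names(expr$coef)) s <- s + expr$coef[[n]] * as.integer(values[[n]])
      as.integer(s > 0L)
    })
}

# all 0/1 assignments over `vars` as a list of named vectors
all_assignments <- function(vars) {
  k <- length(vars)
  if (k == 0L) return(list(stats::setNames(integer(0), character(0))))
  lapply(0:(2^k - 1L), function(i)
    stats::setNames(as.integer(bitwAnd(i, bitwShiftL(1L, seq_len(k) - 1L)) > 0L),
                    vars))
}

# semantic constant-propagation fixpoint: a node is fixed when its rule
# evaluates identically over every completion of the unknown inputs (for
# rules built from distinct literals or unit-weight sums this coincides
# with syntactic constant folding)
ref_fixpoint <- function(net, seed) {
  fixed <- vapply(seed, as.integer, integer(1))
  repeat {
    changed <- FALSE
    for (n in setdiff(net$nodes, names(fixed))) {
      vars <- expr_vars(net$rules[[n]])
      free <- setdiff(vars, names(fixed))
      if (length(free) > 12L) next
      vals <- vapply(all_assignments(free), function(a)
        ref_eval(net$rules[[n]], c(as.list(fixed), as.list(a))), integer(1))
      if (length(unique(vals)) == 1L) {
        fixed[n] <- vals[1L]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fixed
}

# reachability-based SCC oracle: u,v share an SCC iff u ~> v and v ~> u
ref_sccs <- function(g) {
  n <- length(g$vertices)
  reach <- diag(TRUE, n)
  dimnames(reach) <- list(g$vertices, g$vertices)
  if (nrow(g$edges)) for (i in seq_len(nrow(g$edges)))
    reach[g$edges[i, "from"], g$edges[i, "to"]] <- TRUE
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach > 0)) break
    reach <- nxt
  }
  both <- reach & t(reach)
  groups <- unique(apply(both, 1, function(r) paste(which(r), collapse = ",")))
  comps <- lapply(groups, function(gr)
    g$vertices[as.integer(strsplit(gr, ",")[[1]])])
  comps[order(vapply(comps, function(m) match(m[1], g$vertices), integer(1)))]
}

# longest source-to-SCC path layering by exhaustive path enumeration over
# the condensation (vertices = SCC indices, edges = integer pairs)
ref_layering <- function(n_scc, edges) {
  preds <- lapply(seq_len(n_scc), function(v)
    if (nrow(edges)) edges[edges[, 2] == v, 1] else integer(0))
  longest <- function(v) {
    p <- preds[[v]]
    if (length(p) == 0L) return(1L)
    1L + max(vapply(p, longest, integer(1)))
  }
  vapply(seq_len(n_scc), longest, integer(1))
}

# product-space brute force for a driven SCC: enumerate every
# (phase, state) pair, walk to convergence, extract the cycle, and report
# each distinct cycle's member-state sequence in canonical cyclic form
ref_driven_cycles <- function(members, rules, signal) {
  P <- signal$period
  k <- length(members)
  step1 <- function(t, sbits) {
    vals <- c(as.list(stats::setNames(as.integer(sbits), members)),
              as.list(stats::setNames(
                as.integer(signal$states[t + 1L, , drop = TRUE]),
                signal$nodes)))
    vapply(members, function(m) ref_eval(rules[[m]], vals), integer(1))
  }
  canon <- function(mat) {
    p <- nrow(mat)
    strs <- apply(mat, 1, function(r) paste0(as.integer(r), collapse = ""))
    # minimal period, then minimal rotation
    for (d in seq_len(p)) {
      if (p %% d == 0L && all(strs == strs[((seq_len(p) - 1L) %% d) + 1L])) {
        strs <- strs[seq_len(d)]; p <- d; break
      }
    }
    rots <- vapply(seq_len(p), function(r)
      paste(strs[((seq_len(p) + r - 2L) %% p) + 1L], collapse = ","),
      character(1))
    min(rots)
  }
  keys <- character(0)
  seen_states <- character(0)
  for (t0 in 0:(P - 1L)) for (s0 in 0:(2^k - 1L)) {
    t <- t0
    sbits <- as.integer(bitwAnd(s0, bitwShiftL(1L, seq_len(k) - 1L)) > 0L)
    trace <- character(0)
    states <- list()
    repeat {
      key <- paste(t, paste(sbits, collapse = ""))
      hit <- match(key, trace)
      if (!is.na(hit)) {
        cyc <- do.call(rbind, states[hit:length(states)])
        ck <- canon(matrix(cyc, ncol = k))
        anchor <- trace[hit]
        if (!(anchor %in% seen_states)) {
          seen_states <- c(seen_states, trace[hit:length(trace)])
          keys <- c(keys, ck)
        }
        break
      }
      trace <- c(trace, key)
      states[[length(states) + 1L]] <- sbits
      sbits <- step1(t, sbits)
      t <- (t + 1L) %% P
    }
  }
  sort(keys)
}

# canonical member-coordinate keys of driven_attractors output, for
# comparison with ref_driven_cycles
local_attractor_keys <- function(las) {
  sort(vapply(las, function(a) {
    st <- a$states
    p <- nrow(st)
    strs <- apply(st, 1, function(r) paste0(as.integer(r), collapse = ""))
    for (d in seq_len(p)) {
      if (p %% d == 0L && all(strs == strs[((seq_len(p) - 1L) %% d) + 1L])) {
        strs <- strs[seq_len(d)]; p <- d; break
      }
    }
    rots <- vapply(seq_len(p), function(r)
      paste(strs[((seq_len(p) + r - 2L) %% p) + 1L], collapse = ","),
      character(1))
    min(rots)
  }, character(1)))
}
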