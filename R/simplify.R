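# --- Step 1 / Step 2: external and phenotype conditions ---------------------
#
# Fixed-value bookkeeping: a named integer 0/1 vector `fixed` plus a parallel
# named character vector of provenance tags ("external", "secondary-external",
# "phenotype", "secondary-phenotype"). A node carries at most one fixed
# value; a conflict is reported as an infeasibility, never silently
# overwritten.

#' Substitute fixed values into an expression and fold constants
#'
#' Applies the listed folding identities only (`0&e -> 0`, `1&e -> e`,
#' `1|e -> 1`, `0|e -> e`, `!!e -> e`, `!0 -> 1`, `!1 -> 0`); no further
#' logic minimisation is attempted, which keeps the residual rules
#' auditable. For threshold bodies, fixed terms are folded into the offset;
#' if the achievable sum can no longer change the sign test for any
#' assignment of the remaining inputs, the body folds to a constant.
#'
#' @param expr a rule expression
#' @param fixed named 0/1 vector of fixed node values
#' @return the folded expression; a `const` node when fully determined. The
#'   result references only non-fixed nodes.
#' @export
partial_evaluate <- function(expr, fixed) {
  switch(expr$op,
    const = expr,
    var = {
      if (expr$name %in% names(fixed)) bn_const(fixed[[expr$name]]) else expr
    },
    not = {
      x <- partial_evaluate(expr$x, fixed)
      if (is_const(x)) return(bn_const(1L - x$value))
      if (x$op == "not") return(x$x)
      bn_not(x)
    },
    and = {
      l <- partial_evaluate(expr$lhs, fixed)
      if (is_const(l) && l$value == 0L) return(bn_const(0L))
      r <- partial_evaluate(expr$rhs, fixed)
      if (is_const(r) && r$value == 0L) return(bn_const(0L))
      if (is_const(l)) return(r)   # l == 1
      if (is_const(r)) return(l)   # r == 1
      bn_and(l, r)
    },
    or = {
      l <- partial_evaluate(expr$lhs, fixed)
      if (is_const(l) && l$value == 1L) return(bn_const(1L))
      r <- partial_evaluate(expr$rhs, fixed)
      if (is_const(r) && r$value == 1L) return(bn_const(1L))
      if (is_const(l)) return(r)   # l == 0
      if (is_const(r)) return(l)   # r == 0
      bn_or(l, r)
    },
    thr = {
      coef <- expr$coef
      offset <- expr$offset
      hit <- intersect(names(coef), names(fixed))
      for (n in hit) offset <- offset + coef[[n]] * fixed[[n]]
      coef <- coef[setdiff(names(coef), hit)]
      coef <- coef[coef != 0L]
      if (length(coef) == 0L) return(bn_const(as.integer(offset > 0L)))
      minsum <- offset + sum(pmin(coef, 0L))
      maxsum <- offset + sum(pmax(coef, 0L))
      if (minsum > 0L) return(bn_const(1L))
      if (maxsum <= 0L) return(bn_const(0L))
      bn_thr(coef, offset)
    },
    stop("unknown expression op: ", expr$op)
  )
}

# If requiring `expr == value` forces a unique assignment through
# literal-decomposable structure, return it. Decomposable cases: a literal
# (`x`, `!x`, nested negations), a conjunction required to be 1, a
# disjunction required to be 0, and negation (which flips the requirement).
# Returns list(status = "forced"|"free"|"infeasible", fix = named 0/1).
forced_assignment <- function(expr, value) {
  merge_fix <- function(a, b) {
    if (is.null(a) || is.null(b)) return(NULL)
    both <- intersect(names(a), names(b))
    if (any(a[both] != b[both])) return(NA)  # contradiction
    c(a, b[setdiff(names(b), both)])
  }
  rec <- function(e, v) {
    switch(e$op,
      const = if (e$value == v) integer(0) else NA,
      var = stats::setNames(as.integer(v), e$name),
      not = rec(e$x, 1L - v),
      and = if (v == 1L) merge_fix(rec(e$lhs, 1L), rec(e$rhs, 1L)) else NULL,
      or = if (v == 0L) merge_fix(rec(e$lhs, 0L), rec(e$rhs, 0L)) else NULL,
      thr = NULL,
      stop("unknown expression op: ", e$op)
    )
  }
  fx <- rec(expr, as.integer(value))
  if (is.null(fx)) return(list(status = "free"))
  if (length(fx) == 1L && is.na(fx)) return(list(status = "infeasible"))
  list(status = "forced", fix = fx)
}

#' Propagate fixed values through the update rules to a fixpoint
#'
#' Substitutes the current fixed set into every remaining rule; any rule
#' whose body folds to a constant fixes its target (tagged with
#' `secondary_tag`). When `invert_literals = TRUE` (the phenotype stage),
#' a fixed node whose substituted rule body is literal-decomposable also
#' fixes its inputs: a node held constant in an attractor must have its rule
#' body equal that constant at every time step, so a single-literal body (or
#' a conjunction required to be 1 / disjunction required to be 0) pins the
#' referenced nodes. Iterates until no rule folds; the fixed set only grows,
#' so the loop terminates in at most `|nodes|` rounds.
#'
#' @param network a `boolean_network`
#' @param seed named 0/1 vector of already-fixed values
#' @param seed_provenance provenance tag(s) for the seed nodes
#' @param secondary_tag provenance tag for newly derived values
#' @param invert_literals also fix inputs of literal-decomposable bodies
#' @return list with `feasible`; when feasible: `fixed` (named 0/1 vector),
#'   `provenance` (named character), `residual_rules` (fully substituted
#'   rules for the non-fixed nodes); when infeasible: `conflict_node`
#' @export
propagate_constants <- function(network, seed,
                                seed_provenance = "external",
                                secondary_tag = "secondary-external",
                                invert_literals = FALSE) {
  rules <- network$rules
  nodes <- network$nodes
  bad <- setdiff(names(seed), nodes)
  if (length(bad))
    stop("seed names not in network: ", paste(bad, collapse = ", "))
  fixed <- vapply(seed, as.integer, integer(1))
  prov <- stats::setNames(rep_len(seed_provenance, length(fixed)), names(fixed))

  add_fixed <- function(n, v, tag) {
    if (n %in% names(fixed)) {
      if (fixed[[n]] != v) return(n)  # conflict
      return(NULL)
    }
    fixed[n] <<- as.integer(v)
    prov[n] <<- tag
    NULL
  }

  repeat {
    changed <- FALSE
    # forward: rules that fold to constants fix their targets
    for (n in setdiff(nodes, names(fixed))) {
      b <- partial_evaluate(rules[[n]], fixed)
      if (is_const(b)) {
        conflict <- add_fixed(n, b$value, secondary_tag)
        if (!is.null(conflict))
          return(list(feasible = FALSE, conflict_node = conflict,
                      fixed = fixed, provenance = prov))
        changed <- TRUE
      }
    }
    # consistency of fixed nodes with their own rules; optionally backward
    for (n in intersect(nodes, names(fixed))) {
      b <- partial_evaluate(rules[[n]], fixed)
      if (is_const(b)) {
        if (b$value != fixed[[n]])
          return(list(feasible = FALSE, conflict_node = n,
                      fixed = fixed, provenance = prov))
      } else if (invert_literals) {
        fa <- forced_assignment(b, fixed[[n]])
        if (fa$status == "infeasible")
          return(list(feasible = FALSE, conflict_node = n,
                      fixed = fixed, provenance = prov))
        if (fa$status == "forced" && length(fa$fix)) {
          for (m in names(fa$fix)) {
            new_node <- !(m %in% names(fixed))
            conflict <- add_fixed(m, fa$fix[[m]], secondary_tag)
            if (!is.null(conflict))
              return(list(feasible = FALSE, conflict_node = conflict,
                          fixed = fixed, provenance = prov))
            if (new_node) changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  residual <- setdiff(nodes, names(fixed))
  residual_rules <- lapply(stats::setNames(residual, residual),
                           function(n) partial_evaluate(rules[[n]], fixed))
  list(feasible = TRUE, fixed = fixed, provenance = prov,
       residual_rules = residual_rules)
}

#' Invert a phenotype rule into marker-node assignments
#'
#' Enumerates every assignment of the residual inputs of the (substituted)
#' phenotype rule body that makes it equal the required value. For the
#' common case of a conjunction of literals there is exactly one; each
#' assignment seeds one independent phenotype branch.
#'
#' @param rule the phenotype node's rule expression
#' @param required required phenotype value (0 or 1)
#' @param fixed named 0/1 vector of values already fixed (substituted first)
#' @param max_vars refuse to enumerate bodies with more residual inputs
#' @return list of named 0/1 vectors (possibly empty = phenotype infeasible;
#'   a single empty vector when the body is already constant at `required`)
#' @export
invert_phenotype_rule <- function(rule, required, fixed = integer(0),
                                  max_vars = 16L) {
  b <- partial_evaluate(rule, fixed)
  required <- as.integer(required)
  if (is_const(b)) {
    return(if (b$value == required) list(stats::setNames(integer(0), character(0)))
           else list())
  }
  vars <- expr_vars(b)
  if (length(vars) > max_vars)
    stop("phenotype rule references ", length(vars),
         " free inputs; refusing to enumerate more than ", max_vars)
  m <- decode_states(0:(2^length(vars) - 1L), length(vars))
  keep <- vapply(seq_len(nrow(m)), function(i) {
    eval_expr(b, stats::setNames(as.list(as.integer(m[i, ])), vars)) == required
  }, logical(1))
  lapply(which(keep), function(i) stats::setNames(as.integer(m[i, ]), vars))
}

#' Derive the residual constraint equations/inequalities
#'
#' A node held at a constant value in the attractor whose own (substituted)
#' rule body still depends on residual nodes imposes that the body equals
#' the constant at every time step. For threshold bodies the relation is
#' strictly-positive iff the value is 1.
#'
#' @param network a `boolean_network`
#' @param fixed named 0/1 vector of all fixed values
#' @return list of constraints, each of class `bn_constraint` with fields
#'   `node`, `value`, `body` (expression over residual nodes only) and
#'   `relation` (`"eq"` for logic, `"gt0"`/`"le0"` for thresholds); and
#'   `feasible = FALSE` outcomes are reported via attribute `conflict_node`
#'   on an empty list (callers normally reach this only via
#'   [build_simplified_model()], which checks feasibility first)
#' @export
derive_constraints <- function(network, fixed) {
  out <- list()
  for (n in intersect(network$nodes, names(fixed))) {
    b <- partial_evaluate(network$rules[[n]], fixed)
    if (is_const(b)) {
      if (b$value != fixed[[n]]) {
        res <- list()
        attr(res, "conflict_node") <- n
        return(res)
      }
      next
    }
    relation <- if (b$op == "thr") {
      if (fixed[[n]] == 1L) "gt0" else "le0"
    } else "eq"
    out[[length(out) + 1L]] <- structure(
      list(node = n, value = fixed[[n]], body = b, relation = relation,
           compiled = expr_to_call(b)),
      class = "bn_constraint")
  }
  out
}

#' @export
format.bn_constraint <- function(x, ...) {
  if (x$relation == "eq")
    paste0(format_expr(x$body), " = ", x$value)
  else {
    inner <- sub("^sgn\\((.*)\\)$", "\\1", format_expr(x$body))
    if (x$relation == "gt0") paste0("0 < ", inner) else paste0(inner, " <= 0")
  }
}

#' @export
print.bn_constraint <- function(x, ...) {
  cat("Constraint on node ", x$node, ": ", format(x), "\n", sep = "")
  invisible(x)
}

#' Build the simplified model(s) for an environment and phenotype
#'
#' Runs the full simplification pipeline: forward propagation of the
#' external values (external condition), inversion of the phenotype rule
#' into marker assignments, and — per assignment branch — propagation of the
#' phenotype values (with literal inversion) followed by constraint
#' derivation (phenotype condition).
#'
#' @param network a `boolean_network`
#' @param external named 0/1 vector of clamped environment values
#' @param phenotype name of the phenotype node
#' @param value required phenotype value (default 1)
#' @param max_branches refuse to expand more marker assignments than this
#' @return object of class `bn_simplified_set`: list with `branches` (each a
#'   `bn_simplified` with `fixed` data frame (node, value, provenance),
#'   `fixed_values`, `residual_rules`, `constraints`, `feasible`,
#'   `conflict_node`), plus `phenotype`, `value`, `external`
#' @export
build_simplified_model <- function(network, external = integer(0),
                                   phenotype, value = 1L,
                                   max_branches = 64L) {
  stopifnot(phenotype %in% network$nodes)
  external <- vapply(external, as.integer, integer(1))
  s1 <- propagate_constants(network, external,
                            seed_provenance = "external",
                            secondary_tag = "secondary-external",
                            invert_literals = FALSE)
  mk_branch <- function(feasible, fixed = integer(0), prov = character(0),
                        residual = list(), constraints = list(),
                        conflict = NA_character_, assignment = integer(0)) {
    structure(list(
      feasible = feasible,
      fixed = data.frame(node = names(fixed),
                         value = as.integer(fixed),
                         provenance = unname(prov[names(fixed)]),
                         stringsAsFactors = FALSE),
      fixed_values = fixed,
      provenance = prov,
      residual_rules = residual,
      constraints = constraints,
      conflict_node = conflict,
      marker_assignment = assignment), class = "bn_simplified")
  }
  result <- structure(list(branches = list(), phenotype = phenotype,
                           value = as.integer(value), external = external),
                      class = "bn_simplified_set")
  if (!s1$feasible) {
    result$branches <- list(mk_branch(FALSE, s1$fixed, s1$provenance,
                                      conflict = s1$conflict_node))
    return(result)
  }
  assignments <- invert_phenotype_rule(network$rules[[phenotype]],
                                       value, s1$fixed)
  if (length(assignments) > max_branches)
    stop("phenotype rule admits ", length(assignments),
         " marker assignments; raise max_branches to expand them")
  branches <- list()
  for (asg in assignments) {
    fixed2 <- s1$fixed
    prov2 <- s1$provenance
    conflict <- NULL
    # the phenotype node itself is fixed and removed from the residual net
    seeds <- c(stats::setNames(as.integer(value), phenotype), asg)
    for (j in seq_along(seeds)) {
      n <- names(seeds)[j]
      v <- seeds[[j]]
      if (n %in% names(fixed2)) {
        if (fixed2[[n]] != v) { conflict <- n; break }
      } else {
        fixed2[n] <- v
        prov2[n] <- "phenotype"
      }
    }
    if (!is.null(conflict)) {
      branches[[length(branches) + 1L]] <-
        mk_branch(FALSE, fixed2, prov2, conflict = conflict, assignment = asg)
      next
    }
    s2 <- propagate_constants(network, fixed2,
                              seed_provenance = prov2[names(fixed2)],
                              secondary_tag = "secondary-phenotype",
                              invert_literals = TRUE)
    if (!s2$feasible) {
      branches[[length(branches) + 1L]] <-
        mk_branch(FALSE, s2$fixed, s2$provenance,
                  conflict = s2$conflict_node, assignment = asg)
      next
    }
    cons <- derive_constraints(network, s2$fixed)
    if (!is.null(attr(cons, "conflict_node"))) {
      branches[[length(branches) + 1L]] <-
        mk_branch(FALSE, s2$fixed, s2$provenance,
                  conflict = attr(cons, "conflict_node"), assignment = asg)
      next
    }
    branches[[length(branches) + 1L]] <-
      mk_branch(TRUE, s2$fixed, s2$provenance, s2$residual_rules, cons,
                assignment = asg)
  }
  result$branches <- branches
  result
}

#' @export
print.bn_simplified_set <- function(x, ...) {
  feas <- vapply(x$branches, function(b) b$feasible, logical(1))
  cat(sprintf("Simplified model for phenotype %s = %d: %d branch(es), %d feasible\n",
              x$phenotype, x$value, length(x$branches), sum(feas)))
  for (i in seq_along(x$branches)) {
    b <- x$branches[[i]]
    if (!b$feasible) {
      cat(sprintf("  branch %d: infeasible (conflict at %s)\n", i, b$conflict_node))
      next
    }
    cat(sprintf("  branch %d: %d fixed, %d residual, %d constraint(s)\n", i,
                nrow(b$fixed), length(b$residual_rules), length(b$constraints)))
  }
  invisible(x)
}

## ---- scenario files -------------------------------------------------------

#' Read a scenario configuration
#'
#' A scenario file is YAML with keys `external` (map of node to 0/1),
#' `phenotype` (node name) and `value` (required 0/1, default 1).
#'
#' @param file path to the YAML scenario file
#' @return list with `external` (named integer), `phenotype`, `value`
#' @export
read_scenario <- function(file) {
  y <- yaml::read_yaml(file)
  if (is.null(y$phenotype)) stop("scenario file must name a phenotype node")
  ext <- y$external %||% list()
  extv <- stats::setNames(vapply(ext, as.integer, integer(1)),
                          names(ext) %||% character(0))
  list(external = extv,
       phenotype = as.character(y$phenotype),
       value = as.integer(y$value %||% 1L))
}

#' Write a scenario configuration
#' @param scenario list as returned by [read_scenario()]
#' @param file output path
#' @return the path, invisibly
#' @export
write_scenario <- function(scenario, file) {
  yaml::write_yaml(list(external = as.list(scenario$external),
                        phenotype = scenario$phenotype,
                        value = as.integer(scenario$value %||% 1L)),
                   file)
  invisible(file)
}
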