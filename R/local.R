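# --- Step 4-1: local attractors of a driven SCC -----------------------------

#' Construct a periodic signal
#'
#' A periodic trajectory over a set of nodes: row `t+1` of `states` is the
#' value at time `t`, and the value at any time `t` is
#' `states[(t mod period) + 1, ]`. Periods are deliberately never minimised
#' mid-pipeline so that all components stay phase-aligned on a shared clock.
#'
#' @param states logical/0-1 matrix (rows = one full period of samples)
#' @param nodes node names (defaults to `colnames(states)`)
#' @return object of class `bn_signal` with `nodes`, `states`, `period`
#' @export
periodic_signal <- function(states, nodes = NULL) {
  if (is.null(dim(states))) states <- matrix(states, ncol = max(1L, length(nodes)))
  mode(states) <- "logical"
  if (!is.null(nodes)) colnames(states) <- nodes
  structure(list(nodes = colnames(states) %||% character(0),
                 states = states, period = nrow(states)),
            class = "bn_signal")
}

# the empty signal: period 1, no nodes
empty_signal <- function(period = 1L) {
  periodic_signal(matrix(logical(0), nrow = period, ncol = 0L),
                  nodes = character(0))
}

#' Project a periodic signal onto a subset of its nodes
#'
#' The period is kept equal to the joint period (not minimised) to preserve
#' the phase bookkeeping of the shared clock.
#'
#' @param signal a `bn_signal`
#' @param subset character vector of node names (must be carried by `signal`)
#' @return a `bn_signal` over `subset` with the same period
#' @export
restrict_trajectory <- function(signal, subset) {
  unknown <- setdiff(subset, signal$nodes)
  if (length(unknown))
    stop("signal does not carry node(s): ", paste(unknown, collapse = ", "))
  periodic_signal(signal$states[, subset, drop = FALSE], nodes = subset)
}

#' Exhaustively enumerate the attractors of a driven SCC
#'
#' The SCC is iterated in the product space (driver phase, SCC state): from
#' every initial SCC state at driver phase 0, the product map
#' `(t, s) -> (t+1, step(s | signal at t))` is followed until a
#' (phase, state) pair repeats, and the cycle is extracted. Every product
#' cycle passes through phase 0 (cycle lengths are multiples of the driver
#' period), so enumerating phase-0 starts finds all cycles; rotating the
#' driver cannot change the attractor set (see [phase_shift_check()]), and a
#' paranoid mode starting from every phase is available for testing.
#'
#' Reported periods are product-space periods (a point attractor of the SCC
#' under a period-p input has product period p); the returned cycles are
#' anchored so that row 1 is the SCC state at driver phase 0.
#'
#' @param members SCC member nodes (their order fixes the state layout)
#' @param rules named list of rule expressions for `members` (bodies may
#'   reference members and signal nodes only)
#' @param signal a `bn_signal` carrying at least the non-member inputs
#' @param cap refuse SCCs with more members than this (exhaustive search)
#' @param all_phases also start from every driver phase (paranoid mode)
#' @return list of local attractors, each of class `bn_local_attractor` with
#'   `members`, `states` (product-period rows), `period`, `phase_anchor = 0`
#' @export
driven_attractors <- function(members, rules, signal = NULL, cap = 20L,
                              all_phases = FALSE) {
  k <- length(members)
  if (k > cap)
    stop("SCC {", paste(members, collapse = ", "), "} has ", k,
         " nodes, above the exhaustive-search cap of ", cap,
         "; raise `cap` if the state space 2^", k, " is acceptable")
  if (is.null(signal)) signal <- empty_signal()
  P <- signal$period
  need <- setdiff(unique(unlist(lapply(rules[members], expr_vars),
                                use.names = FALSE)), members)
  missing <- setdiff(need, signal$nodes)
  if (length(missing))
    stop("driving signal does not carry input node(s): ",
         paste(missing, collapse = ", "))
  nstate <- bitwShiftL(1L, k)
  if (P * nstate > 2^26)
    stop("product space too large (driver period ", P, " x 2^", k, " states)")
  allm <- decode_states(0:(nstate - 1L), k)
  colnames(allm) <- members
  # next-state table per phase: ntab[t+1, s+1] = encoded successor state
  compiled <- lapply(rules[members], expr_to_call)
  ntab <- matrix(0L, nrow = P, ncol = nstate)
  env <- vector("list", k + length(signal$nodes))
  names(env) <- c(members, signal$nodes)
  for (j in seq_len(k)) env[[j]] <- allm[, j]
  for (t in seq_len(P)) {
    for (j in seq_along(signal$nodes))
      env[[k + j]] <- rep(signal$states[t, j], nstate)
    nxt <- matrix(FALSE, nstate, k)
    for (j in seq_len(k)) {
      v <- eval(compiled[[j]], env)
      if (length(v) == 1L) v <- rep(v, nstate)
      nxt[, j] <- v
    }
    ntab[t, ] <- encode_states(nxt)
  }
  # trace the product-space functional graph
  idx_of <- function(t, s) t * nstate + s + 1L  # t in 0..P-1, s in 0..nstate-1
  status <- integer(P * nstate)  # 0 = unseen, >0 = finished (cycle id or -1)
  cycles <- list()
  start_phases <- if (all_phases) 0:(P - 1L) else 0L
  for (t0 in start_phases) {
    for (s0 in 0:(nstate - 1L)) {
      if (status[idx_of(t0, s0)] != 0L) next
      path_t <- integer(0)
      path_s <- integer(0)
      pos <- new.env(parent = emptyenv())
      t <- t0; s <- s0
      repeat {
        id <- idx_of(t, s)
        st <- status[id]
        if (st != 0L) {
          # path drains into something already classified
          for (j in seq_along(path_t))
            status[idx_of(path_t[j], path_s[j])] <- st
          break
        }
        key <- as.character(id)
        p0 <- pos[[key]]
        if (!is.null(p0)) {
          # new cycle: path[p0 .. end]
          cyc_t <- path_t[p0:length(path_t)]
          cyc_s <- path_s[p0:length(path_s)]
          # rotate so the cycle starts at a phase-0 entry
          z <- which(cyc_t == 0L)[1L]
          ord <- c(z:length(cyc_t), if (z > 1L) 1:(z - 1L))
          cid <- length(cycles) + 1L
          cycles[[cid]] <- cyc_s[ord]
          for (j in seq_along(path_t))
            status[idx_of(path_t[j], path_s[j])] <- cid
          break
        }
        pos[[key]] <- length(path_t) + 1L
        path_t <- c(path_t, t)
        path_s <- c(path_s, s)
        s <- ntab[t + 1L, s + 1L]
        t <- (t + 1L) %% P
      }
    }
  }
  lapply(cycles, function(cyc) {
    structure(list(members = members,
                   states = allm[cyc + 1L, , drop = FALSE],
                   period = length(cyc),
                   phase_anchor = 0L),
              class = "bn_local_attractor")
  })
}

#' @export
print.bn_local_attractor <- function(x, ...) {
  cat(sprintf("Local attractor of {%s}: period %d\n",
              paste(x$members, collapse = ", "), x$period))
  cat("  [", paste(state_strings(x$states), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Check phase-shift invariance of a driven SCC
#'
#' Rotating the starting point of the driving signal (preserving its cyclic
#' order) must not change the set of local attractors, compared as cyclic
#' sequences on the SCC coordinates. Used as a test utility; the main
#' pipeline relies on this invariance to enumerate initial states at driver
#' phase 0 only.
#'
#' @inheritParams driven_attractors
#' @return `TRUE` iff the local-attractor set is identical under every
#'   rotation of the signal
#' @export
phase_shift_check <- function(members, rules, signal, cap = 20L) {
  canon_set <- function(las) {
    sort(vapply(las, function(a) {
      st <- canonical_rotation(a$states[seq_len(minimal_period(a$states)), ,
                                        drop = FALSE])
      paste(state_strings(st), collapse = ",")
    }, character(1)))
  }
  P <- signal$period
  ref <- NULL
  for (r in 0:(P - 1L)) {
    idx <- ((seq_len(P) + r - 1L) %% P) + 1L
    rot <- periodic_signal(signal$states[idx, , drop = FALSE],
                           nodes = signal$nodes)
    las <- driven_attractors(members, rules, rot, cap = cap)
    ks <- canon_set(las)
    if (is.null(ref)) ref <- ks
    else if (!identical(ref, ks)) return(FALSE)
  }
  TRUE
}
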