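# --- validation oracle: brute-force full-search -----------------------------

#' Brute-force attractor search over the full state space
#'
#' Trajectory tracing with memoization over all 2^N initial states. Only
#' feasible for small networks; used to validate the hierarchical pipeline.
#'
#' @param network a `boolean_network`
#' @param cap refuse networks with more nodes than this
#' @return object of class `bn_oracle`: list with `attractors` (canonical
#'   `bn_attractor` set), `basin_sizes` (states draining into each
#'   attractor; sums to 2^N) and `n_states`
#' @export
brute_force_attractors <- function(network, cap = 20L) {
  N <- length(network$nodes)
  if (N > cap)
    stop("network has ", N, " nodes, above the full-search cap of ", cap)
  n_states <- bitwShiftL(1L, N)
  states <- decode_states(0:(n_states - 1L), N)
  colnames(states) <- network$nodes
  succ <- encode_states(step_states(network, states)) + 1L
  attr_of <- integer(n_states)  # 0 = unknown, else attractor id
  cycles <- list()
  for (s0 in seq_len(n_states)) {
    if (attr_of[s0] != 0L) next
    path <- integer(0)
    seen_at <- new.env(parent = emptyenv())
    s <- s0
    repeat {
      a <- attr_of[s]
      if (a != 0L) {
        attr_of[path] <- a
        break
      }
      key <- as.character(s)
      p0 <- seen_at[[key]]
      if (!is.null(p0)) {
        cyc <- path[p0:length(path)]
        cid <- length(cycles) + 1L
        cycles[[cid]] <- cyc
        attr_of[path] <- cid
        break
      }
      seen_at[[key]] <- length(path) + 1L
      path <- c(path, s)
      s <- succ[s]
    }
  }
  attractors <- lapply(cycles, function(cyc)
    as_attractor(states[cyc, , drop = FALSE], network$nodes))
  structure(list(attractors = attractors,
                 basin_sizes = tabulate(attr_of, nbins = length(cycles)),
                 n_states = n_states),
            class = "bn_oracle")
}

#' @export
print.bn_oracle <- function(x, ...) {
  cat(sprintf("Full search: %d states, %d attractor(s)\n",
              x$n_states, length(x$attractors)))
  for (i in seq_along(x$attractors))
    cat(sprintf("  #%d (basin %d): %s\n", i, x$basin_sizes[i],
                format(x$attractors[[i]])))
  invisible(x)
}

#' Filter attractors by fixed node values
#'
#' Keeps the attractors in which every fixed node holds its fixed value in
#' every state.
#'
#' @param oracle a `bn_oracle` or a plain list of `bn_attractor`
#' @param fixed named 0/1 vector
#' @return list of `bn_attractor`
#' @export
phenotype_filter <- function(oracle, fixed) {
  atts <- if (inherits(oracle, "bn_oracle")) oracle$attractors else oracle
  if (length(fixed) == 0L) return(atts)
  Filter(function(a) {
    cols <- a$states[, names(fixed), drop = FALSE]
    all(cols == matrix(rep(fixed == 1L, each = nrow(cols)), nrow = nrow(cols)))
  }, atts)
}
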