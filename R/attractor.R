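# --- cyclic attractor container -------------------------------------------

# smallest d dividing nrow(states) such that the sequence repeats with
# period d
minimal_period <- function(states) {
  p <- nrow(states)
  keys <- state_strings(states)
  for (d in seq_len(p)) {
    if (p %% d != 0L) next
    if (all(keys == keys[((seq_len(p) - 1L) %% d) + 1L])) return(d)
  }
  p
}

# rotation whose concatenated bit-string is lexicographically minimal;
# states within one minimal period are pairwise distinct so ties cannot occur
canonical_rotation <- function(states) {
  p <- nrow(states)
  if (p <= 1L) return(states)
  keys <- vapply(seq_len(p), function(r) {
    idx <- ((seq_len(p) + r - 2L) %% p) + 1L
    paste(state_strings(states[idx, , drop = FALSE]), collapse = "")
  }, character(1))
  r <- which.min(keys)
  idx <- ((seq_len(p) + r - 2L) %% p) + 1L
  states[idx, , drop = FALSE]
}

#' Construct an attractor object
#'
#' An attractor is a cyclic sequence of network states; the synchronous step
#' maps state `i` to state `i + 1 (mod period)`. On construction the period
#' is minimised (in case the sequence was written down on a longer shared
#' clock) and the cycle is stored in canonical rotation, which makes set
#' comparison of attractors well defined.
#'
#' @param states logical/0-1 matrix, one row per time step, columns named by
#'   node
#' @param nodes optional node order (defaults to `colnames(states)`)
#' @param canonicalize minimise the period and rotate to canonical form
#' @return an object of class `bn_attractor` with elements `states`,
#'   `nodes`, `period`
#' @export
as_attractor <- function(states, nodes = NULL, canonicalize = TRUE) {
  if (is.null(dim(states))) states <- matrix(states, ncol = 1L)
  mode(states) <- "logical"
  rownames(states) <- NULL
  if (!is.null(nodes)) colnames(states) <- nodes
  if (canonicalize) {
    d <- minimal_period(states)
    states <- states[seq_len(d), , drop = FALSE]
    states <- canonical_rotation(states)
  }
  structure(list(states = states, nodes = colnames(states),
                 period = nrow(states)),
            class = "bn_attractor")
}

# identity key used for set comparison of attractors
attractor_key <- function(att) {
  paste(state_strings(att$states), collapse = ",")
}

attractor_set_keys <- function(atts) sort(vapply(atts, attractor_key, character(1)))

#' Verify an attractor against a network
#'
#' Checks that applying the network's synchronous update to each state yields
#' the next state of the cycle, and that the stored period is minimal.
#'
#' @param attractor a `bn_attractor` covering all nodes of `network`
#' @param network a `boolean_network`
#' @return `TRUE` or `FALSE`; on failure the attribute `fail_at` carries the
#'   first offending time index (1-based), or 0 for a non-minimal period
#' @export
verify_global <- function(attractor, network) {
  st <- attractor$states
  if (is.null(colnames(st)) || !setequal(colnames(st), network$nodes))
    stop("attractor states must cover all network nodes")
  st <- st[, network$nodes, drop = FALSE]
  p <- nrow(st)
  nxt <- step_states(network, st)
  want <- st[c(seq_len(p)[-1L], 1L), , drop = FALSE]
  bad <- which(rowSums(nxt != want) > 0L)
  if (length(bad)) {
    out <- FALSE
    attr(out, "fail_at") <- bad[1L]
    return(out)
  }
  if (minimal_period(st) != p) {
    out <- FALSE
    attr(out, "fail_at") <- 0L
    return(out)
  }
  TRUE
}

#' Write attractors as a table
#'
#' One row per time index with one column per node (declaration order), plus
#' the attractor id, period and time. The machine-readable JSON variant
#' emits records `{id, period, node_order, states}` with states as
#' bit-strings.
#'
#' @param attractors list of `bn_attractor`
#' @param file optional path (CSV); when `NULL` the data frame is returned
#' @param format `"csv"` or `"json"`
#' @return data frame (csv) or JSON string, invisibly when written
#' @export
write_attractors <- function(attractors, file = NULL, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    recs <- lapply(seq_along(attractors), function(i) {
      a <- attractors[[i]]
      list(id = i, period = a$period, node_order = a$nodes,
           states = state_strings(a$states))
    })
    txt <- jsonlite::toJSON(recs, auto_unbox = TRUE, pretty = TRUE)
    if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
    return(txt)
  }
  rows <- lapply(seq_along(attractors), function(i) {
    a <- attractors[[i]]
    df <- as.data.frame(a$states + 0L)
    names(df) <- a$nodes
    cbind(data.frame(attractor = i, period = a$period, t = seq_len(a$period) - 1L),
          df)
  })
  df <- do.call(rbind, rows)
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}

#' Read attractors from a CSV table written by [write_attractors()]
#' @param file path to the CSV file
#' @return list of `bn_attractor` (stored rotation preserved)
#' @export
read_attractors <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  stopifnot(all(c("attractor", "period", "t") %in% names(df)))
  nodes <- setdiff(names(df), c("attractor", "period", "t"))
  lapply(split(df, df$attractor), function(d) {
    d <- d[order(d$t), , drop = FALSE]
    as_attractor(as.matrix(d[, nodes, drop = FALSE]) > 0L, nodes,
                 canonicalize = FALSE)
  })
}

#' @export
print.bn_attractor <- function(x, ...) {
  kind <- if (x$period == 1L) "point" else "cyclic"
  cat(sprintf("Attractor (%s, period %d) over %d nodes\n",
              kind, x$period, length(x$nodes)))
  cat("  [", paste(state_strings(x$states), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' @export
format.bn_attractor <- function(x, ...) {
  paste0("[", paste(state_strings(x$states), collapse = ", "), "]")
}
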