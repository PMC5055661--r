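# --- Step 3: hierarchical partition for the phenotype (HPFP) ---------------

#' Dependency graph of a set of update rules
#'
#' One edge per (regulator, target) pair: an edge `u -> v` exists iff `v`'s
#' rule body references `u` (threshold rules contribute one edge per
#' nonzero-coefficient term). These are syntactic edges; they may strictly
#' contain the functionally effective edges.
#'
#' @param rules named list of rule expressions (e.g. the residual rules of a
#'   simplified model, or `network$rules`)
#' @return list with `vertices` (targets, in declaration order) and `edges`
#'   (two-column character matrix, from/to; zero rows when none)
#' @export
dependency_graph <- function(rules) {
  vertices <- names(rules)
  from <- character(0)
  to <- character(0)
  for (n in vertices) {
    regs <- expr_vars(rules[[n]])
    if (length(regs)) {
      from <- c(from, regs)
      to <- c(to, rep(n, length(regs)))
    }
  }
  edges <- unique(cbind(from = from, to = to))
  bad <- setdiff(edges[, "from"], vertices)
  if (length(bad))
    stop("rule inputs reference nodes without rules: ",
         paste(bad, collapse = ", "))
  list(vertices = vertices, edges = edges)
}

#' Strongly connected components of a digraph
#'
#' @param g a digraph as returned by [dependency_graph()]
#' @return list of character vectors (the member sets), ordered by the
#'   smallest declaration index of a member; members within a component are
#'   in declaration order
#' @export
strongly_connected_components <- function(g) {
  if (length(g$vertices) == 0L) return(list())
  ig <- igraph::graph_from_data_frame(
    d = as.data.frame(g$edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = g$vertices, stringsAsFactors = FALSE))
  memb <- igraph::components(ig, mode = "strong")$membership
  memb <- memb[g$vertices]  # declaration order
  comps <- split(g$vertices, memb)
  ord <- order(vapply(comps, function(m) match(m[1], g$vertices), integer(1)))
  unname(comps[ord])
}

#' Build the hierarchical partition for the phenotype (HPFP)
#'
#' Partitions the residual network into SCCs and layers them into
#' categories: category 1 holds the SCCs with zero in-degree in the
#' condensation; category n (n >= 2) holds the SCCs all of whose incoming
#' condensation edges come from categories below n, with at least one from
#' category n-1. This is the longest-path layering of the condensation (the
#' unique assignment satisfying both conditions).
#'
#' @param rules named list of residual rule expressions
#' @return object of class `bn_hpfp`: list with `categories` (list of lists
#'   of SCC records `list(id, category, index, members, inputs)`),
#'   `condensation` (two-column matrix of SCC-id edges) and `nodes`
#' @export
hpfp_partition <- function(rules) {
  g <- dependency_graph(rules)
  comps <- strongly_connected_components(g)
  k <- length(comps)
  if (k == 0L) {
    return(structure(list(categories = list(),
                          condensation = cbind(from = character(0),
                                               to = character(0)),
                          nodes = character(0)),
                     class = "bn_hpfp"))
  }
  comp_of <- stats::setNames(rep(seq_len(k), lengths(comps)),
                             unlist(comps, use.names = FALSE))
  # condensation edges (self-loops within an SCC dropped)
  ce <- unique(cbind(comp_of[g$edges[, "from"]], comp_of[g$edges[, "to"]]))
  if (length(ce)) ce <- ce[ce[, 1] != ce[, 2], , drop = FALSE]
  else ce <- matrix(integer(0), 0L, 2L)
  # longest-path layering via Kahn order
  indeg <- tabulate(ce[, 2], nbins = k)
  cat_of <- rep(1L, k)
  queue <- which(indeg == 0L)
  remaining <- indeg
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    outs <- ce[ce[, 1] == u, 2]
    for (v in outs) {
      cat_of[v] <- max(cat_of[v], cat_of[u] + 1L)
      remaining[v] <- remaining[v] - 1L
      if (remaining[v] == 0L) queue <- c(queue, v)
    }
  }
  if (any(remaining > 0L))
    stop("internal error: condensation of SCCs contains a cycle")
  ncat <- max(cat_of)
  categories <- vector("list", ncat)
  for (n in seq_len(ncat)) {
    idx <- which(cat_of == n)  # already ordered by smallest member index
    categories[[n]] <- lapply(seq_along(idx), function(j) {
      ci <- idx[j]
      members <- comps[[ci]]
      regs <- unique(unlist(lapply(rules[members], expr_vars),
                            use.names = FALSE))
      list(id = sprintf("V%d,%d", n, j), category = n, index = j,
           members = members,
           inputs = intersect(g$vertices, setdiff(regs, members)))
    })
  }
  # condensation edge list on V{n,k} labels
  lab <- character(k)
  for (n in seq_len(ncat)) for (s in categories[[n]]) {
    lab[comp_of[[s$members[1]]]] <- s$id
  }
  cond <- cbind(from = lab[ce[, 1]], to = lab[ce[, 2]])
  structure(list(categories = categories, condensation = cond,
                 nodes = g$vertices),
            class = "bn_hpfp")
}

# flat list of SCC records in processing order (category, then index)
hpfp_sccs <- function(hpfp) {
  unlist(hpfp$categories, recursive = FALSE)
}

#' Summary counts of an HPFP
#'
#' Counts cover the residual nodes only (the fixed external/phenotype nodes
#' are not part of the partition); an empty residual network gives all
#' zeros.
#'
#' @param hpfp a `bn_hpfp`
#' @return list with `n_categories`, `n_sccs`, `max_scc_size`
#' @export
hpfp_summary <- function(hpfp) {
  sccs <- hpfp_sccs(hpfp)
  list(n_categories = length(hpfp$categories),
       n_sccs = length(sccs),
       max_scc_size = if (length(sccs))
         max(vapply(sccs, function(s) length(s$members), integer(1))) else 0L)
}

#' Export an HPFP as plain structured records
#'
#' @param hpfp a `bn_hpfp`
#' @param file optional path; writes JSON (categories, SCC members and
#'   inputs) plus, when `edge_file` is given, a two-column text edge list of
#'   the condensation for external graph viewers
#' @param edge_file optional path for the condensation edge list (TSV)
#' @return the record list, invisibly when written
#' @export
export_hpfp <- function(hpfp, file = NULL, edge_file = NULL) {
  recs <- lapply(hpfp$categories, function(cc)
    lapply(cc, function(s)
      list(id = s$id, members = s$members, input_nodes = s$inputs)))
  if (!is.null(edge_file)) {
    utils::write.table(hpfp$condensation, edge_file, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(file)) {
    writeLines(jsonlite::toJSON(list(categories = recs), auto_unbox = TRUE,
                                pretty = TRUE), file)
    return(invisible(recs))
  }
  recs
}

#' @export
print.bn_hpfp <- function(x, ...) {
  s <- hpfp_summary(x)
  cat(sprintf("HPFP: %d categories, %d SCCs, max SCC size %d\n",
              s$n_categories, s$n_sccs, s$max_scc_size))
  for (cc in x$categories) for (scc in cc) {
    cat(sprintf("  %s: {%s}", scc$id, paste(scc$members, collapse = ", ")))
    if (length(scc$inputs))
      cat(sprintf("  <- inputs {%s}", paste(scc$inputs, collapse = ", ")))
    cat("\n")
  }
  invisible(x)
}
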