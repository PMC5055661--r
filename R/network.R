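#' Construct a synchronous Boolean network
#'
#' @param rules named list of rule expressions (as produced by the parser);
#'   names are the target nodes and fix the declaration order
#' @return an object of class `boolean_network` with elements `nodes`
#'   (declaration order), `rules` (named list of ASTs) and `compiled`
#'   (pre-built R calls used for vectorised evaluation)
#' @keywords internal
new_boolean_network <- function(rules) {
  nodes <- names(rules)
  refs <- unique(unlist(lapply(rules, expr_vars), use.names = FALSE))
  undecl <- setdiff(refs, nodes)
  if (length(undecl))
    stop("undeclared node reference: ", paste(undecl, collapse = ", "))
  structure(
    list(nodes = nodes, rules = rules,
         compiled = lapply(rules, expr_to_call)),
    class = "boolean_network"
  )
}

#' Parse a Boolean network from rule text
#'
#' The canonical dialect is the common `targets, factors` plain-text
#' convention: an optional header line `targets, factors`, then one rule per
#' line in the form `Node, expression`. Expressions use `& | !` with
#' parentheses and constants 0/1; threshold (sign) rules are written
#' `sgn(-AKT + p53 - BCL_2 - Bcl_XL)` (square brackets also accepted on
#' input). Lines starting with `#` are comments.
#'
#' @param text character scalar (whole file) or vector of lines
#' @return a `boolean_network`
#' @seealso [read_network()], [write_network()], [network_from_rules()]
#' @export
#' @examples
#' net <- parse_network(c("targets, factors",
#'                        "p70, p70", "MYC, MYC", "p21, p21",
#'                        "Proliferation, p70 & MYC & !p21"))
#' net
parse_network <- function(text) {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(text)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty rule file")
  hdr <- gsub("[[:space:]]", "", tolower(lines[1]))
  if (hdr == "targets,factors") {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  if (length(lines) == 0L) stop("rule file has a header but no rules")
  rules <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    cpos <- regexpr(",", ln, fixed = TRUE)
    if (cpos == -1L)
      stop("line ", lineno[i], ": expected 'Node, expression', got: ", ln)
    target <- trimws(substr(ln, 1L, cpos - 1L))
    body <- trimws(substr(ln, cpos + 1L, nchar(ln)))
    if (!grepl("^[A-Za-z_][A-Za-z0-9_/.]*$", target))
      stop("line ", lineno[i], ": invalid node name '", target, "'")
    if (target %in% names(rules))
      stop("line ", lineno[i], ": duplicate rule for node '", target, "'")
    rules[[target]] <- parse_expr_text(body, line = lineno[i])
  }
  refs <- unique(unlist(lapply(rules, expr_vars), use.names = FALSE))
  undecl <- setdiff(refs, names(rules))
  if (length(undecl)) {
    n1 <- undecl[1]
    at <- which(vapply(rules, function(r) n1 %in% expr_vars(r), logical(1)))[1]
    stop("undeclared node '", n1, "' referenced on line ", lineno[at])
  }
  new_boolean_network(rules)
}

#' Read a Boolean network from a rule file
#' @param file path to a plain-text rule file
#' @return a `boolean_network`
#' @export
read_network <- function(file) parse_network(readLines(file, warn = FALSE))

#' Build a network from a named vector of rule strings
#'
#' Convenience constructor used throughout the examples and tests:
#' `network_from_rules(c(A = "B", B = "!A"))`.
#'
#' @param rules named character vector, one expression per target node
#' @return a `boolean_network`
#' @export
network_from_rules <- function(rules) {
  stopifnot(is.character(rules), !is.null(names(rules)), all(nzchar(names(rules))))
  parse_network(c("targets, factors", paste0(names(rules), ", ", rules)))
}

#' Serialize a network to rule text
#'
#' Writes the canonical dialect with a `targets, factors` header. The output
#' round-trips through [parse_network()] to an identical network.
#'
#' @param network a `boolean_network`
#' @param file optional path; when `NULL` the text is returned invisibly
#' @return character vector of lines, invisibly when written to a file
#' @export
write_network <- function(network, file = NULL) {
  lines <- c("targets, factors",
             vapply(network$nodes,
                    function(n) paste0(n, ", ", format_expr(network$rules[[n]])),
                    character(1)))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Evaluate one update rule in a given state
#'
#' Logic bodies follow standard Boolean evaluation; threshold bodies return 1
#' iff `offset + sum(coef * value)` is strictly positive (a zero sum gives 0).
#'
#' @param rule a rule expression, or a `boolean_network` together with `node`
#' @param state named 0/1 (or logical) vector covering the rule's inputs
#' @param node when `rule` is a network, the target node whose rule to apply
#' @return 0 or 1
#' @export
evaluate_rule <- function(rule, state, node = NULL) {
  if (inherits(rule, "boolean_network")) {
    stopifnot(!is.null(node))
    rule <- rule$rules[[node]]
    if (is.null(rule)) stop("no rule for node '", node, "'")
  }
  eval_expr(rule, as.list(state))
}

#' Vectorised synchronous update over a state matrix
#'
#' @param network a `boolean_network`
#' @param states logical matrix, rows = states, columns = nodes in
#'   declaration order
#' @return logical matrix of the same shape: each row stepped once
#' @export
step_states <- function(network, states) {
  n <- length(network$nodes)
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  stopifnot(ncol(states) == n)
  env <- vector("list", n)
  names(env) <- network$nodes
  for (j in seq_len(n)) env[[j]] <- states[, j]
  out <- matrix(FALSE, nrow(states), n, dimnames = list(NULL, network$nodes))
  for (j in seq_len(n)) {
    v <- eval(network$compiled[[j]], env)
    if (length(v) == 1L) v <- rep(v, nrow(states))
    out[, j] <- v
  }
  out
}

#' Apply one synchronous update step
#'
#' All nodes are updated simultaneously from the same input state.
#'
#' @param network a `boolean_network`
#' @param state named 0/1 (or logical) vector covering all nodes, or an
#'   unnamed vector in declaration order
#' @return named integer 0/1 vector, the state at the next time step
#' @export
synchronous_step <- function(network, state) {
  if (!is.null(names(state))) {
    missing <- setdiff(network$nodes, names(state))
    if (length(missing))
      stop("state is missing values for: ", paste(missing, collapse = ", "))
    state <- state[network$nodes]
  } else if (length(state) != length(network$nodes)) {
    stop("state must cover all ", length(network$nodes), " nodes")
  }
  m <- matrix(as.logical(state), nrow = 1L)
  out <- step_states(network, m)
  stats::setNames(as.integer(out[1L, ]), network$nodes)
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Synchronous Boolean network:", length(x$nodes), "nodes\n")
  for (n in x$nodes) cat("  ", n, " <- ", format_expr(x$rules[[n]]), "\n", sep = "")
  invisible(x)
}
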