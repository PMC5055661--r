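# --- synthetic networks and scenarios for testing ---------------------------

#' Specification for a random Boolean network
#'
#' @param n_nodes number of nodes (excluding a planted phenotype sink)
#' @param seed integer seed; identical specs generate identical networks
#' @param family rule family: `"logic"` (random truth tables rendered as
#'   DNF), `"literal"` (conjunction/disjunction of literals), `"threshold"`
#'   (sign rules with unit weights) or `"mixed"`
#' @param k_max maximum in-degree (in-degree sampled uniformly on 1..k_max)
#' @param n_inputs number of input nodes carrying the self-loop identity
#'   rule `A* = A` (candidates for external clamping)
#' @param phenotype plant a sink node `Phen` whose rule is a conjunction of
#'   literals over randomly chosen nodes
#' @param layers optional planted SCC layout: a list of integer vectors,
#'   one per layer, each entry the size of one cycle; layer n >= 2 cycles
#'   receive at least one input from a layer n-1 cycle. Overrides
#'   `n_nodes`/`n_inputs`.
#' @return object of class `bn_generator_spec`
#' @export
generator_spec <- function(n_nodes = 10L, seed = 1L,
                           family = c("mixed", "logic", "literal", "threshold"),
                           k_max = 3L, n_inputs = 2L, phenotype = TRUE,
                           layers = NULL) {
  family <- match.arg(family)
  stopifnot(n_nodes >= 1L, k_max >= 1L, n_inputs >= 0L, n_inputs <= n_nodes)
  if (k_max > n_nodes - 1L && n_nodes > 1L) k_max <- n_nodes - 1L
  structure(list(n_nodes = as.integer(n_nodes), seed = as.integer(seed),
                 family = family, k_max = as.integer(k_max),
                 n_inputs = as.integer(n_inputs),
                 phenotype = isTRUE(phenotype), layers = layers),
            class = "bn_generator_spec")
}

#' Draw one random rule body over the given regulators
#'
#' Used by the network generator and handy for building small driven
#' fixtures: `"literal"` joins possibly-negated regulators with a single
#' `&` or `|`, `"threshold"` draws unit weights with random signs, and
#' `"logic"` draws a random truth table rendered as a DNF of its minterms.
#'
#' @param regs character vector of regulator names
#' @param family `"logic"`, `"literal"`, `"threshold"` or `"mixed"`
#' @return a rule-body string in the canonical dialect
#' @export
random_rule_text <- function(regs, family) {
  k <- length(regs)
  fam <- if (family == "mixed")
    sample(c("logic", "literal", "threshold"), 1L) else family
  lit <- function(n) if (stats::runif(1) < 0.5) paste0("!", n) else n
  if (fam == "threshold") {
    signs <- sample(c("+", "-"), k, replace = TRUE)
    terms <- paste0(signs, regs)
    return(paste0("sgn(", paste(terms, collapse = " "), ")"))
  }
  if (fam == "literal" || k == 1L) {
    op <- if (stats::runif(1) < 0.5) " & " else " | "
    return(paste(vapply(regs, lit, character(1)), collapse = op))
  }
  # random truth table over k inputs, rendered as a DNF of its minterms
  tt <- stats::runif(2^k) < 0.5
  if (all(!tt)) return("0")
  if (all(tt)) return("1")
  minterms <- vapply(which(tt) - 1L, function(m) {
    bits <- bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) > 0L
    paste0("(", paste(ifelse(bits, regs, paste0("!", regs)), collapse = " & "),
           ")")
  }, character(1))
  paste(minterms, collapse = " | ")
}

#' Generate a random or structured synthetic network
#'
#' Deterministic under the spec's seed. When a phenotype sink is planted,
#' a matching random scenario is generated too: 0-3 external clamps chosen
#' among the input (self-loop) nodes, and the phenotype sink required at 1.
#'
#' @param spec a `bn_generator_spec`
#' @return object of class `bn_synth`: list with `network`
#'   (`boolean_network`), `inputs` (input node names), `phenotype_node`
#'   (or `NULL`) and `scenario` (list with `external`, `phenotype`, `value`;
#'   `NULL` when no phenotype sink was planted)
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "bn_generator_spec"))
  with_local_seed(spec$seed, {
    if (!is.null(spec$layers)) {
      synth <- generate_layered(spec)
    } else {
      synth <- generate_free(spec)
    }
    rules <- synth$rules
    phen_node <- NULL
    if (spec$phenotype) {
      pool <- setdiff(names(rules), synth$inputs)
      if (length(pool) == 0L) pool <- names(rules)
      k <- min(length(pool), sample(2:3, 1L))
      regs <- sample(pool, k)
      lits <- ifelse(stats::runif(k) < 0.3, paste0("!", regs), regs)
      phen_node <- "Phen"
      rules[phen_node] <- paste(lits, collapse = " & ")
    }
    network <- network_from_rules(rules)
    scenario <- NULL
    if (!is.null(phen_node)) {
      n_ext <- if (length(synth$inputs)) sample(0:min(3L, length(synth$inputs)), 1L) else 0L
      ext_nodes <- if (n_ext > 0L) sample(synth$inputs, n_ext) else character(0)
      scenario <- list(
        external = stats::setNames(as.integer(stats::runif(n_ext) < 0.5),
                                   ext_nodes),
        phenotype = phen_node, value = 1L)
    }
    structure(list(network = network, inputs = synth$inputs,
                   phenotype_node = phen_node, scenario = scenario,
                   spec = spec),
              class = "bn_synth")
  })
}

generate_free <- function(spec) {
  n <- spec$n_nodes
  nodes <- sprintf("x%d", seq_len(n))
  inputs <- if (spec$n_inputs > 0L) nodes[seq_len(spec$n_inputs)] else character(0)
  rules <- character(n)
  names(rules) <- nodes
  for (nm in nodes) {
    if (nm %in% inputs) {
      rules[nm] <- nm  # identity self-loop: sustains either clamp
      next
    }
    k <- sample.int(min(spec$k_max, n), 1L)
    regs <- sample(nodes, k)
    rules[nm] <- random_rule_text(regs, spec$family)
  }
  list(rules = rules, inputs = inputs)
}

# planted DAG of cycles: each layer is a list of ring sizes; rings in layer
# n >= 2 get one feed edge from a ring of layer n-1
generate_layered <- function(spec) {
  layers <- spec$layers
  rules <- character(0)
  layer_members <- list()
  idx <- 0L
  for (li in seq_along(layers)) {
    members_this <- list()
    for (size in layers[[li]]) {
      ring <- sprintf("x%d", idx + seq_len(size))
      idx <- idx + size
      for (j in seq_along(ring)) {
        prev <- ring[if (j == 1L) length(ring) else j - 1L]
        rules[ring[j]] <- prev
      }
      if (li > 1L) {
        feeder_ring <- layer_members[[li - 1L]][[
          sample.int(length(layer_members[[li - 1L]]), 1L)]]
        feed <- sample(feeder_ring, 1L)
        tgt <- sample(ring, 1L)
        op <- if (stats::runif(1) < 0.5) "&" else "|"
        rules[tgt] <- paste(rules[tgt], op, feed)
      }
      members_this[[length(members_this) + 1L]] <- ring
    }
    layer_members[[li]] <- members_this
  }
  list(rules = rules, inputs = character(0))
}

#' Write a generated fixture to the canonical file formats
#'
#' Emits the rule file and, when a scenario was generated, the YAML scenario
#' file, so downstream modules can be exercised through their public file
#' interfaces.
#'
#' @param synth a `bn_synth`
#' @param dir output directory (created if missing)
#' @param name base file name
#' @return named list of written paths
#' @export
write_fixture <- function(synth, dir, name = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model <- file.path(dir, paste0(name, ".bnet"))
  write_network(synth$network, model)
  paths <- list(model = model)
  if (!is.null(synth$scenario)) {
    scen <- file.path(dir, paste0(name, "_scenario.yaml"))
    write_scenario(synth$scenario, scen)
    paths$scenario <- scen
  }
  paths
}
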