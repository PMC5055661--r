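#' @title Boolean update-rule expressions
#'
#' @description
#' Update rules are stored as small ASTs. Logic rules use the node types
#' `const` (0/1), `var` (node reference), `not`, `and`, `or`; threshold
#' (sign) rules use a single `thr` node holding integer coefficients per
#' input node plus an integer offset. A threshold rule evaluates to 1 iff
#' `offset + sum(coef * value) > 0` (a sum of exactly zero gives 0, which is
#' what makes `Apoptosis = sgn(Caspase8 + Caspase9)` equal 1 only when an
#' input caspase is active).
#'
#' @name bn-expressions
#' @keywords internal
NULL

bn_const <- function(v) list(op = "const", value = as.integer(v))
bn_var   <- function(name) list(op = "var", name = name)
bn_not   <- function(x) list(op = "not", x = x)
bn_and   <- function(l, r) list(op = "and", lhs = l, rhs = r)
bn_or    <- function(l, r) list(op = "or", lhs = l, rhs = r)
bn_thr   <- function(coef, offset = 0L) {
  list(op = "thr", coef = vapply(coef, as.integer, integer(1)),
       offset = as.integer(offset))
}

is_const <- function(e) e$op == "const"

#' Nodes referenced by an expression
#' @param expr a rule expression
#' @return character vector of node names, in order of first appearance
#' @export
expr_vars <- function(expr) {
  switch(expr$op,
    const = character(0),
    var = expr$name,
    not = expr_vars(expr$x),
    and = ,
    or = unique(c(expr_vars(expr$lhs), expr_vars(expr$rhs))),
    thr = names(expr$coef),
    stop("unknown expression op: ", expr$op)
  )
}

# reference single-state interpreter (vectorised evaluation goes through
# expr_to_call); `values` is a named 0/1 (or logical) vector
eval_expr <- function(expr, values) {
  switch(expr$op,
    const = expr$value,
    var = {
      v <- values[[expr$name]]
      if (is.null(v) || is.na(v))
        stop("missing input value for node '", expr$name, "'")
      as.integer(v)
    },
    not = 1L - eval_expr(expr$x, values),
    and = {
      if (eval_expr(expr$lhs, values) == 0L) 0L else eval_expr(expr$rhs, values)
    },
    or = {
      if (eval_expr(expr$lhs, values) == 1L) 1L else eval_expr(expr$rhs, values)
    },
    thr = {
      s <- expr$offset
      for (n in names(expr$coef)) {
        v <- values[[n]]
        if (is.null(v) || is.na(v))
          stop("missing input value for node '", n, "'")
        s <- s + expr$coef[[n]] * as.integer(v)
      }
      if (s > 0L) 1L else 0L
    },
    stop("unknown expression op: ", expr$op)
  )
}

# compile an AST into an R call evaluated over logical column vectors
expr_to_call <- function(expr) {
  switch(expr$op,
    const = expr$value == 1L,
    var = as.symbol(expr$name),
    not = call("!", expr_to_call(expr$x)),
    and = call("&", expr_to_call(expr$lhs), expr_to_call(expr$rhs)),
    or = call("|", expr_to_call(expr$lhs), expr_to_call(expr$rhs)),
    thr = {
      acc <- expr$offset
      for (n in names(expr$coef))
        acc <- call("+", acc, call("*", expr$coef[[n]], as.symbol(n)))
      call(">", acc, 0L)
    },
    stop("unknown expression op: ", expr$op)
  )
}

## ---- parsing -------------------------------------------------------------

bn_tokenize <- function(text, line = NA) {
  pat <- "[A-Za-z_][A-Za-z0-9_/.]*|[0-9]+|\\&|\\||!|\\(|\\)|\\[|\\]|\\+|-|\\*"
  stripped <- gsub("[[:space:]]+", " ", text)
  m <- gregexpr(pat, text)[[1]]
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  # every non-space character must be consumed by some token
  covered <- rep(FALSE, nchar(text))
  if (length(toks) && m[1] != -1)
    for (i in seq_along(m))
      covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1L)] <- TRUE
  chars <- strsplit(text, "")[[1]]
  bad <- which(!covered & !grepl("[[:space:]]", chars))
  if (length(bad))
    stop("malformed expression", if (!is.na(line)) paste0(" on line ", line),
         ": unexpected character '", chars[bad[1]], "' at position ", bad[1],
         " in: ", stripped)
  list(toks = toks, pos = as.integer(m))
}

# recursive-descent parser with precedence ! > & > |
parse_expr_text <- function(text, line = NA) {
  tk <- bn_tokenize(text, line)
  toks <- tk$toks
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[i] else NA_character_
  advance <- function() { t <- toks[i]; i <<- i + 1L; t }
  expect <- function(what) {
    t <- peek()
    if (is.na(t) || !(t %in% what))
      stop("malformed expression", if (!is.na(line)) paste0(" on line ", line),
           ": expected '", paste(what, collapse = "' or '"), "' near token ",
           i, " ('", if (is.na(t)) "end of line" else t, "') in: ", text)
    advance()
  }
  is_ident <- function(t) grepl("^[A-Za-z_][A-Za-z0-9_/.]*$", t)

  parse_threshold <- function() {
    open <- expect(c("(", "["))
    close <- if (open == "(") ")" else "]"
    coef <- integer(0)
    offset <- 0L
    sign <- 1L
    first <- TRUE
    repeat {
      t <- peek()
      if (is.na(t))
        stop("malformed expression", if (!is.na(line)) paste0(" on line ", line),
             ": unterminated sgn(...) in: ", text)
      if (t == close) { advance(); break }
      if (t == "+") { advance(); sign <- 1L; next }
      if (t == "-") { advance(); sign <- -sign; next }
      mag <- 1L
      if (grepl("^[0-9]+$", t)) {
        mag <- as.integer(advance())
        if (!is.na(peek()) && peek() == "*") advance()
        t <- peek()
        if (is.na(t) || !is_ident(t)) {
          # bare integer contributes to the offset
          offset <- offset + sign * mag
          sign <- 1L
          first <- FALSE
          next
        }
      }
      t <- peek()
      if (is.na(t) || !is_ident(t))
        stop("malformed expression", if (!is.na(line)) paste0(" on line ", line),
             ": expected node name inside sgn(...) in: ", text)
      nm <- advance()
      coef[nm] <- (if (nm %in% names(coef)) coef[[nm]] else 0L) + sign * mag
      sign <- 1L
      first <- FALSE
    }
    coef <- coef[coef != 0L]
    if (length(coef) == 0L)
      stop("threshold rule needs at least one node term",
           if (!is.na(line)) paste0(" (line ", line, ")"), ": ", text)
    bn_thr(coef, offset)
  }

  parse_factor <- function() {
    t <- peek()
    if (is.na(t))
      stop("malformed expression", if (!is.na(line)) paste0(" on line ", line),
           ": unexpected end of line in: ", text)
    if (t == "!") { advance(); return(bn_not(parse_factor())) }
    if (t == "(") {
      advance()
      e <- parse_or()
      expect(")")
      return(e)
    }
    if (t %in% c("0", "1")) { advance(); return(bn_const(as.integer(t))) }
    if (t == "sgn" && !is.na(toks[i + 1L]) && toks[i + 1L] %in% c("(", "[")) {
      advance()
      return(parse_threshold())
    }
    if (is_ident(t)) { advance(); return(bn_var(t)) }
    stop("malformed expression", if (!is.na(line)) paste0(" on line ", line),
         ": unexpected token '", t, "' (token ", i, ") in: ", text)
  }

  parse_and <- function() {
    e <- parse_factor()
    while (!is.na(peek()) && peek() == "&") {
      advance()
      e <- bn_and(e, parse_factor())
    }
    e
  }

  parse_or <- function() {
    e <- parse_and()
    while (!is.na(peek()) && peek() == "|") {
      advance()
      e <- bn_or(e, parse_and())
    }
    e
  }

  e <- parse_or()
  if (!is.na(peek()))
    stop("malformed expression", if (!is.na(line)) paste0(" on line ", line),
         ": trailing token '", peek(), "' (token ", i, ") in: ", text)
  if (e$op != "thr" && length(find_thr(e)))
    stop("sgn(...) may only appear as the whole rule body",
         if (!is.na(line)) paste0(" (line ", line, ")"), ": ", text)
  e
}

find_thr <- function(e) {
  switch(e$op,
    thr = list(e),
    not = find_thr(e$x),
    and = ,
    or = c(find_thr(e$lhs), find_thr(e$rhs)),
    list()[0]
  )
}

## ---- serialization -------------------------------------------------------

# precedence: or = 1, and = 2, not = 3, atoms = 4
expr_prec <- function(e) {
  switch(e$op, or = 1L, and = 2L, not = 3L, 4L)
}

#' Render a rule expression as text
#'
#' Produces the canonical dialect: operators `& | !`, explicit parentheses
#' only where precedence requires them, thresholds as `sgn(...)`.
#'
#' @param expr a rule expression
#' @return a character scalar
#' @export
format_expr <- function(expr) {
  wrap <- function(child, strict, parent_prec) {
    s <- format_expr(child)
    p <- expr_prec(child)
    if (p < parent_prec || (strict && p == parent_prec)) paste0("(", s, ")")
    else s
  }
  switch(expr$op,
    const = as.character(expr$value),
    var = expr$name,
    not = paste0("!", wrap(expr$x, strict = FALSE,
                           parent_prec = 4L)),  # parenthesize non-atoms
    and = paste(wrap(expr$lhs, FALSE, 2L), "&", wrap(expr$rhs, TRUE, 2L)),
    or = paste(wrap(expr$lhs, FALSE, 1L), "|", wrap(expr$rhs, TRUE, 1L)),
    thr = {
      parts <- character(0)
      for (j in seq_along(expr$coef)) {
        cf <- expr$coef[[j]]
        if (cf == 0L) next
        nm <- names(expr$coef)[j]
        mag <- abs(cf)
        term <- if (mag == 1L) nm else paste0(mag, "*", nm)
        if (length(parts) == 0L)
          parts <- if (cf < 0L) paste0("-", term) else term
        else
          parts <- c(parts, paste(if (cf < 0L) "-" else "+", term))
      }
      if (expr$offset != 0L)
        parts <- c(parts, paste(if (expr$offset < 0L) "-" else "+",
                                abs(expr$offset)))
      if (length(parts) == 0L) parts <- "0"
      paste0("sgn(", paste(parts, collapse = " "), ")")
    },
    stop("unknown expression op: ", expr$op)
  )
}
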