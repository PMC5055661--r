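# small internal helpers shared across modules

gcd2 <- function(a, b) {
  while (b != 0) { t <- a %% b; a <- b; b <- t }
  a
}

lcm2 <- function(a, b) (a %/% gcd2(a, b)) * b

lcm_all <- function(x) Reduce(lcm2, x, accumulate = FALSE)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# encode rows of a logical matrix as integers; column 1 is the least
# significant bit, so encodings follow the node declaration order
encode_states <- function(m) {
  if (ncol(m) == 0L) return(rep(0L, nrow(m)))
  as.integer(m %*% 2^(seq_len(ncol(m)) - 1L))
}

decode_states <- function(idx, k) {
  if (k == 0L) return(matrix(logical(0), nrow = length(idx), ncol = 0L))
  m <- matrix(FALSE, length(idx), k)
  for (j in seq_len(k)) m[, j] <- bitwAnd(idx, bitwShiftL(1L, j - 1L)) > 0L
  m
}

state_strings <- function(m) {
  if (ncol(m) == 0L) return(rep("", nrow(m)))
  apply(m, 1L, function(r) paste0(as.integer(r), collapse = ""))
}

# evaluate with the RNG state protected, seeding locally
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
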