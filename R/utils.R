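`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Run `expr` under a private RNG stream; the caller's .Random.seed is restored.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Scalar "is this cell missing": NULL, length-0, NA, or "" all count.
is_missing_value <- function(x) {
  is.null(x) || length(x) == 0L || is.na(x) || (is.character(x) && !nzchar(x))
}

# Deterministic (locale-independent) ordering by dissimilarity, ties by id.
order_by_diss <- function(diss, ids) order(diss, ids, method = "radix")
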