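# Internal helpers shared across modules.

# Largest value representable without loss in a double-backed exact-integer
# computation; anything beyond aborts rather than silently losing precision.
.INT_EXACT_MAX <- 2^49

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

.gcd_vec <- function(x) {
  x <- abs(x[x != 0])
  if (length(x) == 0L) return(1)
  Reduce(.gcd2, x)
}

# Deterministic, locale-independent ordering of character ids.
.id_order <- function(ids) order(ids, method = "radix")

# Radix sort that tolerates NULL/empty input (sorting zero surviving ids).
.sort_ids <- function(x) sort(as.character(if (is.null(x)) character(0) else x),
                              method = "radix")

.check_exact <- function(x, what = "value") {
  if (any(abs(x) > .INT_EXACT_MAX)) {
    stop("exact integer overflow guard tripped while computing ", what,
         "; intermediate values exceed 2^49", call. = FALSE)
  }
  invisible(x)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Run an expression with a local RNG seed, restoring global state afterwards.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
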