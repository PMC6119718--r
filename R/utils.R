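#' @importFrom rlang abort warn .data :=
#' @importFrom stats rnorm runif var sd quantile
NULL

# trapezoid rule on a (possibly non-uniform) grid
trapz <- function(t, y) {
  n <- length(t)
  sum((t[-1] - t[-n]) * (y[-1] + y[-n])) / 2
}

clip01 <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

# Deterministic child-seed derivation: a Lehmer-style mix of the master seed
# and an index, kept inside 32-bit integer range so set.seed() accepts it.
derive_seed <- function(master_seed, index) {
  m <- 2147483647
  x <- (as.double(master_seed) %% m) * 48271 %% m
  as.integer((x + as.double(index) * 16807 + 1) %% m)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(class, fmt, ...) {
  abort(sprintf(fmt, ...), class = c(class, "affectfanova_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
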