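# Internal numerical and RNG helpers.

# Run expr under a temporary RNG state when seed is given; the ambient RNG
# stream is left untouched. With seed = NULL the ambient stream is used (and
# advanced).
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Exact (Gaussian-CDF) GELU and its derivative.
gelu <- function(x) x * stats::pnorm(x)
geluGrad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Row-wise softmax with numerical stabilization.
rowSoftmax <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - mx)
  e / rowSums(e)
}

# Stable log(1 + exp(x)).
log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(x)))

clipValue <- function(x, bound) pmin(pmax(x, -bound), bound)

# Truncated-normal initializer (resample beyond 2 sigma), the transformer
# convention used throughout the model.
truncNormal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
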