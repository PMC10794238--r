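## Internal numeric and RNG helpers.

## log(sum(exp(x))) with the usual max-shift guard; finite whenever x is.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards. All stochastic operations in
## the package route their `seed` arguments through this helper.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Population (1/N) standard deviation.
sd_pop <- function(x) {
  mu <- mean(x)
  sqrt(mean((x - mu)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
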