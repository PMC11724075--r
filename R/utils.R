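#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats median mad sd quantile rnorm runif rbinom kmeans coef
#' @importFrom utils head read.csv write.csv
NULL

## Run code with a locally seeded RNG, restoring the caller's RNG state.
## All stochastic operations in the package route through this so that a
## spec + seed pair is byte-reproducible regardless of surrounding code.
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

## sample() without the length-1 surprise
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size = size, replace = replace)]
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

## Deterministic 31-bit polynomial hash of an integer vector.  Exact in
## double arithmetic: intermediate products stay below 2^53.
hashIntVector <- function(x) {
  h <- 5381
  m <- 2147483647
  for (v in x) {
    h <- (h * 33 + (v %% m)) %% m
  }
  h
}
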