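`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Population (divide by n) or sample (divide by n - 1) variance of a vector.
variance_of <- function(x, estimator = "population") {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (estimator == "sample") {
    n <- length(x)
    if (n < 2L) return(NA_real_)
    v <- v * n / (n - 1)
  }
  v
}

# Stable short hash of an R object (used to stamp feature tables with the
# backbone configuration that produced them).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
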