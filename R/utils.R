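#' @useDynLib assemblyseq, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rpois runif rnorm sd quantile setNames aggregate
#' @importFrom utils read.csv write.csv head
NULL

# Derive a reproducible 31-bit sub-seed from a master seed and a stage label.
# Every stochastic stage of the pipeline draws its own seed through this so a
# single master seed fixes the whole run.
derive_seed <- function(master, label, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  s <- (abs(master) %% 2147483647) + 0
  s <- (s * 48271 + h * 1009 + index * 7919) %% 2147483647
  as.integer(s)
}

# Evaluate `expr` under a local RNG state seeded with `seed` (NULL = leave
# the global stream alone).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
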