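#' @useDynLib dedocr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom Matrix sparseMatrix drop0 triu rowSums colSums
#' @importFrom methods as is new
#' @importFrom stats rpois rbinom runif cor
#' @importFrom utils write.table read.table
NULL

# x * log2(y) with the 0 * log 0 := 0 convention; y entries of 0 are only
# admissible where x is also 0.
xlog2 <- function(x, y) {
  out <- numeric(length(x))
  nz <- x != 0
  out[nz] <- x[nz] * log2(y[nz])
  out
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single number or NULL", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_parse <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}
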