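#' @useDynLib tetrabin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm plogis qlogis rexp rgamma rnorm runif cor setNames
#' @importFrom utils read.table write.table
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

stop_input <- function(...) {
  stop(errorCondition(sprintf(...), class = c("tetrabin_input_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(sprintf(...), class = c("tetrabin_format_error", "error")))
}

stop_state <- function(...) {
  stop(errorCondition(sprintf(...), class = c("tetrabin_state_error", "error")))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Derive a child seed from (seed, k) without overflowing 32-bit integers.
mix_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000 + k) %% 2147483647)
}
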