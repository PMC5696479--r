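#' Reference sound pressure
#'
#' The standard reference pressure for sound pressure level in air,
#' 2e-5 Pa.  All equivalent-SPL computations in this package are referenced
#' to this constant.
#'
#' @format A length-one numeric (Pa).
#' @export
PA_REF <- 2e-5

## dB helpers for amplitude ratios (20 log10)
amp_db <- function(x) 20 * log10(x)
db_amp <- function(l) 10^(l / 20)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global random-number state set from `seed`, then
#' restores whatever state was active before.  With `seed = NULL` the
#' expression is evaluated untouched.  Every stochastic generator in the
#' package routes its randomness through this helper so that a single integer
#' seed makes a whole simulated data set reproducible.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## round x to the nearest multiple of `step`; step 0 means no quantization
quantize <- function(x, step) {
  if (step <= 0) return(x)
  round(x / step) * step
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}
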