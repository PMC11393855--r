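#' @keywords internal
"_PACKAGE"

# numerical floor used on all logs / ratios
EPS <- 1e-10

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state so nested seeded computations (e.g. the wrapper
#' classifier inside a selector loop) do not perturb the outer stream.
#'
#' @param seed integer seed, or NULL to run unseeded.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# moment helpers with the convention that a constant series has
# skewness and kurtosis 0 (excess kurtosis elsewhere uses e1071)
safe_skewness <- function(x) {
  if (stats::sd(x) < EPS) return(0)
  e1071::skewness(x, type = 2)
}

safe_kurtosis <- function(x) {
  if (stats::sd(x) < EPS) return(0)
  e1071::kurtosis(x, type = 2)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}
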