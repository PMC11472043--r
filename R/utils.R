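#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `code`, and restores the caller's RNG
#' state afterwards, so seeded package functions never disturb the global
#' random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream unchanged.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# log(exp(x) + exp(y)), elementwise, -Inf safe
logspace_add <- function(x, y) {
  m <- pmax(x, y)
  out <- m + log1p(exp(-abs(x - y)))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# stop() unless all k are close to nonnegative integers
check_counts <- function(k, what = "k") {
  if (any(!is.finite(k)) || any(k < 0))
    stop(sprintf("'%s' must be finite and >= 0", what))
  if (any(abs(k - round(k)) > 1e-8))
    stop(sprintf("'%s' must be integer-valued for pmf evaluation; round counts at load time", what))
  invisible(round(k))
}
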