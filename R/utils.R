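#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the global random-number generator seeded at
#' \code{seed}, then restores the previous RNG state so callers are not
#' affected. With \code{seed = NULL} the expression runs on the current stream.
#'
#' @param seed Integer seed or \code{NULL}.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# symmetric within tolerance
check_symmetric <- function(m, tol = 1e-10, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix")
  if (length(m) && max(abs(m - t(m)), na.rm = TRUE) > tol)
    stop(what, " is asymmetric beyond tolerance ", tol)
  invisible(TRUE)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
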