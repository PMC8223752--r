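# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so seeded operations never perturb the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

check_numeric_matrix <- function(x, name = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("`%s` must be a numeric matrix", name)
  if (anyNA(x) || any(!is.finite(x)))
    stopf("`%s` contains missing or non-finite values", name)
  invisible(x)
}

# status vector -> 0/1 coding with case = 1; accepts factor/character/logical
status01 <- function(status, case = "case", control = "control") {
  if (is.logical(status)) return(as.integer(status))
  if (is.numeric(status)) {
    if (!all(status %in% c(0, 1))) stopf("numeric status must be 0/1")
    return(as.integer(status))
  }
  s <- as.character(status)
  bad <- setdiff(unique(s), c(case, control))
  if (length(bad))
    stopf("status contains labels other than '%s'/'%s': %s",
          case, control, paste(bad, collapse = ", "))
  as.integer(s == case)
}

# inverse of trigamma via Newton iteration (monotone, convex target)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}
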