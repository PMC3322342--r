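# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a polynomial with ascending coefficients
#'
#' `polyval(c(c0, c1, c2), x)` returns `c0 + c1*x + c2*x^2`.
#' @param coeffs numeric vector of coefficients, constant term first.
#' @param x numeric vector of evaluation points.
#' @return numeric vector the length of `x`.
#' @keywords internal
#' @noRd
polyval <- function(coeffs, x) {
  stopifnot(is.numeric(coeffs), length(coeffs) >= 1L)
  out <- rep(0, length(x))
  for (k in rev(seq_along(coeffs))) out <- out * x + coeffs[k]
  out
}

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("row_vars() needs at least 2 columns")
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1L)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g (got %g)", name, lower, x), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g (got %g)", name, lower, x), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g (got %g)", name, upper, x), call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stop(sprintf("'%s' must be a single integer", name), call. = FALSE)
  if (x < lower)
    stop(sprintf("'%s' must be >= %d (got %d)", name, lower, as.integer(x)),
         call. = FALSE)
  invisible(as.integer(x))
}

# Derive a per-stage seed from the root seed so every stage draws from its
# own reproducible stream. Kept well below .Machine$integer.max.
stage_seed <- function(seed, stage) {
  offsets <- c(atlas = 1L, two_color = 2L, female_gsc = 3L, os_bgcn = 4L,
               annotations = 5L, misc = 6L)
  if (!stage %in% names(offsets))
    stop(sprintf("unknown stage '%s'", stage), call. = FALSE)
  (as.integer(seed) %% 16777216L) * 64L + offsets[[stage]]
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
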