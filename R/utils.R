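# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number state set from `seed`, then
#' restores the previous state, so generators are pure functions of
#' (parameters, seed). A `NULL` seed leaves the current RNG state in place.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Sample-standard-deviation z-score of a numeric vector; NA-free input assumed.
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(NULL)
  (x - mean(x)) / s
}

# Row-wise z-score with one refinement pass: subtracting a large row mean
# leaves a relative centering residue, so the z-scores are re-centered and
# re-scaled once, pushing |mean| and |sd - 1| to machine epsilon.
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  z <- (m - mu) / s
  ok <- is.finite(s) & s > 0
  if (any(ok)) {
    z2 <- z[ok, , drop = FALSE]
    z2 <- z2 - rowMeans(z2)
    z2 <- z2 / apply(z2, 1L, stats::sd)
    z[ok, ] <- z2
  }
  list(values = z, sd = s)
}

assert_species_pair <- function(a, b) {
  if (is.na(a) || is.na(b) || identical(a, b))
    stopf("a species pair must name two distinct species (got %s / %s)", a, b)
}
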