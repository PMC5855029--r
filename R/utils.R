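#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's RNG stream so
#' library functions never perturb user-level reproducibility.
#' @noRd
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Deterministically mix integers into one seed below 2^31
#' @noRd
mix_seed <- function(...) {
  parts <- as.numeric(c(...))
  m <- 2147483629
  s <- 11
  for (p in parts) s <- (s * 69069 + (p %% m) + 1) %% m
  as.integer(s)
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
assert_matrix <- function(X, name = deparse(substitute(X))) {
  if (!is.matrix(X) || !is.numeric(X))
    stopf("`%s` must be a numeric matrix", name)
  if (any(!is.finite(X)))
    stopf("`%s` contains non-finite values", name)
  invisible(X)
}

#' Column standardisation fitted on one matrix, applicable to another
#' @noRd
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sig <- apply(X, 2, stats::sd)
  sig[!is.finite(sig) | sig < 1e-12] <- 1
  list(center = mu, scale = sig)
}

#' @noRd
apply_scaler <- function(X, sc) {
  sweep(sweep(X, 2, sc$center, "-"), 2, sc$scale, "/")
}
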