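#' Within-class scatter matrix
#'
#' Unnormalised sum over classes and samples of outer products of
#' deviations from the class mean.
#'
#' @param X Samples x p numeric matrix.
#' @param labels Class label per row.
#' @return Symmetric positive semi-definite p x p matrix.
#' @export
within_class_scatter <- function(X, labels) {
  assert_matrix(X)
  if (nrow(X) != length(labels))
    stopf("label count (%d) does not match sample count (%d)",
          length(labels), nrow(X))
  labels <- factor(labels)
  S <- matrix(0, ncol(X), ncol(X))
  for (cl in levels(labels)) {
    Xi <- X[labels == cl, , drop = FALSE]
    D <- sweep(Xi, 2, colMeans(Xi), "-")
    S <- S + crossprod(D)
  }
  (S + t(S)) / 2
}

# Normalised (1/n) between- and within-class scatters used by the Fisher
# criterion; the common 1/n cancels in the trace ratio.
class_scatters <- function(X, labels) {
  labels <- factor(labels)
  n <- nrow(X)
  m <- colMeans(X)
  Sw <- within_class_scatter(X, labels) / n
  Sb <- matrix(0, ncol(X), ncol(X))
  for (cl in levels(labels)) {
    Xi <- X[labels == cl, , drop = FALSE]
    d <- colMeans(Xi) - m
    Sb <- Sb + nrow(Xi) * tcrossprod(d)
  }
  list(Sw = Sw, Sb = Sb / n)
}

#' Between-set covariance matrix
#'
#' `(1/n) * sum_i (x_i - m_x)(y_i - m_y)'` over paired samples.
#'
#' @param X,Y Paired samples x p and samples x q matrices.
#' @return p x q matrix.
#' @export
between_set_covariance <- function(X, Y) {
  assert_matrix(X); assert_matrix(Y)
  if (nrow(X) != nrow(Y))
    stopf("X and Y must have the same (paired) sample count")
  crossprod(sweep(X, 2, colMeans(X), "-"),
            sweep(Y, 2, colMeans(Y), "-")) / nrow(X)
}

#' @noRd
default_ridge <- function(S) {
  tr <- sum(diag(S))
  if (tr <= 0) 1e-8 else 1e-6 * tr / ncol(S)
}

# Cholesky factor of S + ridge*I with an actionable singularity error.
chol_ridge <- function(S, ridge, what) {
  Sr <- S + diag(ridge, ncol(S))
  tryCatch(chol(Sr), error = function(e)
    stopf(paste0("%s scatter matrix is singular; supply a positive ridge ",
                 "(argument `ridge`) to regularise it"), what))
}

# Fix column signs: largest-magnitude entry of each u column positive; v
# flipped together with u so the criterion value is preserved.
fix_signs <- function(U, V) {
  for (k in seq_len(ncol(U))) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  list(U = U, V = V)
}

#' Class-aware canonical correlation analysis of two feature sets
#'
#' Finds projection pairs `(u_k, v_k)` maximising the discriminant
#' criterion `u' S_bxy v / (u' S_Wx u * v' S_Wy v)` -- the between-set
#' covariance in the numerator against the within-class scatters of the two
#' sets in the denominator -- under the normalisation
#' `u' S_Wx u = v' S_Wy v = 1`. Solved as a whitened singular value
#' decomposition of the between-set covariance.
#'
#' @param X,Y Paired samples x p and samples x q matrices.
#' @param labels Class label per row (each class needs >= 2 samples).
#' @param d Number of projection pairs (default `min(p, q)`).
#' @param ridge Diagonal loading added to each within-class scatter;
#'   `NULL` uses `1e-6 * trace/p`. Set 0 to forbid regularisation.
#' @return Object of class `gcca_projection`: `U` (p x d), `V` (q x d),
#'   `correlations` (criterion value per column, non-increasing).
#' @export
solve_gcca <- function(X, Y, labels, d = NULL, ridge = NULL) {
  assert_matrix(X); assert_matrix(Y)
  if (nrow(X) != nrow(Y)) stopf("X and Y must be paired (same sample count)")
  labels <- factor(labels)
  if (any(table(labels) < 2)) stopf("every class needs >= 2 samples")
  p <- ncol(X); q <- ncol(Y)
  d <- as.integer(d %||% min(p, q))
  if (d < 1 || d > min(p, q)) stopf("d must be in 1..min(p, q)")
  Swx <- within_class_scatter(X, labels)
  Swy <- within_class_scatter(Y, labels)
  C <- between_set_covariance(X, Y)
  rx <- ridge %||% default_ridge(Swx)
  ry <- ridge %||% default_ridge(Swy)
  Ux <- chol_ridge(Swx, rx, "X within-class")
  Uy <- chol_ridge(Swy, ry, "Y within-class")
  M <- backsolve(Ux, C, transpose = TRUE)            # Ux^-T C
  A <- t(backsolve(Uy, t(M), transpose = TRUE))      # Ux^-T C Uy^-1
  sv <- svd(A, nu = d, nv = d)
  U <- backsolve(Ux, sv$u)
  V <- backsolve(Uy, sv$v)
  fx <- fix_signs(U, V)
  structure(list(U = fx$U, V = fx$V, correlations = sv$d[seq_len(d)],
                 d = d, ridge = c(x = rx, y = ry)),
            class = "gcca_projection")
}

#' Classical canonical correlation analysis (baseline)
#'
#' Whitened-SVD CCA on total (biased) covariances, ignoring class labels.
#' Rank-deficient sets are truncated to their numerical rank with a
#' warning.
#'
#' @inheritParams solve_gcca
#' @return Object of class `gcca_projection` whose `correlations` are the
#'   canonical correlations in `[0, 1]`, non-increasing.
#' @export
solve_cca <- function(X, Y, d = NULL) {
  assert_matrix(X); assert_matrix(Y)
  if (nrow(X) != nrow(Y)) stopf("X and Y must be paired (same sample count)")
  n <- nrow(X)
  whiten <- function(M, what) {
    S <- crossprod(sweep(M, 2, colMeans(M), "-")) / n
    e <- eigen(S, symmetric = TRUE)
    keep <- e$values > max(e$values, 0) * 1e-10
    if (!all(keep))
      warning(sprintf("%s is rank deficient; truncating to rank %d",
                      what, sum(keep)))
    e$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(e$values[keep]), sum(keep))
  }
  Wx <- whiten(X, "X"); Wy <- whiten(Y, "Y")
  A <- t(Wx) %*% between_set_covariance(X, Y) %*% Wy
  dmax <- min(ncol(Wx), ncol(Wy))
  d <- as.integer(d %||% dmax)
  if (d > dmax) {
    warning("d truncated to the available rank")
    d <- dmax
  }
  sv <- svd(A, nu = d, nv = d)
  fx <- fix_signs(Wx %*% sv$u, Wy %*% sv$v)
  structure(list(U = fx$U, V = fx$V,
                 correlations = pmin(pmax(sv$d[seq_len(d)], 0), 1),
                 d = d, ridge = c(x = 0, y = 0)),
            class = "gcca_projection")
}

#' Project paired feature sets onto canonical directions
#'
#' @param X,Y Paired feature matrices.
#' @param P A [solve_gcca()] / [solve_cca()] projection.
#' @return List with `Xs = X U` and `Ys = Y V`, each samples x d.
#' @export
project <- function(X, Y, P) {
  stopifnot(inherits(P, "gcca_projection"))
  if (ncol(X) != nrow(P$U) || ncol(Y) != nrow(P$V))
    stopf("feature dimensions do not match the projection")
  list(Xs = X %*% P$U, Ys = Y %*% P$V)
}

#' Fuse two projected feature sets
#'
#' Type I stacks the projected sets side by side (dimension `2d`); type II
#' sums them (dimension `d`).
#'
#' @param Xs,Ys Projected sets, samples x d each.
#' @param mode `"type1"` or `"type2"`.
#' @return Fused samples x (2d or d) matrix with a `mode` attribute.
#' @export
fuse <- function(Xs, Ys, mode = c("type1", "type2")) {
  mode <- match.arg(mode)
  if (nrow(Xs) != nrow(Ys) || ncol(Xs) != ncol(Ys))
    stopf("projected sets must have identical shape")
  Z <- if (mode == "type1") cbind(Xs, Ys) else Xs + Ys
  attr(Z, "mode") <- mode
  Z
}

#' Multiset class-aware canonical correlation fusion
#'
#' Extends the two-set analysis to `m >= 2` paired feature sets. The
#' default `"sumcor"` strategy solves one block generalised eigenproblem
#' (between-set covariances off the block diagonal, within-class scatters
#' on it), maximising the sum of pairwise criteria; `"pairwise"` fuses sets
#' (1,2) and (3,4)... by two-set analyses and then fuses the results
#' recursively.
#'
#' @param sets List of paired samples x p_i matrices.
#' @param labels Class label per sample (ignored when `within = "total"`).
#' @param d Components per set (default `min(p_i)`).
#' @param ridge As in [solve_gcca()].
#' @param ridge_frac Alternative relative regularisation: ridge set to
#'   `ridge_frac * trace(S_Wi)/p_i` per set (ignored when `ridge` is
#'   given).
#' @param strategy `"sumcor"` or `"pairwise"`.
#' @param mode Fusion mode for the returned fused matrix.
#' @param within `"class"` uses within-class scatters (class-aware);
#'   `"total"` uses total covariances (plain multiset CCA baseline).
#' @return Object of class `multiset_projection`: per-set projection
#'   matrices (`U`, sumcor only), `correlations` (per-component sum of
#'   pairwise criteria), `fused` matrix, and a replayable transform for new
#'   data via [apply_multiset()].
#' @export
multiset_gcca <- function(sets, labels = NULL, d = NULL, ridge = NULL,
                          ridge_frac = NULL,
                          strategy = c("sumcor", "pairwise"),
                          mode = c("type1", "type2"),
                          within = c("class", "total")) {
  strategy <- match.arg(strategy)
  mode <- match.arg(mode)
  within <- match.arg(within)
  if (!is.list(sets) || length(sets) < 2)
    stopf("need a list of >= 2 feature sets")
  ns <- vapply(sets, nrow, integer(1))
  if (length(unique(ns)) != 1) stopf("sets must be paired (equal row counts)")
  if (within == "class" && is.null(labels))
    stopf("labels are required for class-aware fusion")
  m <- length(sets)
  ps <- vapply(sets, ncol, integer(1))
  d <- as.integer(d %||% min(ps))
  if (d < 1 || d > min(ps)) stopf("d must be in 1..min(p_i)")

  if (strategy == "pairwise") return(
    multiset_pairwise(sets, labels, d, ridge, mode, within))

  n <- ns[1]
  Sw <- lapply(sets, function(X) {
    if (within == "class") within_class_scatter(X, labels)
    else crossprod(sweep(X, 2, colMeans(X), "-"))
  })
  ridges <- vapply(Sw, function(S) {
    ridge %||% (if (!is.null(ridge_frac))
      ridge_frac * sum(diag(S)) / ncol(S) else default_ridge(S))
  }, numeric(1))
  chols <- mapply(chol_ridge, Sw, ridges,
                  MoreArgs = list(what = "a set's within"), SIMPLIFY = FALSE)
  # whitened block matrix: zero diagonal, Ui^-T C_ij Uj^-1 off-diagonal
  ptot <- sum(ps)
  off <- cumsum(c(0, ps))
  B <- matrix(0, ptot, ptot)
  C <- vector("list", m * m)
  dim(C) <- c(m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i >= j) next
    Cij <- between_set_covariance(sets[[i]], sets[[j]])
    C[[i, j]] <- Cij
    Mij <- backsolve(chols[[i]], Cij, transpose = TRUE)
    Bij <- t(backsolve(chols[[j]], t(Mij), transpose = TRUE))
    B[(off[i] + 1):off[i + 1], (off[j] + 1):off[j + 1]] <- Bij
    B[(off[j] + 1):off[j + 1], (off[i] + 1):off[i + 1]] <- t(Bij)
  }
  e <- eigen(B, symmetric = TRUE)
  W <- e$vectors[, seq_len(d), drop = FALSE]
  U <- vector("list", m)
  for (i in seq_len(m)) {
    Wi <- W[(off[i] + 1):off[i + 1], , drop = FALSE]
    Ui <- backsolve(chols[[i]], Wi)
    # renormalise each column to u' S_W u = 1 where non-degenerate
    for (k in seq_len(d)) {
      qf <- drop(crossprod(Ui[, k], (Sw[[i]] +
                 diag(ridges[i], ps[i])) %*% Ui[, k]))
      if (qf > 1e-12) Ui[, k] <- Ui[, k] / sqrt(qf)
    }
    U[[i]] <- Ui
  }
  # sign convention anchored on the first set
  for (k in seq_len(d)) {
    i0 <- which.max(abs(U[[1]][, k]))
    if (U[[1]][i0, k] < 0) for (i in seq_len(m)) U[[i]][, k] <- -U[[i]][, k]
  }
  corr <- vapply(seq_len(d), function(k) {
    s <- 0
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i >= j) next
      s <- s + drop(crossprod(U[[i]][, k], C[[i, j]] %*% U[[j]][, k]))
    }
    s
  }, numeric(1))
  blocks <- lapply(seq_len(m), function(i) sets[[i]] %*% U[[i]])
  fused <- fuse_blocks(blocks, mode)
  structure(list(U = U, correlations = corr, fused = fused, d = d,
                 mode = mode, strategy = "sumcor", within = within,
                 channel_blocks = rep(seq_len(m),
                                      each = if (mode == "type1") d else 0),
                 ridges = ridges),
            class = "multiset_projection")
}

# Pairwise-sequential reduction: fuse adjacent pairs, recurse.
multiset_pairwise <- function(sets, labels, d, ridge, mode, within) {
  solve2 <- function(X, Y) {
    if (within == "class") solve_gcca(X, Y, labels, d = min(d, ncol(X),
                                      ncol(Y)), ridge = ridge)
    else solve_cca(X, Y, d = min(d, ncol(X), ncol(Y)))
  }
  steps <- list()
  level <- sets
  while (length(level) > 1) {
    nxt <- list()
    lv_steps <- list()
    i <- 1
    while (i <= length(level)) {
      if (i == length(level)) {       # odd set passes through
        nxt[[length(nxt) + 1]] <- level[[i]]
        lv_steps[[length(lv_steps) + 1]] <- list(pass = TRUE)
      } else {
        P <- solve2(level[[i]], level[[i + 1]])
        pr <- project(level[[i]], level[[i + 1]], P)
        nxt[[length(nxt) + 1]] <- fuse(pr$Xs, pr$Ys, mode)
        lv_steps[[length(lv_steps) + 1]] <- list(pass = FALSE, P = P)
      }
      i <- i + 2
    }
    steps[[length(steps) + 1]] <- lv_steps
    level <- nxt
  }
  top_corr <- steps[[1]][[1]]$P$correlations
  structure(list(steps = steps, correlations = top_corr,
                 fused = level[[1]], d = ncol(level[[1]]), mode = mode,
                 strategy = "pairwise", within = within),
            class = "multiset_projection")
}

#' @noRd
fuse_blocks <- function(blocks, mode) {
  if (mode == "type1") do.call(cbind, blocks) else Reduce(`+`, blocks)
}

#' Apply a fitted multiset projection to new paired sets
#'
#' @param P A [multiset_gcca()] result.
#' @param sets List of new feature sets matching the training layout.
#' @return Fused feature matrix for the new samples.
#' @export
apply_multiset <- function(P, sets) {
  stopifnot(inherits(P, "multiset_projection"))
  if (P$strategy == "sumcor") {
    if (length(sets) != length(P$U)) stopf("set count mismatch")
    blocks <- lapply(seq_along(sets), function(i) sets[[i]] %*% P$U[[i]])
    return(fuse_blocks(blocks, P$mode))
  }
  level <- sets
  for (lv_steps in P$steps) {
    nxt <- list()
    i <- 1
    for (stp in lv_steps) {
      if (isTRUE(stp$pass)) {
        nxt[[length(nxt) + 1]] <- level[[i]]
        i <- i + 1
      } else {
        pr <- project(level[[i]], level[[i + 1]], stp$P)
        nxt[[length(nxt) + 1]] <- fuse(pr$Xs, pr$Ys, P$mode)
        i <- i + 2
      }
    }
    level <- nxt
  }
  level[[1]]
}

#' Per-channel projected blocks of a sumcor multiset projection
#' @noRd
project_blocks <- function(P, sets) {
  stopifnot(P$strategy == "sumcor")
  lapply(seq_along(sets), function(i) sets[[i]] %*% P$U[[i]])
}
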