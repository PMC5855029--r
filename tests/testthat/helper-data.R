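# Shared fixtures, all generated in code under fixed seeds.

# Gaussian class blobs: K classes, n_per samples each, dim d, centres at
# distance ~sep from the origin.
make_blobs <- function(n_per, K, d = 3, sep = 6, seed = 1) {
  set.seed(seed)
  # well-spread centres: greedy farthest-point selection from a pool so
  # every pair of blobs is separated by a comparable distance
  pool <- matrix(stats::rnorm(200 * d), 200, d)
  pool <- sep * pool / sqrt(rowSums(pool^2))
  idx <- sample.int(200, 1)
  while (length(idx) < K) {
    d2 <- apply(as.matrix(stats::dist(rbind(pool[idx, , drop = FALSE],
                                            pool)))[-seq_along(idx),
                                                    seq_along(idx),
                                                    drop = FALSE],
                1, min)
    idx <- c(idx, which.max(d2))
  }
  centers <- pool[idx, , drop = FALSE]
  X <- do.call(rbind, lapply(seq_len(K), function(k)
    matrix(stats::rnorm(n_per * d), n_per, d) +
      centers[rep(k, n_per), , drop = FALSE]))
  list(X = X, y = factor(rep(seq_len(K), each = n_per)))
}

# A paired two-view instance with class structure in both views.
make_paired_views <- function(n_per = 10, K = 3, p = 3, q = 3, seed = 1) {
  set.seed(seed)
  y <- rep(seq_len(K), each = n_per)
  X <- matrix(stats::rnorm(n_per * K * p), ncol = p) +
    outer(y, seq_len(p)) * 0.5
  Y <- matrix(stats::rnorm(n_per * K * q), ncol = q) +
    outer(y, rev(seq_len(q))) * 0.3
  list(X = X, Y = Y, y = factor(y))
}

# Planted GA instance: 4 informative columns carrying class-mean structure
# plus 8 pure-noise columns; 8 classes, n = 400.
make_planted_ga <- function(seed = 1, n_per = 50, K = 8,
                            n_inf = 4, n_noise = 8) {
  set.seed(seed)
  y <- rep(seq_len(K), each = n_per)
  inf <- sapply(seq_len(n_inf), function(j) {
    mu <- stats::rnorm(K, sd = 2)
    mu[y] + stats::rnorm(length(y))
  })
  Z <- cbind(inf, matrix(stats::rnorm(length(y) * n_noise),
                         ncol = n_noise))
  list(Z = Z, y = factor(y), informative = seq_len(n_inf))
}

# Exhaustive Fisher-criterion optimum over all non-empty masks of a
# small instance (independent oracle for the GA). Scatters are computed
# once; each mask costs one small solve.
exhaustive_fisher_best <- function(Z, y, dim_penalty = 2) {
  L <- ncol(Z)
  y <- factor(y)
  sc <- semgfusion:::class_scatters(Z, y)
  ridge <- semgfusion:::default_ridge(sc$Sw) + 1e-12
  col_penalty <- dim_penalty * (nlevels(y) - 1) / nrow(Z)
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), L)))[-1, ]
  fits <- apply(masks, 1, function(m) {
    idx <- which(m)
    semgfusion:::fisher_trace(sc$Sw[idx, idx, drop = FALSE],
                              sc$Sb[idx, idx, drop = FALSE], ridge) -
      col_penalty * length(idx)
  })
  list(fitness = max(fits), mask = masks[which.max(fits), ])
}

# A hand-made multi-channel feature_set (bypasses signal synthesis) with
# class structure shared across channels plus channel-specific noise.
make_fake_feature_set <- function(n_per = 12, K = 8, n_channels = 4,
                                  p = 6, sep = 3, seed = 1) {
  set.seed(seed)
  y <- factor(rep(seq_len(K), each = n_per))
  shared <- matrix(stats::rnorm(K * p), K, p) * sep
  sets <- lapply(seq_len(n_channels), function(ch) {
    gain <- stats::runif(1, 0.5, 1.5)
    shared[as.integer(y), , drop = FALSE] * gain +
      matrix(stats::rnorm(length(y) * p), ncol = p)
  })
  names(sets) <- paste0("ch", seq_len(n_channels))
  structure(list(sets = sets, labels = y, config = NULL),
            class = "feature_set")
}

# Independent maximiser of the two-set discriminant criterion
# u'Cv / (u'Swx u * v'Swy v): vectorised random restarts under the unit
# quadratic-form normalisation, then local refinement with optim().
brute_force_gcca <- function(Swx, Swy, C, n_restarts = 10000, seed = 1) {
  p <- ncol(Swx); q <- ncol(Swy)
  set.seed(seed)
  U <- matrix(stats::rnorm(p * n_restarts), p)
  V <- matrix(stats::rnorm(q * n_restarts), q)
  U <- sweep(U, 2, sqrt(colSums(U * (Swx %*% U))), "/")
  V <- sweep(V, 2, sqrt(colSums(V * (Swy %*% V))), "/")
  vals <- abs(colSums(U * (C %*% V)))
  i0 <- which.max(vals)
  f <- function(th) {
    u <- th[1:p]; v <- th[(p + 1):(p + q)]
    nu <- sqrt(drop(crossprod(u, Swx %*% u)))
    nv <- sqrt(drop(crossprod(v, Swy %*% v)))
    if (nu < 1e-12 || nv < 1e-12) return(0)
    -abs(drop(crossprod(u, C %*% v))) / (nu * nv)
  }
  opt <- stats::optim(c(U[, i0], V[, i0]), f, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  -opt$value
}

# Cache of synthetic end-to-end feature sets shared across test blocks
# (feature extraction is the expensive step; the same seeded datasets back
# several directional checks).
.e2e_cache <- new.env(parent = emptyenv())

e2e_feature_set <- function(s, n_channels = 4, n_trials_per_class = 12) {
  key <- sprintf("s%d_c%d_n%d", s, n_channels, n_trials_per_class)
  if (!is.null(.e2e_cache[[key]])) return(.e2e_cache[[key]])
  scfg <- synth_config(n_trials_per_class = n_trials_per_class,
                       n_channels = n_channels,
                       seed = semgfusion:::mix_seed(42, s))
  fs <- extract_feature_set(generate_dataset(scfg))
  .e2e_cache[[key]] <- fs
  fs
}
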