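#' Fuzzy c-means clustering
#'
#' Standard alternating updates of memberships and centres minimising the
#' membership-weighted squared-distance objective. The recorded objective
#' trace is non-increasing; iteration stops when the objective change drops
#' below `tol` or at `max_iter`.
#'
#' @param Z Samples x dim matrix.
#' @param c Number of clusters (`1 <= c <= nrow(Z)`).
#' @param fuzzifier Fuzziness exponent m (> 1).
#' @param tol Absolute objective-change tolerance.
#' @param max_iter Iteration cap.
#' @param seed Seed for the centre initialisation (sampled data rows).
#' @return Object of class `fcm_result`: `centers` (c x dim),
#'   `memberships` (samples x c, rows sum to 1), `objective_trace`,
#'   `hard_labels`.
#' @export
fcm <- function(Z, c, fuzzifier = 2, tol = 1e-5, max_iter = 300, seed = 1) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (c < 1) stopf("c must be >= 1")
  if (c > n) stopf("cannot form %d clusters from %d samples", c, n)
  if (fuzzifier <= 1) stopf("fuzzifier must exceed 1")
  m <- fuzzifier
  sq_dist <- function(centers) {
    # n x c matrix of squared Euclidean distances
    d2 <- outer(rowSums(Z^2), rep(1, nrow(centers))) -
      2 * Z %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    pmax(d2, 0)
  }
  memberships <- function(d2) {
    u <- matrix(0, n, c)
    zero <- d2 < 1e-12
    has_zero <- rowSums(zero) > 0
    if (any(has_zero))
      u[has_zero, ] <- zero[has_zero, , drop = FALSE] /
        rowSums(zero[has_zero, , drop = FALSE])
    if (any(!has_zero)) {
      w <- d2[!has_zero, , drop = FALSE]^(-1 / (m - 1))
      u[!has_zero, ] <- w / rowSums(w)
    }
    u
  }
  # farthest-point initialisation: random first centre, then rows
  # maximising the minimum distance to the centres chosen so far; avoids
  # collapsed initialisations on well-separated data
  init_centers <- function() {
    idx <- sample.int(n, 1)
    if (c > 1) for (k in 2:c) {
      d2min <- apply(sq_dist(Z[idx, , drop = FALSE]), 1, min)
      d2min[idx] <- -1
      idx <- c(idx, which.max(d2min))
    }
    Z[idx, , drop = FALSE]
  }
  local_seed(seed, {
    centers <- init_centers()
    trace <- numeric(0)
    J_prev <- Inf
    for (it in seq_len(max_iter)) {
      u <- memberships(sq_dist(centers))
      um <- u^m
      cs <- colSums(um)
      dead <- cs < 1e-12
      if (any(dead)) {          # re-seed empty clusters deterministically
        centers[dead, ] <- Z[sample.int(n, sum(dead)), , drop = FALSE]
        u <- memberships(sq_dist(centers))
        um <- u^m
        cs <- colSums(um)
      }
      centers <- (t(um) %*% Z) / cs
      J <- sum(um * sq_dist(centers))
      trace <- c(trace, J)
      if (is.finite(J_prev) && abs(J_prev - J) < tol) break
      J_prev <- J
    }
    hard <- max.col(u, ties.method = "first")
    structure(list(centers = centers, memberships = u,
                   objective_trace = trace, hard_labels = hard,
                   iterations = length(trace), fuzzifier = m),
              class = "fcm_result")
  })
}

#' Davies-Bouldin index
#'
#' `DBI = (1/K) * sum_i max_{j != i} (S_i + S_j) / d_ij` with `S_i` the mean
#' Euclidean distance of cluster-i members to their centroid and `d_ij` the
#' centroid distance. Smaller values indicate tighter, better-separated
#' clusters. Scale-invariant (a ratio of distances).
#'
#' @param Z Samples x dim matrix.
#' @param labels Cluster assignment per row (>= 2 non-empty clusters).
#' @return Object of class `dbi_result`: `K`, `S` (dispersions), `D`
#'   (pairwise centroid distances), `value`.
#' @export
dbi <- function(Z, labels) {
  Z <- as.matrix(Z)
  if (!is.factor(labels)) labels <- factor(labels)
  K <- nlevels(labels)
  if (K < 2) stopf("DBI needs K >= 2 clusters")
  counts <- table(labels)
  if (any(counts == 0))
    stopf("cluster '%s' is empty", names(counts)[which(counts == 0)[1]])
  cent <- t(sapply(levels(labels), function(cl)
    colMeans(Z[labels == cl, , drop = FALSE])))
  if (ncol(Z) == 1) cent <- matrix(cent, ncol = 1)
  S <- vapply(seq_len(K), function(i) {
    Zi <- Z[labels == levels(labels)[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(Zi, 2, cent[i, ], "-")^2)))
  }, numeric(1))
  D <- as.matrix(stats::dist(cent))
  R <- vapply(seq_len(K), function(i)
    max(((S[i] + S[-i]) / D[i, -i])), numeric(1))
  structure(list(K = K, S = S, D = D, value = mean(R)),
            class = "dbi_result")
}

#' Davies-Bouldin curve over a range of cluster counts
#'
#' Runs fuzzy c-means for each `K` and scores the hard partition with
#' [dbi()]. Initialisations that leave a cluster empty are retried with a
#' shifted seed (up to 5 times).
#'
#' In high-dimensional spaces the fuzzifier-2 membership profile flattens
#' and hard clusters can collapse; when every seeded retry leaves a cluster
#' empty the sweep progressively lowers the fuzzifier towards 1 (the
#' k-means limit) until a complete partition is obtained.
#'
#' @param Z Samples x dim matrix.
#' @param K_range Candidate cluster counts (default 2..10).
#' @param fuzzifier,tol,max_iter,seed Passed to [fcm()].
#' @param fallback_fuzzifiers Decreasing fuzzifiers tried (in order) when
#'   the configured one cannot fill all K hard clusters.
#' @return Data frame with columns `K` and `dbi`.
#' @export
dbi_sweep <- function(Z, K_range = 2:10, fuzzifier = 2, tol = 1e-5,
                      max_iter = 300, seed = 1,
                      fallback_fuzzifiers = c(1.6, 1.3, 1.15)) {
  Z <- as.matrix(Z)
  if (max(K_range) > nrow(Z)) stopf("max K exceeds the sample count")
  vals <- vapply(K_range, function(K) {
    for (fz in c(fuzzifier, fallback_fuzzifiers)) {
      for (attempt in 0:2) {
        f <- fcm(Z, K, fz, tol, max_iter,
                 seed = mix_seed(seed, K, attempt))
        if (length(unique(f$hard_labels)) == K)
          return(dbi(Z, f$hard_labels)$value)
      }
    }
    stopf("FCM produced an empty cluster for K = %d in every retry", K)
  }, numeric(1))
  data.frame(K = as.integer(K_range), dbi = vals)
}
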