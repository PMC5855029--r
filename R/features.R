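#' Configuration of the per-channel feature set
#'
#' The per-channel feature vector has 12 components in fixed order: Wilson
#' amplitude (1), fuzzy entropy (1), permutation entropy (1), third-order-
#' cumulant autoregressive coefficients (4), and wavelet-band energies
#' (4 detail bands + 1 approximation = 5). Thresholds expressed as fractions
#' of the per-signal standard deviation make the set scale-adaptive.
#'
#' @param wamp_threshold Wilson-amplitude threshold as a fraction of the
#'   signal SD.
#' @param fe_m,fe_r,fe_n Fuzzy-entropy embedding dimension, tolerance
#'   (fraction of SD), and fuzzy-power exponent.
#' @param pe_order,pe_delay Permutation-entropy order and delay.
#' @param ar_order Order of the cumulant-based AR fit (4 keeps the vector at
#'   12 components).
#' @param wavelet Wavelet name; only the orthonormal Daubechies `"db4"`
#'   filter is built in.
#' @param wavelet_levels Decomposition depth (4 gives 5 band energies).
#' @param features Subset of `c("wamp","fe","pe","arcu","ewt")` to compute;
#'   the default computes the full 12-dimensional set.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(wamp_threshold = 0.05, fe_m = 2, fe_r = 0.2,
                           fe_n = 2, pe_order = 3, pe_delay = 1,
                           ar_order = 4, wavelet = "db4",
                           wavelet_levels = 4,
                           features = c("wamp", "fe", "pe", "arcu", "ewt")) {
  features <- match.arg(features, c("wamp", "fe", "pe", "arcu", "ewt"),
                        several.ok = TRUE)
  if (wamp_threshold < 0) stopf("wamp_threshold must be >= 0")
  if (fe_r <= 0) stopf("fe_r must be positive")
  if (pe_order < 2) stopf("pe_order must be >= 2")
  structure(list(wamp_threshold = wamp_threshold, fe_m = as.integer(fe_m),
                 fe_r = fe_r, fe_n = fe_n, pe_order = as.integer(pe_order),
                 pe_delay = as.integer(pe_delay),
                 ar_order = as.integer(ar_order), wavelet = wavelet,
                 wavelet_levels = as.integer(wavelet_levels),
                 features = features),
            class = "feature_config")
}

#' Wilson amplitude
#'
#' Number of consecutive-sample absolute differences exceeding a threshold;
#' a time-domain measure of muscle-contraction activity.
#'
#' @param x Numeric signal of length >= 2.
#' @param threshold Non-negative amplitude threshold (absolute units).
#' @return Integer count in `[0, length(x) - 1]`.
#' @export
wamp <- function(x, threshold) {
  if (length(x) < 2) stopf("wamp needs a signal of length >= 2")
  if (threshold < 0) stopf("threshold must be >= 0")
  sum(abs(diff(x)) > threshold)
}

#' Fuzzy entropy
#'
#' Negative log ratio of average exponential similarity degrees of
#' mean-centred embedding templates at dimensions `m` and `m + 1`, with
#' fuzzy membership `exp(-(d/r)^n)` of the Chebyshev template distance `d`.
#'
#' @param x Numeric signal.
#' @param m Embedding dimension.
#' @param r Tolerance; interpreted as a fraction of `sd(x)` when
#'   `relative = TRUE` (making the result invariant to affine rescaling of
#'   the signal), otherwise absolute.
#' @param n Fuzzy-power exponent.
#' @param relative Whether `r` scales with the signal SD.
#' @return Non-negative real; 0 for a constant signal.
#' @export
fuzzy_entropy <- function(x, m = 2, r = 0.2, n = 2, relative = TRUE) {
  if (r <= 0) stopf("tolerance r must be positive")
  if (length(x) <= m + 1) stopf("signal too short for embedding dimension m")
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps) return(0)
  r_abs <- if (relative) r * s else r
  phi <- fe_phi_pair(as.numeric(x), as.integer(m), r_abs, n)
  if (any(phi <= 0))
    stopf("degenerate similarity (tolerance r too small)")
  max(0, log(phi[1]) - log(phi[2]))
}

#' Permutation entropy
#'
#' Shannon entropy (natural log) of the distribution of ordinal patterns of
#' embedded subsequences (Bandt-Pompe). Bounded by `log(factorial(order))`.
#'
#' @param x Numeric signal.
#' @param order Pattern order (>= 2).
#' @param delay Embedding delay.
#' @return Value in `[0, log(factorial(order))]`.
#' @export
permutation_entropy <- function(x, order = 3, delay = 1) {
  if (order < 2) stopf("order must be >= 2")
  if (delay < 1) stopf("delay must be >= 1")
  n <- length(x)
  n_pat <- n - (order - 1) * delay
  if (n_pat < 1) stopf("signal too short for order/delay")
  emb <- sapply(seq_len(order), function(k) x[(1:n_pat) + (k - 1) * delay])
  if (n_pat == 1) emb <- matrix(emb, nrow = 1)
  # ordinal rank of each column among the `order` columns, ties broken by
  # column index; encode the rank vector as an integer pattern id
  id <- integer(n_pat)
  for (j in seq_len(order)) {
    rj <- rep(0L, n_pat)
    for (k in seq_len(order)) {
      if (k == j) next
      rj <- rj + (emb[, k] < emb[, j]) + (emb[, k] == emb[, j] & k < j)
    }
    id <- id * order + rj
  }
  p <- tabulate(match(id, unique(id)))
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Autoregressive coefficients from third-order cumulants
#'
#' Fits an AR(`order`) model using moment equations built from the diagonal
#' third-order cumulant slices `E[x_t^2 x_{t+s}]` and `E[x_t x_{t+s}^2]`,
#' solved in the least-squares sense. Because third-order cumulants of
#' Gaussian noise vanish, the estimate is insensitive to additive Gaussian
#' disturbance; it requires skewed innovations to be identifiable.
#'
#' @param x Numeric signal (length well above `50 * order` recommended).
#' @param order AR order (default 4).
#' @param n_eq Number of moment equations (default `3 * order`).
#' @return Numeric vector of `order` coefficients `a` in
#'   `x_t = a_1 x_{t-1} + ... + a_p x_{t-p} + e_t`.
#' @export
arcu <- function(x, order = 4, n_eq = 3 * order) {
  if (order < 1) stopf("order must be >= 1")
  if (length(x) < 10 * order)
    stopf("signal too short for cumulant AR estimation")
  if (stats::sd(x) < .Machine$double.eps)
    stopf("degenerate (zero-variance) signal")
  x <- x - mean(x)
  N <- length(x)
  # h(s) = E[x_t^2 x_{t+s}], g(s) = E[x_t x_{t+s}^2], s >= 0
  max_s <- n_eq
  h <- sapply(0:max_s, function(s) mean(x[1:(N - s)]^2 * x[(1 + s):N]))
  g <- sapply(0:max_s, function(s) mean(x[1:(N - s)] * x[(1 + s):N]^2))
  H <- function(s) if (s >= 0) h[s + 1] else g[-s + 1]
  A <- matrix(0, n_eq, order)
  b <- numeric(n_eq)
  for (tau in seq_len(n_eq)) {
    b[tau] <- h[tau + 1]
    for (k in seq_len(order)) A[tau, k] <- H(tau - k)
  }
  a <- tryCatch(qr.solve(A, b),
                error = function(e) stopf("cumulant system is singular"))
  if (any(!is.finite(a))) stopf("cumulant AR estimation failed")
  as.numeric(a)
}

# Daubechies db4 (8-tap) orthonormal scaling filter.
db4_filter <- function() {
  c(0.230377813308855, 0.714846570552542, 0.630880767929590,
    -0.027983769416984, -0.187034811718881, 0.030841381835987,
    0.032883011666983, -0.010597401784997)
}

# One level of the periodic orthonormal DWT: returns approximation and
# detail, each half the input length (input length must be even).
dwt_step <- function(a, h) {
  n <- length(a)
  g <- rev(h) * (-1)^(seq_along(h) - 1)   # quadrature mirror filter
  L <- length(h)
  idx <- outer(seq(0, n - 2, by = 2), seq_len(L) - 1, "+") %% n + 1
  A <- matrix(a[idx], ncol = L)
  list(approx = as.numeric(A %*% h), detail = as.numeric(A %*% g))
}

#' Wavelet-band energies
#'
#' Energies of the detail bands at levels `1..levels` and of the final
#' approximation band of a periodic orthonormal discrete wavelet transform
#' (Daubechies db4). With 4 levels this yields 5 energies whose sum equals
#' the signal energy (Parseval).
#'
#' @param x Numeric signal; length must be divisible by `2^levels`.
#' @param wavelet Wavelet name (only `"db4"` available).
#' @param levels Decomposition depth.
#' @return Numeric vector of `levels + 1` non-negative energies, ordered
#'   detail level 1..`levels` then approximation.
#' @export
ewt <- function(x, wavelet = "db4", levels = 4) {
  if (wavelet != "db4") stopf("only the db4 wavelet is built in")
  if (levels < 1) stopf("levels must be >= 1")
  n <- length(x)
  if (n < 2^levels || n %% 2^levels != 0)
    stopf("signal length must be a positive multiple of 2^levels")
  h <- db4_filter()
  energies <- numeric(levels + 1)
  a <- as.numeric(x)
  for (lv in seq_len(levels)) {
    st <- dwt_step(a, h)
    energies[lv] <- sum(st$detail^2)
    a <- st$approx
  }
  energies[levels + 1] <- sum(a^2)
  energies
}

#' Extract the per-channel feature vectors of one trial
#'
#' Applies the configured feature set to the whole trial (no sub-windowing),
#' one 12-dimensional vector per channel.
#'
#' @param trial An `semg_trial`.
#' @param cfg A [feature_config()].
#' @return Matrix channels x features with named rows and columns.
#' @export
extract_features <- function(trial, cfg = feature_config()) {
  stopifnot(inherits(trial, "semg_trial"), inherits(cfg, "feature_config"))
  rows <- lapply(seq_len(nrow(trial$samples)), function(ch) {
    x <- trial$samples[ch, ]
    ch_name <- trial$channel_names[ch]
    tryCatch({
      out <- c()
      if ("wamp" %in% cfg$features)
        out <- c(out, WAMP = wamp(x, cfg$wamp_threshold * stats::sd(x)))
      if ("fe" %in% cfg$features)
        out <- c(out, FE = fuzzy_entropy(x, cfg$fe_m, cfg$fe_r, cfg$fe_n))
      if ("pe" %in% cfg$features)
        out <- c(out, PE = permutation_entropy(x, cfg$pe_order, cfg$pe_delay))
      if ("arcu" %in% cfg$features) {
        a <- arcu(x, cfg$ar_order)
        names(a) <- paste0("ARCU", seq_along(a))
        out <- c(out, a)
      }
      if ("ewt" %in% cfg$features) {
        e <- ewt(x, cfg$wavelet, cfg$wavelet_levels)
        names(e) <- paste0("EWT", seq_along(e))
        out <- c(out, e)
      }
      out
    }, error = function(e)
      stopf("feature extraction failed on channel %s: %s", ch_name,
            conditionMessage(e)))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- trial$channel_names
  m
}

#' Extract features for every trial of a dataset
#'
#' @param ds An `semg_dataset` (or list of `semg_trial`).
#' @param cfg A [feature_config()].
#' @return An object of class `feature_set`: list with `sets` (named list,
#'   one trials x features matrix per channel), `labels` (factor), and the
#'   config echo.
#' @export
extract_feature_set <- function(ds, cfg = feature_config()) {
  trials <- if (inherits(ds, "semg_dataset")) ds$trials else ds
  stopifnot(length(trials) >= 1)
  per_trial <- lapply(trials, extract_features, cfg = cfg)
  channels <- rownames(per_trial[[1]])
  sets <- lapply(seq_along(channels), function(ch)
    do.call(rbind, lapply(per_trial, function(m) m[ch, ])))
  names(sets) <- channels
  labels <- factor(vapply(trials, function(tr) tr$label, character(1)),
                   levels = intersect(activity_classes(),
                                      unique(vapply(trials, `[[`,
                                                    character(1), "label"))))
  structure(list(sets = sets, labels = labels, config = cfg),
            class = "feature_set")
}

#' Write a feature set as one wide CSV
#'
#' Columns are named `<channel>_<feature>` (for example `ch1_WAMP`,
#' `ch1_EWT5`), plus a final `label` column.
#'
#' @param fs A [extract_feature_set()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_set <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  wide <- do.call(cbind, lapply(names(fs$sets), function(ch) {
    m <- fs$sets[[ch]]
    colnames(m) <- paste0(ch, "_", colnames(m))
    m
  }))
  df <- as.data.frame(wide)
  df$label <- as.character(fs$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
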