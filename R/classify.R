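#' Radial basis function kernel
#'
#' `K(x, x_i) = exp(-|x - x_i|^2 / sigma^2)`, where `sigma` is the kernel
#' width.
#'
#' @param x,xi Numeric vectors.
#' @param sigma Positive kernel width.
#' @return Value in `(0, 1]`.
#' @export
rbf_kernel <- function(x, xi, sigma) {
  if (sigma <= 0) stopf("sigma must be positive")
  exp(-sum((x - xi)^2) / sigma^2)
}

#' SVM / PSO configuration
#'
#' @param sigma RBF width; `NULL` uses the median heuristic (median pairwise
#'   training distance) per fit.
#' @param cost Soft-margin penalty.
#' @param pso Either `NULL` (no tuning) or a list as returned by
#'   [pso_config()]; when set, `sigma` and `cost` are tuned per training
#'   fold by particle swarm optimisation.
#' @return Object of class `svm_config`.
#' @export
svm_config <- function(sigma = NULL, cost = 10, pso = NULL) {
  if (!is.null(sigma) && sigma <= 0) stopf("sigma must be positive")
  if (cost <= 0) stopf("cost must be positive")
  structure(list(sigma = sigma, cost = cost, pso = pso),
            class = "svm_config")
}

#' Particle swarm configuration for SVM hyperparameter search
#'
#' Particles move in `(log10 sigma, log10 cost)` space; the objective is
#' inner stratified cross-validation accuracy on the training split.
#'
#' @param swarm_size,iterations Swarm size and iteration count.
#' @param inertia,cognitive,social Standard PSO coefficients.
#' @param sigma_bounds Multiplicative log10 bounds around the median-
#'   heuristic sigma.
#' @param cost_bounds log10 bounds for the cost.
#' @param inner_folds Folds of the inner CV objective.
#' @param seed Integer seed.
#' @return List of class `pso_config`.
#' @export
pso_config <- function(swarm_size = 15, iterations = 20, inertia = 0.7,
                       cognitive = 1.5, social = 1.5,
                       sigma_bounds = c(-2, 2), cost_bounds = c(-1, 3),
                       inner_folds = 3, seed = 1) {
  if (diff(range(sigma_bounds)) <= 0 || diff(range(cost_bounds)) <= 0)
    stopf("empty hyperparameter bounds")
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations), inertia = inertia,
                 cognitive = cognitive, social = social,
                 sigma_bounds = sigma_bounds, cost_bounds = cost_bounds,
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "pso_config")
}

#' @noRd
median_heuristic_sigma <- function(X, max_rows = 400, seed = 17) {
  n <- nrow(X)
  idx <- if (n > max_rows)
    local_seed(seed, sample.int(n, max_rows)) else seq_len(n)
  d <- stats::median(stats::dist(X[idx, , drop = FALSE]))
  if (!is.finite(d) || d <= 0) 1 else d
}

# One-vs-rest RBF-SVM ensemble over e1071 binary machines. Decision-value
# orientation is read from the libsvm column name ("pos/neg" vs "neg/pos").
fit_ovr_svm <- function(X, y, sigma, cost) {
  y <- factor(y)
  models <- lapply(levels(y), function(cl) {
    yy <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(X, yy, kernel = "radial", gamma = 1 / sigma^2, cost = cost,
               scale = FALSE)
  })
  structure(list(models = models, classes = levels(y), sigma = sigma,
                 cost = cost),
            class = "ovr_svm")
}

#' @noRd
predict_ovr <- function(fit, X) {
  scores <- sapply(seq_along(fit$models), function(i) {
    p <- predict(fit$models[[i]], X, decision.values = TRUE)
    dv <- attr(p, "decision.values")
    sgn <- if (startsWith(colnames(dv)[1], "pos")) 1 else -1
    sgn * dv[, 1]
  })
  if (nrow(X) == 1) scores <- matrix(scores, nrow = 1)
  factor(fit$classes[max.col(scores, ties.method = "first")],
         levels = fit$classes)
}

#' @noRd
stratified_folds <- function(labels, k, seed) {
  labels <- factor(labels)
  if (any(table(labels) < k))
    stopf("a class has fewer than %d samples; use a smaller k", k)
  fold <- integer(length(labels))
  local_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  fold
}

# Inner-CV accuracy of a fixed (sigma, cost) on standardised features.
inner_cv_accuracy <- function(X, y, sigma, cost, folds) {
  acc <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- fit_ovr_svm(X[tr, , drop = FALSE], y[tr], sigma, cost)
    pred <- predict_ovr(fit, X[!tr, , drop = FALSE])
    acc <- acc + sum(pred == y[!tr])
  }
  acc / length(y)
}

#' Tune RBF-SVM hyperparameters by particle swarm optimisation
#'
#' @param X Standardised training features.
#' @param y Training labels.
#' @param cfg A [pso_config()].
#' @return List with `sigma`, `cost`, `accuracy` (best inner-CV accuracy)
#'   and `trace` (global-best accuracy per iteration, non-decreasing).
#' @export
pso_tune <- function(X, y, cfg = pso_config()) {
  stopifnot(inherits(cfg, "pso_config"))
  X <- as.matrix(X)
  y <- factor(y)
  sig0 <- log10(median_heuristic_sigma(X))
  lo <- c(sig0 + cfg$sigma_bounds[1], cfg$cost_bounds[1])
  hi <- c(sig0 + cfg$sigma_bounds[2], cfg$cost_bounds[2])
  folds <- stratified_folds(y, cfg$inner_folds, seed = cfg$seed)
  obj <- function(theta)
    inner_cv_accuracy(X, y, 10^theta[1], 10^theta[2], folds)
  local_seed(mix_seed(cfg$seed, 211), {
    S <- cfg$swarm_size
    pos <- cbind(stats::runif(S, lo[1], hi[1]), stats::runif(S, lo[2], hi[2]))
    vel <- matrix(0, S, 2)
    pbest <- pos
    pval <- apply(pos, 1, obj)
    g <- which.max(pval)
    gbest <- pbest[g, ]
    gval <- pval[g]
    trace <- numeric(cfg$iterations)
    for (it in seq_len(cfg$iterations)) {
      r1 <- matrix(stats::runif(S * 2), S, 2)
      r2 <- matrix(stats::runif(S * 2), S, 2)
      vel <- cfg$inertia * vel +
        cfg$cognitive * r1 * (pbest - pos) +
        cfg$social * r2 * sweep(pos, 2, gbest, function(p, g) g - p)
      pos <- pos + vel
      pos[, 1] <- pmin(pmax(pos[, 1], lo[1]), hi[1])
      pos[, 2] <- pmin(pmax(pos[, 2], lo[2]), hi[2])
      val <- apply(pos, 1, obj)
      upd <- val > pval
      pbest[upd, ] <- pos[upd, , drop = FALSE]
      pval[upd] <- val[upd]
      g <- which.max(pval)
      if (pval[g] > gval) {
        gval <- pval[g]
        gbest <- pbest[g, ]
      }
      trace[it] <- gval
    }
    list(sigma = 10^gbest[1], cost = 10^gbest[2], accuracy = gval,
         trace = trace)
  })
}

#' Per-class sensitivity and specificity from a confusion matrix
#'
#' One-vs-rest: `SEN = TP / (TP + FN)`, `SPE = TN / (TN + FP)`; rows of the
#' confusion matrix are true classes, columns predictions.
#'
#' @param confusion Square count matrix.
#' @param cls Optional class name or index; default returns all classes.
#' @return Matrix with columns `sen` and `spe` (fractions), one row per
#'   class (or the requested class).
#' @export
sen_spe <- function(confusion, cls = NULL) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stopf("confusion matrix must be square")
  if (any(confusion < 0)) stopf("confusion counts must be non-negative")
  total <- sum(confusion)
  out <- t(vapply(seq_len(nrow(confusion)), function(i) {
    tp <- confusion[i, i]
    fn <- sum(confusion[i, ]) - tp
    if (tp + fn == 0) stopf("class row %d is empty", i)
    fp <- sum(confusion[, i]) - tp
    tn <- total - tp - fn - fp
    c(sen = tp / (tp + fn), spe = tn / (tn + fp))
  }, c(sen = 0, spe = 0)))
  rownames(out) <- rownames(confusion) %||% seq_len(nrow(confusion))
  if (!is.null(cls)) out[cls, , drop = FALSE] else out
}

#' Stratified k-fold cross-validation of an RBF-SVM on (possibly fused)
#' features
#'
#' For each fold, an optional `builder` is fitted on the training split
#' only (feature fusion, selection and weighting happen inside the fold),
#' hyperparameters are optionally PSO-tuned on the training split, and the
#' held-out fold is predicted. Raw feature-matrix input is standardised
#' with training statistics; builder output is taken as emitted, because
#' fused spaces are scale-calibrated by the projection normalisation and
#' channel weights live in the column scales. Confusion counts are pooled
#' across folds.
#'
#' @param x Either a samples x p feature matrix, or a list of per-channel
#'   matrices when `builder` is supplied.
#' @param labels Class label per sample (every class needs >= k samples).
#' @param k Number of folds (default 6).
#' @param svm_cfg A [svm_config()].
#' @param seed Seed for the fold assignment and tuning.
#' @param builder Optional `function(train_x, train_labels)` returning a
#'   list with `transform` (maps `x`-like input to a feature matrix) and
#'   `info` (diagnostics kept in the report).
#' @return Object of class `cv_report`: `fold_accuracies`, `mean_accuracy`,
#'   `confusion` (counts), `confusion_pct` (row percentages), `sen`, `spe`,
#'   `folds` (train/test index bookkeeping), `builder_info`, `tuning`,
#'   `seed`.
#' @export
crossval <- function(x, labels, k = 6, svm_cfg = svm_config(), seed = 1,
                     builder = NULL) {
  stopifnot(inherits(svm_cfg, "svm_config"))
  labels <- factor(labels)
  n <- length(labels)
  subset_x <- function(idx) {
    if (is.list(x) && !is.data.frame(x))
      lapply(x, function(M) M[idx, , drop = FALSE])
    else as.matrix(x)[idx, , drop = FALSE]
  }
  fold <- stratified_folds(labels, k, seed = mix_seed(seed, 400))
  classes <- levels(labels)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, pred = classes))
  fold_acc <- numeric(k)
  folds_meta <- vector("list", k)
  builder_info <- vector("list", k)
  tuning <- vector("list", k)
  for (f in seq_len(k)) {
    tr_idx <- which(fold != f)
    te_idx <- which(fold == f)
    x_tr <- subset_x(tr_idx)
    x_te <- subset_x(te_idx)
    y_tr <- labels[tr_idx]
    if (!is.null(builder)) {
      # the builder standardises its inputs and emits a scale-calibrated
      # space (channel weights live in the column scales, so no further
      # per-column standardisation here)
      b <- builder(x_tr, y_tr)
      Z_tr <- b$transform(x_tr)
      Z_te <- b$transform(x_te)
      builder_info[[f]] <- c(b$info, list(n_train = length(tr_idx),
                                          train_idx = tr_idx))
    } else {
      sc <- fit_scaler(x_tr)
      Z_tr <- apply_scaler(x_tr, sc)
      Z_te <- apply_scaler(x_te, sc)
    }
    if (!is.null(svm_cfg$pso)) {
      pcfg <- svm_cfg$pso
      pcfg$seed <- mix_seed(seed, 500, f)
      tune <- pso_tune(Z_tr, y_tr, pcfg)
      sigma <- tune$sigma
      cost <- tune$cost
      tuning[[f]] <- c(tune[c("sigma", "cost", "accuracy")],
                       list(n_train = length(tr_idx), train_idx = tr_idx))
    } else {
      sigma <- svm_cfg$sigma %||% median_heuristic_sigma(Z_tr)
      cost <- svm_cfg$cost
    }
    fit <- fit_ovr_svm(Z_tr, y_tr, sigma, cost)
    pred <- predict_ovr(fit, Z_te)
    truth <- labels[te_idx]
    for (i in seq_along(te_idx))
      confusion[as.character(truth[i]), as.character(pred[i])] <-
        confusion[as.character(truth[i]), as.character(pred[i])] + 1L
    fold_acc[f] <- mean(pred == truth)
    folds_meta[[f]] <- list(train_idx = tr_idx, test_idx = te_idx)
  }
  ss <- sen_spe(confusion)
  structure(list(fold_accuracies = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 confusion = confusion,
                 confusion_pct = 100 * confusion /
                   pmax(rowSums(confusion), 1),
                 sen = ss[, "sen"], spe = ss[, "spe"],
                 folds = folds_meta, builder_info = builder_info,
                 tuning = tuning, k = k, seed = seed,
                 svm_config = svm_cfg),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold CV, mean accuracy %.4f\n", x$k,
              x$mean_accuracy))
  cat("fold accuracies:", paste(sprintf("%.3f", x$fold_accuracies),
                                collapse = " "), "\n")
  invisible(x)
}
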