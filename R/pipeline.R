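#' Pipeline configuration
#'
#' Bundles the stage configurations of the end-to-end fusion pipeline:
#' extract per-channel features, fuse channels, optionally prune components
#' with the genetic algorithm, optionally re-weight channels by clustering
#' accuracy, then evaluate by a Davies-Bouldin sweep and SVM
#' cross-validation.
#'
#' @param method Fusion method: `"none"` (concatenation), `"cca"`,
#'   `"gcca"`, `"ga-gcca"`, `"wga-gcca"`, `"pca-gcca"`, `"svd-gcca"`.
#' @param mode Fusion mode, `"type1"` (stack) or `"type2"` (sum).
#' @param d Canonical components retained per set (default: all,
#'   `min(p_i)`; the GA stage is what prunes the fused space).
#' @param ridge Absolute within-class scatter regularisation (see
#'   [solve_gcca()]); overrides `ridge_frac`.
#' @param ridge_frac Relative regularisation, `ridge_frac * trace/p` per
#'   set. The pipeline default (0.25) shrinks the within-class whitening
#'   towards the identity, which stabilises the projections when classes
#'   have few training samples.
#' @param strategy Multiset strategy (see [multiset_gcca()]); channel
#'   weighting requires `"sumcor"`.
#' @param ga A [ga_config()] (used by the GA-based methods).
#' @param w_min Weight floor of [compute_weights()].
#' @param keep_fraction Fraction of components kept by the PCA/SVD
#'   selectors.
#' @param svm A [svm_config()].
#' @param feature_cfg A [feature_config()].
#' @param k_folds Cross-validation folds (default 6).
#' @param dbi_k Cluster counts of the Davies-Bouldin sweep (default 2..10).
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(method = c("wga-gcca", "none", "cca", "gcca",
                                       "ga-gcca", "pca-gcca", "svd-gcca"),
                            mode = c("type1", "type2"), d = NULL,
                            ridge = NULL, ridge_frac = 0.25,
                            strategy = "sumcor",
                            ga = ga_config(), w_min = 0.1,
                            keep_fraction = 0.25, svm = svm_config(),
                            feature_cfg = feature_config(), k_folds = 6,
                            dbi_k = 2:10, seed = 1) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (method == "wga-gcca" && strategy != "sumcor")
    stopf("channel weighting requires the sumcor multiset strategy")
  structure(list(method = method, mode = mode, d = d, ridge = ridge,
                 ridge_frac = ridge_frac,
                 strategy = strategy, ga = ga, w_min = w_min,
                 keep_fraction = keep_fraction, svm = svm,
                 feature_cfg = feature_cfg, k_folds = as.integer(k_folds),
                 dbi_k = dbi_k, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Retain leading principal components of a fused feature space
#'
#' @param Z Samples x p matrix (p >= 2).
#' @param keep_fraction Fraction in `(0, 1]`; `ceiling(keep_fraction * p)`
#'   components are kept.
#' @return Object of class `pca_select`: `scores`, `rotation`, `center`,
#'   `k`, `sdev`.
#' @export
pca_select <- function(Z, keep_fraction = 0.25) {
  Z <- as.matrix(Z)
  if (keep_fraction <= 0 || keep_fraction > 1)
    stopf("keep_fraction must lie in (0, 1]")
  k <- ceiling(keep_fraction * ncol(Z))
  pc <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center, k = k, sdev = pc$sdev),
            class = "pca_select")
}

#' Retain leading singular directions of a fused feature space
#'
#' As [pca_select()] but by singular-value truncation of the uncentred
#' matrix.
#'
#' @inheritParams pca_select
#' @return Object of class `svd_select`: `scores`, `v`, `d` (singular
#'   values, non-increasing), `k`.
#' @export
svd_select <- function(Z, keep_fraction = 0.25) {
  Z <- as.matrix(Z)
  if (keep_fraction <= 0 || keep_fraction > 1)
    stopf("keep_fraction must lie in (0, 1]")
  k <- min(ceiling(keep_fraction * ncol(Z)), min(dim(Z)))
  sv <- svd(Z)
  structure(list(scores = Z %*% sv$v[, seq_len(k), drop = FALSE],
                 v = sv$v[, seq_len(k), drop = FALSE], d = sv$d, k = k),
            class = "svd_select")
}

# Builder factory: returns function(train_sets, train_labels) fitting the
# configured fusion on the training split only and exposing a transform
# for new data. This is what crossval() calls inside each fold, so GA
# selection, weighting and PSO tuning never see test samples.
make_builder <- function(cfg) {
  force(cfg)
  function(train_x, y) {
    train_sets <- if (is.list(train_x) && !is.data.frame(train_x))
      train_x else list(as.matrix(train_x))
    m <- length(train_sets)
    scalers <- lapply(train_sets, fit_scaler)
    scale_all <- function(sets) {
      sets <- if (is.list(sets) && !is.data.frame(sets)) sets
              else list(as.matrix(sets))
      out <- mapply(apply_scaler, sets, scalers, SIMPLIFY = FALSE)
      if (m == 1) out <- list(out[[1]], out[[1]])  # self-paired single set
      out
    }
    S <- scale_all(train_sets)
    ps <- vapply(train_sets, ncol, integer(1))
    info <- list(method = cfg$method, raw_dims = ps, raw_total = sum(ps))

    if (cfg$method == "none") {
      transform <- function(sets) do.call(cbind, scale_all(sets)[
        seq_len(max(m, 1))])
      info$final_dim <- sum(ps)
      return(list(transform = transform, info = info))
    }

    d_use <- min(cfg$d %||% min(ps), min(ps))
    msp <- multiset_gcca(S, labels = y, d = d_use, ridge = cfg$ridge,
                         ridge_frac = cfg$ridge_frac,
                         strategy = cfg$strategy, mode = cfg$mode,
                         within = if (cfg$method == "cca") "total"
                                  else "class")
    fused_tr <- msp$fused
    info$post_gcca <- ncol(fused_tr)

    if (cfg$method %in% c("pca-gcca", "svd-gcca")) {
      sel <- if (cfg$method == "pca-gcca")
        pca_select(fused_tr, cfg$keep_fraction)
      else svd_select(fused_tr, cfg$keep_fraction)
      transform <- function(sets) {
        Z <- apply_multiset(msp, scale_all(sets))
        if (inherits(sel, "pca_select"))
          sweep(Z, 2, sel$center, "-") %*% sel$rotation
        else Z %*% sel$v
      }
      info$final_dim <- sel$k
      return(list(transform = transform, info = info))
    }

    mask <- rep(TRUE, ncol(fused_tr))
    ga_res <- NULL
    if (cfg$method %in% c("ga-gcca", "wga-gcca")) {
      gcfg <- cfg$ga
      gcfg$seed <- mix_seed(cfg$seed, 77)
      ga_res <- run_ga(fused_tr, y, gcfg)
      mask <- ga_res$best_mask
      info$post_ga <- sum(mask)
      info$ga_fitness <- ga_res$best_fitness
    }

    weights <- NULL
    if (cfg$method == "wga-gcca") {
      nb <- length(S)
      dd <- msp$d
      blocks <- project_blocks(msp, S)
      block_mask <- function(i) {
        if (cfg$mode == "type1") mask[((i - 1) * dd + 1):(i * dd)]
        else mask
      }
      accu <- vapply(seq_len(nb), function(i) {
        sel <- block_mask(i)
        if (!any(sel)) return(0)
        channel_recognition_rate(blocks[[i]][, sel, drop = FALSE], y,
                                 seed = mix_seed(cfg$seed, 600, i))
      }, numeric(1))
      weights <- compute_weights(accu, cfg$w_min)
      info$weights <- weights$r
      info$channel_accu <- accu
    }

    transform <- function(sets) {
      Ssc <- scale_all(sets)
      if (is.null(weights)) {
        Z <- apply_multiset(msp, Ssc)
        return(Z[, mask, drop = FALSE])
      }
      blocks <- project_blocks(msp, Ssc)
      if (cfg$mode == "type1") {
        Z <- fuse_blocks(mapply(`*`, blocks, weights$r, SIMPLIFY = FALSE),
                         "type1")
        Z[, mask, drop = FALSE]
      } else {
        Z <- fuse_blocks(mapply(`*`, blocks, weights$r, SIMPLIFY = FALSE),
                         "type2")
        Z[, mask, drop = FALSE]
      }
    }
    info$final_dim <- sum(mask)
    list(transform = transform, info = info, ga = ga_res,
         weights = weights)
  }
}

#' Run the end-to-end fusion pipeline on a dataset
#'
#' Extracts per-channel features (unless given a ready `feature_set`),
#' fits the configured fusion on the full data for the Davies-Bouldin
#' evaluation, and estimates recognition accuracy by stratified k-fold
#' cross-validation in which every supervised stage (fusion, GA selection,
#' weighting, hyperparameter tuning) is re-fitted inside each training
#' fold.
#'
#' @param data An `semg_dataset` or a `feature_set`.
#' @param cfg A [pipeline_config()].
#' @return Object of class `fusion_report`: `method`, `mode`, `dbi_curve`
#'   (data frame K vs DBI), `cv` ([crossval()] report), `dims` (per-stage
#'   dimensions), `weights`, `ga_trace`, `seed`, `config`.
#' @export
run_pipeline <- function(data, cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  fset <- if (inherits(data, "feature_set")) data
          else extract_feature_set(data, cfg$feature_cfg)
  sets <- fset$sets
  labels <- fset$labels
  if (nlevels(labels) < 2) stopf("need >= 2 classes")
  builder <- make_builder(cfg)

  fit_all <- builder(sets, labels)
  Z_all <- fit_all$transform(sets)
  dbi_curve <- dbi_sweep(Z_all, cfg$dbi_k, seed = mix_seed(cfg$seed, 901))

  cv <- crossval(sets, labels, k = cfg$k_folds, svm_cfg = cfg$svm,
                 seed = cfg$seed, builder = builder)

  structure(list(method = cfg$method, mode = cfg$mode,
                 dbi_curve = dbi_curve, cv = cv, dims = fit_all$info,
                 weights = if (!is.null(fit_all$weights))
                   fit_all$weights$r,
                 ga_trace = if (!is.null(fit_all$ga))
                   fit_all$ga$fitness_trace,
                 seed = cfg$seed, config = cfg),
            class = "fusion_report")
}

#' @export
print.fusion_report <- function(x, ...) {
  cat(sprintf("<fusion_report> method=%s mode=%s\n", x$method, x$mode))
  cat(sprintf("  mean CV accuracy: %.4f\n", x$cv$mean_accuracy))
  k8 <- x$dbi_curve$dbi[x$dbi_curve$K == 8]
  if (length(k8)) cat(sprintf("  DBI at K=8: %.4f\n", k8))
  cat(sprintf("  dimensions: raw %d -> final %d\n", x$dims$raw_total,
              x$dims$final_dim))
  if (!is.null(x$weights))
    cat("  channel weights:", paste(sprintf("%.3f", x$weights),
                                    collapse = " "), "\n")
  invisible(x)
}

#' Per-stage dimension bookkeeping of a pipeline run
#'
#' @param report A [run_pipeline()] result.
#' @return Data frame with one row per recorded stage (raw, post-fusion,
#'   post-GA, final) and the dimension at that stage.
#' @export
dimension_report <- function(report) {
  stopifnot(inherits(report, "fusion_report"))
  d <- report$dims
  stages <- c(raw = d$raw_total, post_gcca = d$post_gcca %||% NA,
              post_ga = d$post_ga %||% NA, final = d$final_dim)
  data.frame(stage = names(stages), dimension = as.numeric(stages),
             row.names = NULL)
}

#' Serialise a fusion report to JSON
#'
#' Writes the reproducible payload of the report (curves, accuracies,
#' confusion percentages, dimensions, weights, seeds, config scalars);
#' byte-identical for identical seeds and inputs.
#'
#' @param report A `fusion_report`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "fusion_report"))
  payload <- list(
    method = report$method, mode = report$mode, seed = report$seed,
    dbi_curve = report$dbi_curve,
    mean_accuracy = report$cv$mean_accuracy,
    fold_accuracies = report$cv$fold_accuracies,
    confusion_pct = report$cv$confusion_pct,
    sen = report$cv$sen, spe = report$cv$spe,
    dims = report$dims[setdiff(names(report$dims), "method")],
    weights = report$weights, ga_trace = report$ga_trace,
    k_folds = report$config$k_folds)
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                         null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Recognition accuracy versus number of input channels
#'
#' Runs the configured methods on the first `1..max(channel_counts)`
#' channels of 6-channel (or wider) synthetic datasets and records the
#' mean cross-validated accuracy, averaged over `seeds`. Single-channel
#' runs pair the channel with itself for the two-set fusion methods.
#'
#' @param synth_cfg A [synth_config()] with at least
#'   `max(channel_counts)` channels, or a list of ready `feature_set`
#'   objects (one per seed replicate).
#' @param cfg A [pipeline_config()] (its `method` is overridden).
#' @param channel_counts Channel counts to evaluate (default 1..6).
#' @param methods Fusion methods to compare.
#' @param seeds Seeds of the dataset replicates.
#' @return List with `table` (methods x channel counts mean accuracy) and
#'   `increments` (accuracy change from n to n+1 channels).
#' @export
monotonicity_experiment <- function(synth_cfg, cfg = pipeline_config(),
                                    channel_counts = 1:6,
                                    methods = c("wga-gcca"), seeds = 1) {
  fsets <- if (is.list(synth_cfg) && !inherits(synth_cfg, "synth_config")) {
    synth_cfg
  } else {
    stopifnot(inherits(synth_cfg, "synth_config"))
    if (synth_cfg$n_channels < max(channel_counts))
      stopf("dataset has %d channels; %d requested",
            synth_cfg$n_channels, max(channel_counts))
    lapply(seeds, function(s) {
      sc <- synth_cfg
      sc$seed <- mix_seed(synth_cfg$seed, s)
      extract_feature_set(generate_dataset(sc), cfg$feature_cfg)
    })
  }
  nch_avail <- length(fsets[[1]]$sets)
  if (nch_avail < max(channel_counts))
    stopf("feature sets have %d channels; %d requested", nch_avail,
          max(channel_counts))
  acc <- matrix(0, length(methods), length(channel_counts),
                dimnames = list(methods, channel_counts))
  for (mi in seq_along(methods)) {
    for (ci in seq_along(channel_counts)) {
      n_ch <- channel_counts[ci]
      vals <- vapply(seq_along(fsets), function(si) {
        fs <- fsets[[si]]
        cfg2 <- cfg
        cfg2$method <- methods[mi]
        cfg2$seed <- mix_seed(cfg$seed, si)
        builder <- make_builder(cfg2)
        cv <- crossval(fs$sets[seq_len(n_ch)], fs$labels,
                       k = cfg$k_folds, svm_cfg = cfg$svm,
                       seed = cfg2$seed, builder = builder)
        cv$mean_accuracy
      }, numeric(1))
      acc[mi, ci] <- mean(vals)
    }
  }
  inc <- acc[, -1, drop = FALSE] - acc[, -ncol(acc), drop = FALSE]
  list(table = acc, increments = inc)
}
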