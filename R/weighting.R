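#' Clustering recognition rate of one feature set
#'
#' Runs fuzzy c-means with as many clusters as classes, maps each cluster
#' to its majority true label, and returns the fraction of samples whose
#' mapped label is correct. Used as the per-channel accuracy `accu_i`
#' driving the dynamic weights.
#'
#' @param X Samples x p feature matrix of one channel.
#' @param labels True class labels (>= 2 classes).
#' @param fuzzifier,tol,max_iter,seed Passed to [fcm()].
#' @return Fraction in `[0, 1]`.
#' @export
channel_recognition_rate <- function(X, labels, fuzzifier = 2, tol = 1e-5,
                                     max_iter = 300, seed = 1) {
  X <- as.matrix(X)
  if (!is.factor(labels)) labels <- factor(labels)
  c <- nlevels(labels)
  if (c < 2) stopf("need >= 2 classes")
  if (nrow(X) < c) stopf("fewer samples than clusters")
  f <- fcm(X, c, fuzzifier, tol, max_iter, seed = seed)
  mapped <- character(length(labels))
  for (k in sort(unique(f$hard_labels))) {
    members <- f$hard_labels == k
    tab <- table(labels[members])
    mapped[members] <- names(tab)[which.max(tab)]
  }
  mean(mapped == as.character(labels))
}

#' Clustering-accuracy-based dynamic weights
#'
#' `W_i = accu_i - accu_min + W_min`, normalised to weight coefficients
#' `r_i = W_i / sum(W)`. The floor `W_min > 0` keeps the worst channel at a
#' small positive share.
#'
#' @param accu Recognition rate per feature set (non-empty numeric).
#' @param w_min Positive floor weight (default 0.1).
#' @return Object of class `weight_set`: `accu`, `W`, `r` (sums to 1),
#'   `w_min`.
#' @export
compute_weights <- function(accu, w_min = 0.1) {
  if (length(accu) < 1) stopf("accu must be non-empty")
  if (!is.numeric(w_min) || w_min <= 0)
    stopf("W_min must be positive (zero would zero-out the worst channel)")
  W <- accu - min(accu) + w_min
  structure(list(accu = accu, W = W, r = W / sum(W), w_min = w_min),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat("<weight_set>\n")
  print(round(rbind(accu = x$accu, r = x$r), 4))
  invisible(x)
}

#' Apply channel weights and fuse the projected blocks
#'
#' Scales each channel's projected block by its weight coefficient and
#' fuses: type I stacks the weighted blocks, type II sums them.
#'
#' @param blocks List of samples x d matrices, one per channel.
#' @param r Weight coefficients (same length as `blocks`).
#' @param mode `"type1"` or `"type2"`.
#' @return Fused weighted feature matrix.
#' @export
apply_weights <- function(blocks, r, mode = c("type1", "type2")) {
  mode <- match.arg(mode)
  if (length(blocks) != length(r)) stopf("length mismatch: blocks vs r")
  ns <- vapply(blocks, nrow, integer(1))
  if (length(unique(ns)) != 1) stopf("blocks must be paired")
  fuse_blocks(mapply(function(B, w) B * w, blocks, r, SIMPLIFY = FALSE),
              mode)
}
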