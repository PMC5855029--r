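#' Cosine evolutionary-rate schedule
#'
#' Scale factor `cos((gen / gen_max) * pi / 2)` applied to the base
#' crossover and mutation rates: 1 at generation 0, `sqrt(2)/2` halfway,
#' exactly 0 at the final generation, so exploration decays smoothly.
#'
#' @param gen Current generation, `0 <= gen <= gen_max`.
#' @param gen_max Total number of generations (>= 1).
#' @return Scale in `[0, 1]`.
#' @export
rate_schedule <- function(gen, gen_max) {
  if (gen_max < 1) stopf("gen_max must be >= 1")
  if (gen < 0 || gen > gen_max) stopf("gen must be in [0, gen_max]")
  cospi(gen / (2 * gen_max))
}

#' Fisher separability criterion
#'
#' `trace(S_W^-1 S_B)` of the (1/n-normalised) within- and between-class
#' scatters of the selected feature columns; larger means better class
#' separation. The within-class scatter is ridge-stabilised automatically
#' if singular (with a message).
#'
#' @param Z Samples x d feature matrix (already restricted to the columns
#'   under evaluation).
#' @param labels Class label per row (>= 2 classes).
#' @param ridge Optional explicit diagonal loading.
#' @return Non-negative real.
#' @export
fisher_fitness <- function(Z, labels, ridge = NULL) {
  Z <- as.matrix(Z)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stopf("need >= 2 classes")
  if (ncol(Z) < 1) stopf("need a non-empty column selection")
  sc <- class_scatters(Z, labels)
  fisher_trace(sc$Sw, sc$Sb, ridge)
}

#' @noRd
fisher_trace <- function(Sw, Sb, ridge = NULL) {
  val <- if (is.null(ridge)) {
    tryCatch(sum(diag(solve(Sw, Sb))), error = function(e) {
      message("within-class scatter singular; ridge-stabilising")
      r <- default_ridge(Sw) + 1e-10
      sum(diag(solve(Sw + diag(r, ncol(Sw)), Sb)))
    })
  } else sum(diag(solve(Sw + diag(ridge, ncol(Sw)), Sb)))
  max(0, val)
}

#' Genetic-algorithm configuration
#'
#' @param population_size Chromosomes per generation.
#' @param gen_max Number of generations.
#' @param base_crossover_rate,base_mutation_rate Base rates, scaled each
#'   generation by [rate_schedule()].
#' @param elitism Number of best chromosomes copied unchanged.
#' @param seed Integer seed.
#' @param min_selected Minimum number of selected columns after repair.
#' @param dim_penalty Finite-sample debiasing of the fitness: on n samples
#'   and K classes, every selected column -- informative or not -- inflates
#'   the trace criterion by about `(K-1)/n`, so the GA maximises
#'   `trace(S_W^-1 S_B) - dim_penalty * |mask| * (K-1)/n`. The default 2
#'   requires a component to exceed twice its chance-level contribution to
#'   be worth keeping; 0 restores the raw trace.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population_size = 40, gen_max = 30,
                      base_crossover_rate = 0.8, base_mutation_rate = 0.05,
                      elitism = 2, seed = 1, min_selected = 1,
                      dim_penalty = 2) {
  if (gen_max < 1) stopf("gen_max must be >= 1")
  if (population_size < 2) stopf("population_size must be >= 2")
  if (base_crossover_rate < 0 || base_crossover_rate > 1 ||
      base_mutation_rate < 0 || base_mutation_rate > 1)
    stopf("rates must lie in [0, 1]")
  structure(list(population_size = as.integer(population_size),
                 gen_max = as.integer(gen_max),
                 base_crossover_rate = base_crossover_rate,
                 base_mutation_rate = base_mutation_rate,
                 elitism = as.integer(elitism), seed = as.integer(seed),
                 min_selected = as.integer(min_selected),
                 dim_penalty = dim_penalty),
            class = "ga_config")
}

# Lexicographic comparison: higher fitness wins; near-ties (relative 1e-9)
# break towards the smaller selected dimension.
ga_better <- function(fit_a, n_a, fit_b, n_b) {
  tol <- 1e-9 * max(1, abs(fit_a), abs(fit_b))
  if (fit_a > fit_b + tol) return(TRUE)
  if (fit_b > fit_a + tol) return(FALSE)
  n_a < n_b
}

#' Binary genetic algorithm selecting fused-feature components
#'
#' Tournament selection (size 2), single-point crossover and per-bit
#' mutation over binary masks of the columns of `Z`, with the Fisher
#' criterion as fitness and crossover/mutation rates decayed by the cosine
#' schedule. Elitism guarantees a non-decreasing best fitness. Fitness ties
#' break towards fewer selected columns.
#'
#' @param Z Samples x L fused feature matrix (L >= 2).
#' @param labels Class label per row (>= 2 classes).
#' @param cfg A [ga_config()].
#' @return Object of class `ga_result`: `best_mask` (logical), `best_fitness`,
#'   `fitness_trace` (elitist best per generation, non-decreasing),
#'   `selected_dimension`, and the config echo.
#' @export
run_ga <- function(Z, labels, cfg = ga_config()) {
  stopifnot(inherits(cfg, "ga_config"))
  Z <- as.matrix(Z)
  labels <- factor(labels)
  if (ncol(Z) < 2) stopf("Z must have >= 2 columns")
  if (nlevels(labels) < 2) stopf("need >= 2 classes (degenerate labels)")
  L <- ncol(Z)
  sc <- class_scatters(Z, labels)
  ridge <- default_ridge(sc$Sw) + 1e-12
  col_penalty <- (cfg$dim_penalty %||% 0) *
    (nlevels(labels) - 1) / nrow(Z)
  fit_mask <- function(mask) {
    idx <- which(mask)
    fisher_trace(sc$Sw[idx, idx, drop = FALSE],
                 sc$Sb[idx, idx, drop = FALSE], ridge) -
      col_penalty * length(idx)
  }
  repair <- function(mask) {
    need <- cfg$min_selected - sum(mask)
    if (need > 0) mask[sample(which(!mask), need)] <- TRUE
    mask
  }

  local_seed(cfg$seed, {
    pop <- matrix(stats::runif(cfg$population_size * L) < 0.5,
                  cfg$population_size, L)
    pop <- t(apply(pop, 1, repair))
    fit <- apply(pop, 1, fit_mask)
    nb <- rowSums(pop)
    ord <- order(-fit, nb)
    best_mask <- pop[ord[1], ]
    best_fit <- fit[ord[1]]
    trace <- numeric(cfg$gen_max)

    for (gen in seq_len(cfg$gen_max)) {
      sched <- rate_schedule(gen, cfg$gen_max)
      cx <- cfg$base_crossover_rate * sched
      mut <- cfg$base_mutation_rate * sched
      # tournament selection of parents
      pick <- function() {
        ij <- sample.int(cfg$population_size, 2)
        if (ga_better(fit[ij[1]], nb[ij[1]], fit[ij[2]], nb[ij[2]]))
          ij[1] else ij[2]
      }
      children <- matrix(FALSE, cfg$population_size, L)
      for (s in seq(1, cfg$population_size, by = 2)) {
        a <- pop[pick(), ]
        b <- pop[pick(), ]
        if (L > 1 && stats::runif(1) < cx) {
          cut <- sample.int(L - 1, 1)
          tmp <- a
          a <- c(a[1:cut], b[(cut + 1):L])
          b <- c(b[1:cut], tmp[(cut + 1):L])
        }
        children[s, ] <- a
        if (s + 1 <= cfg$population_size) children[s + 1, ] <- b
      }
      if (mut > 0) {
        flips <- matrix(stats::runif(cfg$population_size * L) < mut,
                        cfg$population_size, L)
        children <- xor(children, flips)
      }
      children <- t(apply(children, 1, repair))
      cfit <- apply(children, 1, fit_mask)
      cnb <- rowSums(children)
      # elitism: previous best chromosomes replace the worst children
      if (cfg$elitism > 0) {
        elite <- order(-fit, nb)[seq_len(min(cfg$elitism,
                                             cfg$population_size))]
        worst <- order(cfit, -cnb)[seq_along(elite)]
        children[worst, ] <- pop[elite, , drop = FALSE]
        cfit[worst] <- fit[elite]
        cnb[worst] <- nb[elite]
      }
      pop <- children; fit <- cfit; nb <- cnb
      ord1 <- order(-fit, nb)[1]
      if (ga_better(fit[ord1], nb[ord1], best_fit, sum(best_mask))) {
        best_fit <- fit[ord1]
        best_mask <- pop[ord1, ]
      }
      trace[gen] <- best_fit
    }

    structure(list(best_mask = as.logical(best_mask),
                   best_fitness = best_fit, fitness_trace = trace,
                   selected_dimension = sum(best_mask), config = cfg),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> selected %d/%d columns, fitness %.4f\n",
              x$selected_dimension, length(x$best_mask), x$best_fitness))
  invisible(x)
}
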