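#' Write projection matrices as CSV
#'
#' One file per side: rows are input features, columns are component
#' indices (`comp1`, `comp2`, ...).
#'
#' @param P A `gcca_projection` ([solve_gcca()] / [solve_cca()]).
#' @param path_u,path_v Output CSV paths (`path_v` optional).
#' @return Invisibly, the paths written.
#' @export
write_projection <- function(P, path_u, path_v = NULL) {
  stopifnot(inherits(P, "gcca_projection"))
  dump1 <- function(M, path) {
    df <- as.data.frame(M)
    names(df) <- paste0("comp", seq_len(ncol(M)))
    rownames(df) <- rownames(M) %||% paste0("f", seq_len(nrow(M)))
    utils::write.csv(df, path, row.names = TRUE)
  }
  dump1(P$U, path_u)
  if (!is.null(path_v)) dump1(P$V, path_v)
  invisible(c(path_u, path_v))
}

#' Serialise a GA selection result as JSON
#'
#' Mask, fitness, per-generation trace, selected dimension, and the
#' configuration echo (including the seed).
#'
#' @param g A [run_ga()] result.
#' @param path Optional file path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written.
#' @export
ga_json <- function(g, path = NULL) {
  stopifnot(inherits(g, "ga_result"))
  js <- jsonlite::toJSON(list(
    mask = as.integer(g$best_mask), fitness = g$best_fitness,
    fitness_trace = g$fitness_trace,
    selected_dimension = g$selected_dimension,
    config = unclass(g$config)), digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Serialise a weight set as JSON
#'
#' @param w A [compute_weights()] result.
#' @param path Optional file path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written.
#' @export
weights_json <- function(w, path = NULL) {
  stopifnot(inherits(w, "weight_set"))
  js <- jsonlite::toJSON(unclass(w), digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
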