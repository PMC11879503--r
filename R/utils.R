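#' Derive a reproducible substream seed
#'
#' Stage-keyed substreams: every stochastic stage of the pipeline draws its
#' seed from the master seed plus a fixed stage offset, so adding, removing or
#' reconfiguring one stage never perturbs another stage's random draws.
#'
#' @param master integer master seed.
#' @param stream integer stream index (fixed per stage/replicate).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, stream) {
  m <- 2147483647  # 2^31 - 1
  as.integer(((as.numeric(master) %% m) + 104729 * (as.numeric(stream) %% m)) %% m)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce any of the accepted inputs (questionnaire_dataset, matrix,
# data.frame) to a plain numeric score matrix with column names.
#' @noRd
as_score_matrix <- function(x) {
  if (inherits(x, "questionnaire_dataset")) return(x$scores)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  m
}

#' @noRd
dataset_communities <- function(x, p = NULL) {
  if (inherits(x, "questionnaire_dataset") && !is.null(x$communities))
    return(x$communities)
  NULL
}

# z-score columns; errors on constant columns (naming them) because every
# downstream estimator assumes nonzero variance.
#' @noRd
zscore_columns <- function(X) {
  s <- apply(X, 2, sd)
  if (any(s == 0)) {
    stop("constant column(s): ", paste(colnames(X)[s == 0], collapse = ", "))
  }
  scale(X, center = TRUE, scale = TRUE)
}

#' @noRd
check_square_symmetric <- function(M, name = "matrix", tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(name, " must be a square matrix")
  if (max(abs(M - t(M))) > tol)
    stop(name, " must be symmetric")
  invisible(TRUE)
}

# Names of the p(p-1)/2 unordered pairs, in column-major upper-triangle order
# (the order used by upper.tri extraction throughout).
#' @noRd
pair_names <- function(nodes) {
  p <- length(nodes)
  idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  paste(nodes[idx[, 1]], nodes[idx[, 2]], sep = "--")
}

#' @noRd
upper_vec <- function(M) M[upper.tri(M)]
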