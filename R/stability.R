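# Centrality indices tracked through the bootstrap machinery.
BOOT_INDICES <- c("strength", "closeness", "betweenness",
                  "expected_influence", "bridge_strength", "bridge_closeness",
                  "bridge_betweenness", "bridge_expected_influence_1step")

# Centralities of a weight matrix as a named numeric vector, index-major
# (used by both bootstrap routines so replicates and originals line up).
#' @noRd
centrality_vectors <- function(W, node_names, communities) {
  net <- weighted_network(W, node_names, communities)
  nc <- node_centralities(net)
  out <- list(strength = nc$strength, closeness = nc$closeness,
              betweenness = nc$betweenness,
              expected_influence = nc$expected_influence)
  if (!is.null(communities) &&
      length(unique(communities[node_names])) > 1) {
    bc <- bridge_centralities(net, communities)
    out$bridge_strength <- bc$bridge_strength
    out$bridge_closeness <- bc$bridge_closeness
    out$bridge_betweenness <- bc$bridge_betweenness
    out$bridge_expected_influence_1step <- bc$bridge_expected_influence_1step
  }
  lapply(out, setNames, node_names)
}

# Resample row indices, redrawing (up to max_redraw times) if the resampled
# data has a constant column; returns indices.
#' @noRd
resample_rows <- function(X, n_out, replace, max_redraw = 10) {
  for (k in seq_len(max_redraw + 1)) {
    idx <- sample.int(nrow(X), n_out, replace = replace)
    if (all(apply(X[idx, , drop = FALSE], 2, var) > 0)) return(idx)
    message("degenerate resample (constant column), redrawing [", k, "]")
  }
  stop("could not draw a non-degenerate resample after ", max_redraw,
       " redraws")
}

#' Nonparametric bootstrap of edge weights and centralities
#'
#' Resamples participants with replacement, re-runs the full
#' Spearman + EBIC-glasso estimator on every resample, and collects edge
#' weights and centrality indices; edge-weight accuracy is summarized by
#' percentile 95% confidence intervals.
#'
#' @param data scores ([questionnaire_dataset()] or matrix).
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param gamma,n_lambda,lambda_min_ratio estimator configuration passed to
#'   the EBIC-glasso pipeline.
#' @param communities community labels (defaults to the dataset's) enabling
#'   bridge-centrality tracking.
#' @param ci_level confidence level for the percentile intervals.
#' @return an object of class `bootstrap_result`: list with `B`,
#'   `edge_samples` (`B x p(p-1)/2`), `centrality_samples` (list of `B x p`
#'   matrices), `point` (observed edge weights and centralities), `ci`
#'   (data frame `edge, estimate, ci_low, ci_high`), `seed`.
#' @export
bootstrap_edges <- function(data, B = 1000, seed, gamma = 0.5,
                            n_lambda = 100, lambda_min_ratio = 0.01,
                            communities = NULL, ci_level = 0.95) {
  X <- as_score_matrix(data)
  communities <- communities %||% dataset_communities(data)
  nodes <- colnames(X)
  W0 <- estimate_W(X, gamma, n_lambda, lambda_min_ratio)
  cent0 <- centrality_vectors(W0, nodes, communities)
  pn <- pair_names(nodes)
  edge_samples <- matrix(NA_real_, B, length(pn),
                         dimnames = list(NULL, pn))
  cent_samples <- lapply(cent0, function(v)
    matrix(NA_real_, B, length(v), dimnames = list(NULL, names(v))))
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(B)) {
      idx <- resample_rows(X, nrow(X), replace = TRUE)
      Wb <- estimate_W(X[idx, , drop = FALSE], gamma, n_lambda,
                       lambda_min_ratio)
      edge_samples[b, ] <- upper_vec(Wb)
      cb <- centrality_vectors(Wb, nodes, communities)
      for (nm in names(cent_samples)) cent_samples[[nm]][b, ] <- cb[[nm]]
    }
  })
  a <- (1 - ci_level) / 2
  ci <- data.frame(edge = pn, estimate = upper_vec(W0),
                   ci_low = apply(edge_samples, 2, quantile, a),
                   ci_high = apply(edge_samples, 2, quantile, 1 - a),
                   row.names = NULL)
  structure(list(B = B, edge_samples = edge_samples,
                 centrality_samples = cent_samples,
                 point = list(W = W0, centralities = cent0),
                 ci = ci, ci_level = ci_level, seed = as.integer(seed),
                 nodes = nodes, communities = communities),
            class = "bootstrap_result")
}

#' Bootstrapped difference test for edges or centralities
#'
#' For each pair of edges (or nodes), the bootstrap 95% percentile CI of the
#' difference between their values; a pair is significantly different iff the
#' CI excludes zero. Symmetric by construction; self-comparisons are never
#' significant.
#'
#' @param boot a [bootstrap_edges()] result.
#' @param kind which quantity to compare: `"edge"`, `"strength"`, `"EI"`, or
#'   `"bridge_EI"`.
#' @param ci_level confidence level (default 0.95).
#' @return list with `significant` (logical matrix), `diff_low`, `diff_high`.
#' @export
difference_test <- function(boot, kind = c("edge", "strength", "EI",
                                           "bridge_EI"),
                            ci_level = 0.95) {
  stopifnot(inherits(boot, "bootstrap_result"))
  kind <- match.arg(kind)
  S <- switch(kind,
              edge = boot$edge_samples,
              strength = boot$centrality_samples$strength,
              EI = boot$centrality_samples$expected_influence,
              bridge_EI = boot$centrality_samples$bridge_expected_influence_1step)
  if (is.null(S)) stop("bootstrap samples for '", kind, "' not available")
  m <- ncol(S)
  a <- (1 - ci_level) / 2
  lo <- hi <- matrix(0, m, m, dimnames = list(colnames(S), colnames(S)))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    d <- S[, i] - S[, j]
    lo[i, j] <- quantile(d, a)
    hi[i, j] <- quantile(d, 1 - a)
  }
  sig <- lo > 0 | hi < 0
  diag(sig) <- FALSE
  list(kind = kind, significant = sig, diff_low = lo, diff_high = hi)
}

#' Case-dropping bootstrap for centrality stability
#'
#' For each drop proportion `q`, draws `B` subsamples without replacement
#' retaining `(1-q)*n` participants, re-estimates the network, and records
#' the Pearson correlation between each replicate's centralities and the
#' original sample's.
#'
#' @param data scores.
#' @param proportions strictly increasing drop proportions in (0, 1).
#' @param B replicates per proportion (default 1000).
#' @param seed integer seed.
#' @param gamma,n_lambda,lambda_min_ratio estimator configuration.
#' @param communities community labels for bridge indices.
#' @return an object of class `casedrop_result`: list with
#'   `drop_proportions`, `correlations` (list per index of `B x n_prop`
#'   matrices), `seed`.
#' @export
casedrop_bootstrap <- function(data, proportions = c(seq(0.1, 0.7, 0.1), 0.75),
                               B = 1000, seed, gamma = 0.5, n_lambda = 100,
                               lambda_min_ratio = 0.01, communities = NULL) {
  X <- as_score_matrix(data)
  communities <- communities %||% dataset_communities(data)
  if (any(diff(proportions) <= 0) || any(proportions <= 0) ||
      any(proportions >= 1))
    stop("proportions must be strictly increasing within (0, 1)")
  n <- nrow(X); p <- ncol(X)
  if (floor((1 - max(proportions)) * n) <= 3 * p)
    stop("smallest retained subsample must exceed 3p rows")
  nodes <- colnames(X)
  W0 <- estimate_W(X, gamma, n_lambda, lambda_min_ratio)
  cent0 <- centrality_vectors(W0, nodes, communities)
  cors <- lapply(cent0, function(v)
    matrix(NA_real_, B, length(proportions),
           dimnames = list(NULL, paste0("q", proportions))))
  withr::with_seed(as.integer(seed), {
    for (qi in seq_along(proportions)) {
      keep <- floor((1 - proportions[qi]) * n)
      for (b in seq_len(B)) {
        idx <- resample_rows(X, keep, replace = FALSE)
        Wb <- estimate_W(X[idx, , drop = FALSE], gamma, n_lambda,
                         lambda_min_ratio)
        cb <- centrality_vectors(Wb, nodes, communities)
        for (nm in names(cors)) {
          x0 <- cent0[[nm]]; xb <- cb[[nm]]
          cors[[nm]][b, qi] <-
            if (sd(x0) == 0 || sd(xb) == 0) 0 else cor(x0, xb)
        }
      }
    }
  })
  structure(list(drop_proportions = proportions, correlations = cors,
                 point = cent0, B = B, seed = as.integer(seed)),
            class = "casedrop_result")
}

#' Correlation-stability (CS) coefficient
#'
#' The largest drop proportion in the grid at which at least `confidence` of
#' the replicates still correlate at least `threshold` with the original
#' centralities; 0 if no grid point qualifies. The conventional
#' interpretability benchmark is CS > 0.5.
#'
#' @param res a [casedrop_bootstrap()] result.
#' @param threshold correlation threshold (default 0.7).
#' @param confidence required replicate fraction (default 0.95).
#' @return named numeric vector, one CS value per centrality index.
#' @export
cs_coefficient <- function(res, threshold = 0.7, confidence = 0.95) {
  stopifnot(inherits(res, "casedrop_result"))
  vapply(res$correlations, function(M) {
    ok <- colMeans(M >= threshold, na.rm = TRUE) >= confidence
    if (!any(ok)) 0 else max(res$drop_proportions[ok])
  }, numeric(1))
}
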