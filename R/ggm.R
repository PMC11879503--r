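#' Spearman correlation matrix with positive-definite repair
#'
#' Pairwise Spearman rank correlations (average ranks for ties). If the
#' result is not positive definite, eigenvalues are clipped at `1e-6` and the
#' matrix rescaled to unit diagonal; the `repaired` flag records whether this
#' happened.
#'
#' @param X score matrix, data frame, or [questionnaire_dataset()]; no missing
#'   values, no constant columns.
#' @return an object of class `correlation_matrix`: list with `R`, `n`,
#'   `method = "spearman"`, `repaired`.
#' @export
spearman_matrix <- function(X) {
  X <- as_score_matrix(X)
  if (anyNA(X)) stop("missing values in score matrix")
  s <- apply(X, 2, sd)
  if (any(s == 0))
    stop("constant column(s): ", paste(colnames(X)[s == 0], collapse = ", "))
  R <- cor(X, method = "spearman")
  rep_out <- repair_pd(R)
  structure(list(R = rep_out$R, n = nrow(X), method = "spearman",
                 repaired = rep_out$repaired),
            class = "correlation_matrix")
}

# Nearest-PD repair by eigenvalue clipping at `eps`, then rescale to unit
# diagonal. Deterministic and symmetry-preserving.
#' @noRd
repair_pd <- function(R, eps = 1e-6) {
  ee <- eigen(R, symmetric = TRUE)
  if (min(ee$values) >= eps) return(list(R = R, repaired = FALSE))
  vals <- pmax(ee$values, eps)
  R2 <- ee$vectors %*% (vals * t(ee$vectors))
  R2 <- stats::cov2cor((R2 + t(R2)) / 2)
  dimnames(R2) <- dimnames(R)
  list(R = R2, repaired = TRUE)
}

#' @noRd
as_correlation_matrix <- function(R, n = NULL) {
  if (inherits(R, "correlation_matrix")) return(R)
  check_square_symmetric(R, "R")
  structure(list(R = R, n = n, method = "spearman", repaired = FALSE),
            class = "correlation_matrix")
}

#' Graphical lasso at a single penalty
#'
#' Solves `max log det K - tr(RK) - lambda * sum_(i!=j) |K_ij|` by block
#' coordinate descent; the diagonal is not penalized. Entries with
#' `|K_ij| < 1e-8` are set to exact zero.
#'
#' @param R a `correlation_matrix` or plain PD correlation matrix.
#' @param lambda nonnegative penalty.
#' @param n sample size (for the log-likelihood; taken from `R` if absent).
#' @param maxit,tol outer-loop iteration cap and relative tolerance.
#' @return an object of class `glasso_fit`: list with `K_hat`, `lambda`,
#'   `loglik`, `E` (nonzero off-diagonal pairs), `ebic` (at `gamma`),
#'   `gamma`, `n`, `p`.
#' @export
glasso_solve <- function(R, lambda, n = NULL, maxit = 500, tol = 1e-9) {
  cm <- as_correlation_matrix(R, n)
  n <- n %||% cm$n
  fits <- glasso_path_fits(cm$R, lambda, n = n, maxit = maxit, tol = tol)
  fits[[1]]
}

# Shared path engine wrapper: lambdas in decreasing order, warm starts inside
# C++; returns a list of glasso_fit objects.
#' @noRd
glasso_path_fits <- function(R, lambdas, n = NULL, gamma = 0.5,
                             maxit = 500, tol = 1e-9) {
  p <- nrow(R)
  out <- glasso_path_engine(R, as.numeric(lambdas), maxit = maxit, tol = tol)
  if (any(out$converged == 0)) {
    bad <- which(out$converged == 0)[1]
    K <- out$K[, , bad]
    stop("graphical lasso failed to converge at lambda = ", lambdas[bad],
         " (max KKT violation ", signif(kkt_violation(K, R, lambdas[bad]), 3),
         ")")
  }
  lapply(seq_along(lambdas), function(l) {
    K <- out$K[, , l]
    dimnames(K) <- dimnames(R)
    ll <- if (is.null(n)) NA_real_ else
      (n / 2) * (out$crit[l] - p * log(2 * pi))
    fit <- structure(list(K_hat = K, lambda = lambdas[l], loglik = ll,
                          E = out$E[l], gamma = gamma, n = n, p = p,
                          iterations = out$iterations[l]),
                     class = "glasso_fit")
    fit$ebic <- if (is.null(n)) NA_real_ else ebic_score(fit, n, p, gamma)
    fit
  })
}

# Max violation of the stationarity conditions of the penalized likelihood;
# used in error reporting and by the test-suite oracle.
#' @noRd
kkt_violation <- function(K, R, lambda) {
  G <- solve(K) - R
  p <- nrow(K)
  v <- abs(diag(G))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    v <- c(v, if (K[i, j] != 0) abs(G[i, j] - lambda * sign(K[i, j]))
           else max(0, abs(G[i, j]) - lambda))
  }
  max(v)
}

#' Extended Bayesian Information Criterion of a graphical-lasso fit
#'
#' `EBIC = -2*loglik + E*log(n) + 4*E*gamma*log(p)`; `gamma = 0` reduces to
#' the ordinary BIC.
#'
#' @param fit a `glasso_fit` (or any list with `loglik` and `E`).
#' @param n sample size.
#' @param p node count.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @return scalar EBIC value.
#' @export
ebic_score <- function(fit, n, p, gamma = 0.5) {
  stopifnot(n > 0)
  -2 * fit$loglik + fit$E * log(n) + 4 * fit$E * gamma * log(p)
}

#' Weighted (partial-correlation) network
#'
#' @param W symmetric edge-weight matrix, zero diagonal, `|w| < 1`.
#' @param node_names node labels.
#' @param communities optional named community vector.
#' @return an object of class `weighted_network`.
#' @export
weighted_network <- function(W, node_names = NULL, communities = NULL) {
  check_square_symmetric(W, "W")
  if (max(abs(diag(W))) > 1e-12) stop("W must have zero diagonal")
  if (max(abs(W)) >= 1) stop("edge weights must satisfy |w| < 1")
  W <- (W + t(W)) / 2
  diag(W) <- 0
  node_names <- node_names %||% colnames(W) %||% paste0("V", seq_len(ncol(W)))
  dimnames(W) <- list(node_names, node_names)
  structure(list(W = W, node_names = node_names, communities = communities),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  E <- sum(upper_vec(x$W) != 0)
  cat("weighted_network:", length(x$node_names), "nodes,", E, "edges,",
      "global strength", round(global_strength(x), 3), "\n")
  invisible(x)
}

#' Global strength of a network
#'
#' Sum of absolute edge weights over unordered node pairs.
#'
#' @param net a `weighted_network` (or weight matrix).
#' @return scalar.
#' @export
global_strength <- function(net) {
  W <- if (inherits(net, "weighted_network")) net$W else net
  sum(abs(upper_vec(W)))
}

#' EBIC model selection along a graphical-lasso path
#'
#' Fits the graphical lasso on a log-spaced penalty path from
#' `lambda_max = max off-diagonal |r|` down to `lambda_max * lambda_min_ratio`
#' and selects the fit with minimum EBIC; ties break toward the larger
#' penalty (sparser model). The selected precision matrix is converted to
#' partial correlations.
#'
#' @param R a `correlation_matrix` (or PD correlation matrix with `n` given).
#' @param n sample size.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda path length (default 100).
#' @param lambda_min_ratio smallest penalty as a fraction of `lambda_max`.
#' @param communities optional community labels attached to the network.
#' @param maxit,tol solver controls.
#' @return list with `network` ([weighted_network()]), `fit` (selected
#'   `glasso_fit`), `path` (data frame `lambda, E, loglik, ebic`), and
#'   `lambda_index`.
#' @export
ebic_glasso_select <- function(R, n = NULL, gamma = 0.5, n_lambda = 100,
                               lambda_min_ratio = 0.01, communities = NULL,
                               maxit = 500, tol = 1e-9) {
  cm <- as_correlation_matrix(R, n)
  n <- n %||% cm$n
  if (is.null(n)) stop("sample size n required for EBIC selection")
  sel <- ebic_glasso_core(cm$R, n, gamma, n_lambda, lambda_min_ratio,
                          maxit, tol)
  fits <- glasso_path_fits(cm$R, sel$lambdas, n = n, gamma = gamma,
                           maxit = maxit, tol = tol)
  path <- data.frame(lambda = sel$lambdas,
                     E = vapply(fits, `[[`, 0L, "E"),
                     loglik = vapply(fits, `[[`, 0, "loglik"),
                     ebic = vapply(fits, `[[`, 0, "ebic"))
  list(network = weighted_network(sel$W, colnames(cm$R), communities),
       fit = fits[[sel$index]], path = path, lambda_index = sel$index)
}

# Fast core used inside bootstrap/permutation loops: returns only the selected
# partial-correlation matrix (and selection bookkeeping), no object wrapping.
#' @noRd
ebic_glasso_core <- function(R, n, gamma = 0.5, n_lambda = 100,
                             lambda_min_ratio = 0.01, maxit = 500,
                             tol = 1e-9) {
  p <- nrow(R)
  lmax <- max(abs(R[upper.tri(R)]))
  if (lmax <= 0) lmax <- 1e-4  # exactly uncorrelated: any path gives K diagonal
  lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                     length.out = n_lambda))
  out <- glasso_path_engine(R, lambdas, maxit = maxit, tol = tol)
  if (any(out$converged == 0))
    stop("graphical lasso failed to converge on the penalty path")
  ebic <- -n * (out$crit - p * log(2 * pi)) + out$E * log(n) +
    4 * gamma * out$E * log(p)
  # ties toward larger lambda: which.min returns the first (largest-lambda)
  idx <- which.min(round(ebic, 10))
  K <- out$K[, , idx]
  W <- partial_corr_from_precision(K)
  dimnames(W) <- dimnames(R)
  list(W = W, K = K, index = idx, lambdas = lambdas, ebic = ebic, E = out$E)
}

# One-call estimator used everywhere downstream: Spearman + PD repair +
# EBIC-glasso; returns the partial-correlation matrix only.
#' @noRd
estimate_W <- function(X, gamma = 0.5, n_lambda = 100,
                       lambda_min_ratio = 0.01) {
  Xr <- apply(X, 2, rank)
  R <- cor(Xr)
  R <- repair_pd(R)$R
  dimnames(R) <- list(colnames(X), colnames(X))
  ebic_glasso_core(R, nrow(X), gamma, n_lambda, lambda_min_ratio)$W
}

#' Estimate the regularized partial-correlation network from raw scores
#'
#' Convenience wrapper: Spearman correlations (with PD repair) followed by
#' [ebic_glasso_select()].
#'
#' @param data scores ([questionnaire_dataset()], matrix or data frame).
#' @param gamma,n_lambda,lambda_min_ratio see [ebic_glasso_select()].
#' @return as [ebic_glasso_select()], with communities carried over from the
#'   dataset when present.
#' @export
estimate_network <- function(data, gamma = 0.5, n_lambda = 100,
                             lambda_min_ratio = 0.01) {
  cm <- spearman_matrix(data)
  ebic_glasso_select(cm, gamma = gamma, n_lambda = n_lambda,
                     lambda_min_ratio = lambda_min_ratio,
                     communities = dataset_communities(data))
}

#' Export a network as an edge-list CSV (and optionally GraphML)
#'
#' @param net a [weighted_network()].
#' @param csv_path path for the long-format edge list
#'   (`node_i, node_j, weight`).
#' @param graphml_path optional path for GraphML output (edge `weight`
#'   attribute, node `community` attribute).
#' @return `csv_path`, invisibly.
#' @export
export_network <- function(net, csv_path, graphml_path = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  el <- network_edge_list(net)
  write.csv(el, csv_path, row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- network_igraph(net, absolute = FALSE)
    if (!is.null(net$communities))
      igraph::V(g)$community <- unname(net$communities[igraph::V(g)$name])
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(csv_path)
}

#' @noRd
network_edge_list <- function(net, keep_zero = FALSE) {
  W <- net$W
  idx <- which(upper.tri(W), arr.ind = TRUE)
  el <- data.frame(node_i = net$node_names[idx[, 1]],
                   node_j = net$node_names[idx[, 2]],
                   weight = W[idx])
  if (!keep_zero) el <- el[el$weight != 0, , drop = FALSE]
  rownames(el) <- NULL
  el
}

# igraph view of the network; edge weights are |w| (absolute = TRUE) or raw.
#' @noRd
network_igraph <- function(net, absolute = TRUE) {
  W <- if (absolute) abs(net$W) else net$W
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}
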