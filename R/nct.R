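#' Permutation network comparison test between two groups
#'
#' Estimates the regularized partial-correlation network in each group and
#' compares them by (a) network-structure invariance `M` — the maximum
#' absolute edge-weight difference, (b) global-strength invariance `S` — the
#' absolute difference between the groups' summed absolute edge weights,
#' (c) edge-level tests with Benjamini-Hochberg FDR correction, and (d)
#' centrality (strength, expected influence) differences. Null distributions
#' come from pooling all participants and randomly reassigning them to groups
#' of the original sizes, re-estimating both networks each time. Two-sided by
#' construction; p-values use `(1 + count) / (1 + n_perm)` and therefore lie
#' in `(0, 1]`.
#'
#' @param data_A,data_B scores for the two groups (same columns).
#' @param n_perm permutation count (default 10000).
#' @param seed integer seed.
#' @param tests subset of `c("structure", "global", "edges", "centrality")`.
#' @param gamma,n_lambda,lambda_min_ratio estimator configuration (the same
#'   estimator, EBIC-glasso with this gamma, is re-run inside every
#'   permutation).
#' @return an object of class `nct_result`.
#' @export
nct_run <- function(data_A, data_B, n_perm = 10000, seed,
                    tests = c("structure", "global", "edges", "centrality"),
                    gamma = 0.5, n_lambda = 100, lambda_min_ratio = 0.01) {
  tests <- match.arg(tests, several.ok = TRUE)
  XA <- as_score_matrix(data_A)
  XB <- as_score_matrix(data_B)
  if (!identical(colnames(XA), colnames(XB)))
    stop("both groups must share the same columns")
  p <- ncol(XA)
  if (nrow(XA) <= 3 * p || nrow(XB) <= 3 * p)
    stop("each group needs more than 3p rows")
  nodes <- colnames(XA)
  nA <- nrow(XA); nB <- nrow(XB)
  pool <- rbind(XA, XB)

  WA <- estimate_W(XA, gamma, n_lambda, lambda_min_ratio)
  WB <- estimate_W(XB, gamma, n_lambda, lambda_min_ratio)
  edge_diff_obs <- abs(upper_vec(WA) - upper_vec(WB))
  M_obs <- max(edge_diff_obs)
  gsA <- global_strength(WA); gsB <- global_strength(WB)
  S_obs <- abs(gsA - gsB)
  cent_obs <- list(strength = abs(rowSums(abs(WA)) - rowSums(abs(WB))),
                   expected_influence = abs(rowSums(WA) - rowSums(WB)))

  want_edges <- "edges" %in% tests
  want_cent <- "centrality" %in% tests
  M_perm <- S_perm <- numeric(n_perm)
  edge_ge <- if (want_edges) numeric(length(edge_diff_obs)) else NULL
  cent_ge <- if (want_cent) lapply(cent_obs, function(v) numeric(length(v)))
             else NULL

  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_perm)) {
      repeat {
        idx <- sample.int(nA + nB, nA)
        PA <- pool[idx, , drop = FALSE]
        PB <- pool[-idx, , drop = FALSE]
        okA <- all(apply(PA, 2, var) > 0)
        okB <- all(apply(PB, 2, var) > 0)
        if (okA && okB) break
        message("degenerate permutation resample, redrawing")
      }
      Wa <- estimate_W(PA, gamma, n_lambda, lambda_min_ratio)
      Wb <- estimate_W(PB, gamma, n_lambda, lambda_min_ratio)
      d <- abs(upper_vec(Wa) - upper_vec(Wb))
      M_perm[b] <- max(d)
      S_perm[b] <- abs(global_strength(Wa) - global_strength(Wb))
      if (want_edges) edge_ge <- edge_ge + (d >= edge_diff_obs)
      if (want_cent) {
        cent_ge$strength <- cent_ge$strength +
          (abs(rowSums(abs(Wa)) - rowSums(abs(Wb))) >= cent_obs$strength)
        cent_ge$expected_influence <- cent_ge$expected_influence +
          (abs(rowSums(Wa) - rowSums(Wb)) >= cent_obs$expected_influence)
      }
    }
  })

  perm_p <- function(count) (1 + count) / (1 + n_perm)
  pn <- pair_names(nodes)
  edge_table <- NULL
  if (want_edges) {
    praw <- perm_p(edge_ge)
    edge_table <- data.frame(edge = pn, diff = upper_vec(WA) - upper_vec(WB),
                             p_raw = praw,
                             p_fdr = p.adjust(praw, method = "BH"),
                             row.names = NULL)
  }
  cent_table <- NULL
  if (want_cent) {
    cent_table <- data.frame(
      node = nodes,
      strength_diff = rowSums(abs(WA)) - rowSums(abs(WB)),
      strength_p = perm_p(cent_ge$strength),
      ei_diff = rowSums(WA) - rowSums(WB),
      ei_p = perm_p(cent_ge$expected_influence),
      row.names = NULL)
  }
  structure(list(
    M_observed = M_obs,
    S_observed = S_obs,
    global_strength_A = gsA, global_strength_B = gsB,
    p_M = if ("structure" %in% tests) perm_p(sum(M_perm >= M_obs)) else NA_real_,
    p_S = if ("global" %in% tests) perm_p(sum(S_perm >= S_obs)) else NA_real_,
    M_permutations = M_perm, S_permutations = S_perm,
    edge_tests = edge_table, centrality_tests = cent_table,
    W_A = WA, W_B = WB,
    n_A = nA, n_B = nB, n_permutations = n_perm, seed = as.integer(seed)),
    class = "nct_result")
}

#' @export
print.nct_result <- function(x, ...) {
  cat("network comparison test (", x$n_permutations, " permutations)\n",
      sep = "")
  cat(sprintf("  structure: M = %.4f, p = %.4f\n", x$M_observed, x$p_M))
  cat(sprintf("  global strength: %.3f vs %.3f, S = %.4f, p = %.4f\n",
              x$global_strength_A, x$global_strength_B, x$S_observed, x$p_S))
  if (!is.null(x$edge_tests))
    cat("  edges with FDR p < .05:",
        sum(x$edge_tests$p_fdr < 0.05), "of", nrow(x$edge_tests), "\n")
  invisible(x)
}

#' Median split of a dataset on a total-score column
#'
#' Participants strictly below the median form the low group, strictly above
#' the high group; participants exactly at the median are excluded (their
#' count is recorded in the `n_excluded` attribute).
#'
#' @param data a [questionnaire_dataset()] (or matrix).
#' @param column the splitting score: a numeric vector of length `n`, the
#'   name of a column in `data$groups`, or the name of a score column.
#' @return list with `low` and `high` ([questionnaire_dataset()]s), `median`,
#'   `n_low`, `n_high`, `n_excluded`.
#' @export
median_split <- function(data, column) {
  X <- as_score_matrix(data)
  if (is.numeric(column) && length(column) == nrow(X)) {
    total <- column
  } else if (inherits(data, "questionnaire_dataset") &&
             !is.null(data$groups) && column %in% names(data$groups)) {
    total <- data$groups[[column]]
  } else if (column %in% colnames(X)) {
    total <- X[, column]
  } else {
    stop("split column '", column, "' not found")
  }
  med <- median(total)
  lo <- total < med
  hi <- total > med
  if (!any(lo) || !any(hi))
    stop("degenerate median split: one group is empty")
  subset_ds <- function(keep) {
    if (inherits(data, "questionnaire_dataset")) {
      questionnaire_dataset(
        data$scores[keep, , drop = FALSE],
        communities = data$communities,
        groups = if (!is.null(data$groups))
          data$groups[keep, , drop = FALSE] else NULL)
    } else {
      questionnaire_dataset(X[keep, , drop = FALSE])
    }
  }
  out <- list(low = subset_ds(lo), high = subset_ds(hi), median = med,
              n_low = sum(lo), n_high = sum(hi),
              n_excluded = sum(!lo & !hi))
  out
}
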