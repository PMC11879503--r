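#' Marginal specification for one questionnaire subscale
#'
#' Describes the bounded, integer-valued distribution of a subscale sum score:
#' hard bounds, target mean and SD (score units), and the expected direction
#' of skew. Generated scores always respect the bounds exactly; the mean is
#' matched exactly in distribution, while SD and skew are matched only
#' approximately by the shifted-binomial family (see [sample_copula()]).
#'
#' @param name node label.
#' @param min_score,max_score integer score bounds, `min_score < max_score`.
#' @param mean target mean, within the bounds.
#' @param sd target standard deviation, positive.
#' @param skew_direction one of `"left"`, `"right"`, `"none"`.
#' @return an object of class `marginal_spec`.
#' @export
marginal_spec <- function(name, min_score, max_score, mean, sd,
                          skew_direction = c("none", "left", "right")) {
  skew_direction <- match.arg(skew_direction)
  if (!(min_score < max_score)) stop("min_score must be < max_score")
  if (mean < min_score || mean > max_score)
    stop("infeasible marginal '", name, "': mean outside [min, max]")
  if (sd <= 0) stop("sd must be positive")
  structure(list(name = name, min_score = as.integer(min_score),
                 max_score = as.integer(max_score), mean = mean, sd = sd,
                 skew_direction = skew_direction),
            class = "marginal_spec")
}

#' Ground-truth precision (inverse covariance) specification
#'
#' Edge list on the partial-correlation scale: each entry `(i, j, rho)`
#' requests partial correlation `rho` between nodes `i` and `j` given all
#' others. [build_precision()] turns this into a symmetric positive-definite
#' precision matrix.
#'
#' @param p node count.
#' @param edges data frame (or 3-column matrix) with columns `i`, `j`, `rho`
#'   (`i < j`, `|rho| < 1`), or `NULL` for the empty network.
#' @param diagonal_inflation nonnegative scalar added to the unit diagonal
#'   before any geometric inflation needed for positive definiteness.
#' @return an object of class `precision_spec`.
#' @export
precision_spec <- function(p, edges = NULL, diagonal_inflation = 0) {
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(i = integer(), j = integer(), rho = numeric())
  } else {
    edges <- as.data.frame(edges)
    names(edges)[1:3] <- c("i", "j", "rho")
    if (any(edges$i >= edges$j)) stop("edges must have i < j")
    if (any(edges$j > p) || any(edges$i < 1)) stop("edge index out of range")
    if (any(abs(edges$rho) >= 1)) stop("|partial correlation| must be < 1")
    if (anyDuplicated(edges[, c("i", "j")])) stop("duplicate edges")
  }
  if (diagonal_inflation < 0) stop("diagonal_inflation must be >= 0")
  structure(list(p = as.integer(p), edges = edges,
                 diagonal_inflation = diagonal_inflation),
            class = "precision_spec")
}

#' Build a precision matrix realizing requested partial correlations
#'
#' Starts from the identity and sets off-diagonals so that
#' `-K[i,j] / sqrt(K[i,i] * K[j,j])` equals each requested partial
#' correlation. If the result is not positive definite, the diagonal is
#' inflated geometrically (factor 1.3 per step, at most 50 steps) until it
#' is; inflation shrinks the achieved partials, which are recorded in the
#' `achieved_partials` attribute.
#'
#' @param spec a [precision_spec()].
#' @return a `p x p` precision matrix with attributes `achieved_partials`
#'   (data frame `i, j, rho`) and `inflation_steps`.
#' @export
build_precision <- function(spec) {
  stopifnot(inherits(spec, "precision_spec"))
  p <- spec$p
  K <- diag(p)
  for (r in seq_len(nrow(spec$edges))) {
    e <- spec$edges[r, ]
    K[e$i, e$j] <- K[e$j, e$i] <- -e$rho  # unit diagonal: -rho*sqrt(1*1)
  }
  d <- spec$diagonal_inflation
  steps <- 0L
  repeat {
    Ki <- K + diag(d, p)
    ev <- min(eigen(Ki, symmetric = TRUE, only.values = TRUE)$values)
    if (ev > 1e-10) break
    steps <- steps + 1L
    if (steps > 50L) {
      bad <- spec$edges[order(-abs(spec$edges$rho)), ]
      stop("requested partial correlations jointly infeasible after 50 ",
           "diagonal-inflation steps; largest offending edges: ",
           paste(sprintf("(%d,%d,%.3f)", head(bad$i, 3), head(bad$j, 3),
                         head(bad$rho, 3)), collapse = " "))
    }
    d <- if (d == 0) 0.05 else d * 1.3
  }
  K <- K + diag(d, p)
  ach <- spec$edges
  if (nrow(ach)) {
    ach$rho <- -K[cbind(ach$i, ach$j)] /
      sqrt(K[cbind(ach$i, ach$i)] * K[cbind(ach$j, ach$j)])
  }
  attr(K, "achieved_partials") <- ach
  attr(K, "inflation_steps") <- steps
  K
}

#' Partial correlations implied by a precision matrix
#'
#' Standard Gaussian graphical model identity:
#' `rho_ij.rest = -K[i,j] / sqrt(K[i,i] * K[j,j])`.
#'
#' @param K symmetric positive-definite precision matrix.
#' @return symmetric matrix of partial correlations with zero diagonal.
#' @export
partial_corr_from_precision <- function(K) {
  check_square_symmetric(K, "K")
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("K is not positive definite (min eigenvalue ", ev, ")")
  d <- 1 / sqrt(diag(K))
  P <- -K * tcrossprod(d)
  diag(P) <- 0
  attributes(P) <- attributes(P)[c("dim", "dimnames")]
  P
}

#' Ground-truth linear-Gaussian DAG specification
#'
#' @param p node count.
#' @param arcs data frame (or 3-column matrix) with columns `parent`, `child`,
#'   `coef` (node indices), or `NULL` for the empty DAG.
#' @param noise_sd residual SD, scalar or length-`p` vector.
#' @return an object of class `dag_spec`.
#' @export
dag_spec <- function(p, arcs = NULL, noise_sd = 1) {
  if (is.null(arcs) || NROW(arcs) == 0) {
    arcs <- data.frame(parent = integer(), child = integer(), coef = numeric())
  } else {
    arcs <- as.data.frame(arcs)
    names(arcs)[1:3] <- c("parent", "child", "coef")
    if (!all(is.finite(arcs$coef))) stop("coefficients must be finite")
    if (any(arcs$parent == arcs$child)) stop("self-loop arc")
  }
  noise_sd <- rep_len(noise_sd, p)
  if (any(noise_sd <= 0)) stop("noise_sd must be positive")
  spec <- structure(list(p = as.integer(p), arcs = arcs, noise_sd = noise_sd),
                    class = "dag_spec")
  ord <- topological_order(arcs_to_amat(arcs, p))
  if (is.null(ord)) {
    cyc <- find_cycle(arcs_to_amat(arcs, p))
    stop("arc set is cyclic: ", paste(cyc, collapse = " -> "))
  }
  attr(spec, "topological_order") <- ord
  spec
}

#' @noRd
arcs_to_amat <- function(arcs, p) {
  A <- matrix(0L, p, p)
  if (nrow(arcs)) A[cbind(arcs$parent, arcs$child)] <- 1L
  A
}

# Kahn's algorithm; NULL if cyclic.
#' @noRd
topological_order <- function(A) {
  p <- nrow(A)
  indeg <- colSums(A)
  ord <- integer(0)
  avail <- which(indeg == 0)
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    ord <- c(ord, v)
    ch <- which(A[v, ] == 1L)
    indeg[ch] <- indeg[ch] - 1L
    avail <- c(avail, ch[indeg[ch] == 0])
  }
  if (length(ord) < p) NULL else ord
}

# Return one directed cycle (node index sequence) for an error message.
#' @noRd
find_cycle <- function(A) {
  p <- nrow(A)
  color <- integer(p)  # 0 white, 1 grey, 2 black
  stack <- integer(0)
  res <- NULL
  visit <- function(v) {
    if (!is.null(res)) return()
    color[v] <<- 1L
    stack <<- c(stack, v)
    for (w in which(A[v, ] == 1L)) {
      if (!is.null(res)) return()
      if (color[w] == 1L) {
        res <<- c(stack[which(stack == w):length(stack)], w)
        return()
      }
      if (color[w] == 0L) visit(w)
    }
    color[v] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (v in seq_len(p)) if (color[v] == 0L) visit(v)
  res
}

#' Questionnaire dataset container
#'
#' @param scores numeric `n x p` matrix of subscale scores (no missing values,
#'   every column with nonzero variance unless `check = FALSE`).
#' @param node_names length-`p` labels (default: column names).
#' @param communities named character vector mapping node to community (e.g.
#'   SPQ/ERQ/DASS), or `NULL`.
#' @param groups optional data frame of per-participant categorical or numeric
#'   labels (gender, age band, total scores ...).
#' @param truth optional list recording the generating ground truth.
#' @param check validate invariants (default `TRUE`).
#' @return an object of class `questionnaire_dataset`.
#' @export
questionnaire_dataset <- function(scores, node_names = NULL,
                                  communities = NULL, groups = NULL,
                                  truth = NULL, check = TRUE) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (!is.null(node_names)) colnames(scores) <- node_names
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("V", seq_len(ncol(scores)))
  if (check) {
    if (anyNA(scores)) stop("scores contain missing values")
    v <- apply(scores, 2, var)
    if (any(v == 0))
      stop("zero-variance column(s): ",
           paste(colnames(scores)[v == 0], collapse = ", "))
    if (!is.null(groups) && NROW(groups) != nrow(scores))
      stop("groups must have one row per participant")
  }
  structure(list(scores = scores, node_names = colnames(scores),
                 communities = communities,
                 groups = if (!is.null(groups)) as.data.frame(groups) else NULL,
                 truth = truth),
            class = "questionnaire_dataset")
}

#' @export
print.questionnaire_dataset <- function(x, ...) {
  cat("questionnaire_dataset:", nrow(x$scores), "participants x",
      ncol(x$scores), "nodes\n")
  cat("  nodes:", paste(x$node_names, collapse = ", "), "\n")
  if (!is.null(x$communities))
    cat("  communities:", paste(unique(x$communities), collapse = ", "), "\n")
  if (!is.null(x$groups))
    cat("  group columns:", paste(names(x$groups), collapse = ", "), "\n")
  invisible(x)
}

# Shifted-binomial parameters matching a marginal's mean exactly.
#' @noRd
binomial_params <- function(m) {
  size <- m$max_score - m$min_score
  q <- (m$mean - m$min_score) / size
  list(size = size, q = q)
}

#' Gaussian-copula sampler with bounded discrete marginals
#'
#' Draws latent multivariate-normal vectors with the correlation structure
#' implied by `dependence`, then maps each latent column through its normal
#' CDF and the inverse CDF of a shifted binomial on `[min_score, max_score]`
#' whose success probability matches the target mean. With `marginals = NULL`
#' the latent (continuous) variables are returned directly.
#'
#' @param n sample size; `n < 10 p` triggers a warning (downstream network
#'   estimates will be unstable).
#' @param dependence a precision matrix (`input = "precision"`, default) or a
#'   correlation matrix (`input = "correlation"`).
#' @param marginals list of [marginal_spec()] (length `p`) or `NULL`.
#' @param seed integer seed; the same call with the same seed returns an
#'   identical dataset.
#' @param input how to interpret `dependence`.
#' @param node_names,communities,groups passed to [questionnaire_dataset()].
#' @return a [questionnaire_dataset()]; `truth` records the latent
#'   correlation matrix, the partial correlations, the seed and marginals.
#' @export
sample_copula <- function(n, dependence, marginals = NULL, seed,
                          input = c("precision", "correlation"),
                          node_names = NULL, communities = NULL,
                          groups = NULL) {
  input <- match.arg(input)
  check_square_symmetric(dependence, "dependence")
  p <- nrow(dependence)
  if (input == "precision") {
    R <- stats::cov2cor(solve(dependence))
    Ptrue <- partial_corr_from_precision(dependence)
  } else {
    R <- dependence
    if (max(abs(diag(R) - 1)) > 1e-8) stop("correlation matrix needs unit diagonal")
    Ptrue <- partial_corr_from_precision(solve(R))
  }
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("dependence matrix is not positive definite")
  if (!is.null(marginals)) {
    if (length(marginals) != p) stop("need one marginal per node")
    if (is.null(node_names))
      node_names <- vapply(marginals, function(m) m$name, character(1))
  }
  if (n < 10 * p)
    warning("n < 10p: downstream network estimates will be unstable")

  X <- withr::with_seed(as.integer(seed), {
    Z <- matrix(rnorm(n * p), n, p) %*% chol(R)
    if (is.null(marginals)) {
      Z
    } else {
      U <- pnorm(Z)
      out <- matrix(0, n, p)
      for (j in seq_len(p)) {
        bp <- binomial_params(marginals[[j]])
        out[, j] <- marginals[[j]]$min_score + qbinom(U[, j], bp$size, bp$q)
      }
      out
    }
  })
  colnames(X) <- node_names %||% paste0("V", seq_len(p))
  questionnaire_dataset(
    X, communities = communities, groups = groups,
    truth = list(latent_correlation = R, partial_correlations = Ptrue,
                 seed = as.integer(seed), marginals = marginals))
}

#' Sample from a linear-Gaussian DAG
#'
#' Each node equals the coefficient-weighted sum of its parents plus Gaussian
#' noise, generated in topological order.
#'
#' @param n sample size.
#' @param spec a [dag_spec()].
#' @param seed integer seed.
#' @param node_names,communities passed to [questionnaire_dataset()].
#' @return a [questionnaire_dataset()] with `truth` recording the generating
#'   structure.
#' @export
sample_linear_dag <- function(n, spec, seed, node_names = NULL,
                              communities = NULL) {
  stopifnot(inherits(spec, "dag_spec"))
  p <- spec$p
  ord <- attr(spec, "topological_order")
  X <- withr::with_seed(as.integer(seed), {
    M <- matrix(0, n, p)
    for (v in ord) {
      pa <- spec$arcs[spec$arcs$child == v, , drop = FALSE]
      mu <- 0
      if (nrow(pa)) mu <- M[, pa$parent, drop = FALSE] %*% pa$coef
      M[, v] <- mu + rnorm(n, sd = spec$noise_sd[v])
    }
    M
  })
  colnames(X) <- node_names %||% paste0("V", seq_len(p))
  questionnaire_dataset(X, communities = communities,
                        truth = list(dag = spec, seed = as.integer(seed)))
}

#' Closed-form covariance implied by a linear-Gaussian DAG
#'
#' `Sigma = (I - B)^-T D (I - B)^-1` where `B[parent, child]` holds the arc
#' coefficients and `D` the noise variances.
#'
#' @param spec a [dag_spec()].
#' @return the `p x p` covariance matrix.
#' @export
dag_covariance <- function(spec) {
  stopifnot(inherits(spec, "dag_spec"))
  p <- spec$p
  B <- matrix(0, p, p)
  if (nrow(spec$arcs)) B[cbind(spec$arcs$parent, spec$arcs$child)] <- spec$arcs$coef
  Minv <- solve(diag(p) - B)  # X = t(Minv) %*% eps in stacked form
  t(Minv) %*% diag(spec$noise_sd^2, p) %*% Minv
}

#' The eight-subscale descriptive fixture
#'
#' Marginal specifications (bounds, means, SDs, skew direction) for the eight
#' subscale nodes — three SPQ schizotypy dimensions, two ERQ emotion-regulation
#' strategies, three DASS negative-affect dimensions — together with their
#' instrument communities.
#'
#' @return list with elements `marginals` (list of 8 [marginal_spec()]) and
#'   `communities` (named character vector).
#' @export
table1_marginals <- function() {
  m <- list(
    marginal_spec("SPQ-CP", 0, 8,  2.83, 2.08, "right"),
    marginal_spec("SPQ-I",  0, 8,  2.39, 2.06, "right"),
    marginal_spec("SPQ-D",  0, 6,  1.06, 1.37, "right"),
    marginal_spec("ERQ-R",  6, 30, 18.33, 6.72, "left"),
    marginal_spec("ERQ-S",  4, 20, 10.28, 4.32, "right"),
    marginal_spec("DASS-D", 0, 21, 2.93, 3.89, "right"),
    marginal_spec("DASS-A", 0, 21, 4.11, 4.08, "right"),
    marginal_spec("DASS-S", 0, 21, 3.91, 4.05, "right"))
  communities <- c("SPQ-CP" = "SPQ", "SPQ-I" = "SPQ", "SPQ-D" = "SPQ",
                   "ERQ-R" = "ERQ", "ERQ-S" = "ERQ",
                   "DASS-D" = "DASS", "DASS-A" = "DASS", "DASS-S" = "DASS")
  list(marginals = m, communities = communities)
}

#' Concatenated per-group samples with perturbed network structure
#'
#' Group differences are injected only through precision-matrix edges (not
#' marginals), so that network-comparison tests target structure. An empty
#' perturbation list gives the null case: all groups share one distribution.
#'
#' @param n_per_group named integer vector of per-group sample sizes.
#' @param base_spec a [precision_spec()] shared by all groups.
#' @param delta_edges `NULL`, or a named list (names = group names) of data
#'   frames `i, j, rho` overriding/adding edges of `base_spec` for that group.
#' @param marginals list of [marginal_spec()] or `NULL` (continuous).
#' @param seed integer master seed; each group draws from its own substream.
#' @param communities optional named community vector.
#' @param group_column name of the grouping column (default `"group"`).
#' @return a [questionnaire_dataset()] with a grouping column and per-group
#'   ground truth in `truth`.
#' @export
grouped_dataset <- function(n_per_group, base_spec, delta_edges = NULL,
                            marginals = NULL, seed, communities = NULL,
                            group_column = "group") {
  stopifnot(inherits(base_spec, "precision_spec"))
  gnames <- names(n_per_group) %||% paste0("G", seq_along(n_per_group))
  names(n_per_group) <- gnames
  truth <- list(seed = as.integer(seed), groups = list())
  pieces <- vector("list", length(gnames))
  for (g in seq_along(gnames)) {
    spec_g <- base_spec
    dg <- delta_edges[[gnames[g]]]
    if (!is.null(dg) && NROW(dg)) {
      dg <- as.data.frame(dg)
      names(dg)[1:3] <- c("i", "j", "rho")
      ed <- spec_g$edges
      for (r in seq_len(nrow(dg))) {
        hit <- which(ed$i == dg$i[r] & ed$j == dg$j[r])
        if (length(hit)) ed$rho[hit] <- dg$rho[r]
        else ed <- rbind(ed, dg[r, c("i", "j", "rho")])
      }
      ed <- ed[ed$rho != 0, , drop = FALSE]
      spec_g <- precision_spec(base_spec$p, ed, base_spec$diagonal_inflation)
    }
    K <- build_precision(spec_g)
    ds <- sample_copula(n_per_group[g], K, marginals = marginals,
                        seed = substream_seed(seed, g),
                        communities = communities)
    truth$groups[[gnames[g]]] <- ds$truth
    pieces[[g]] <- ds$scores
  }
  scores <- do.call(rbind, pieces)
  groups <- data.frame(rep(gnames, n_per_group), stringsAsFactors = FALSE)
  names(groups) <- group_column
  questionnaire_dataset(scores, communities = communities, groups = groups,
                        truth = truth)
}

#' Write/read a questionnaire dataset as CSV plus sidecar JSON
#'
#' Scores and group columns go to a header CSV; node names, communities, seed
#' and any ground-truth spec go to `<path>.json`.
#'
#' @param data a [questionnaire_dataset()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_questionnaire_csv <- function(data, path) {
  stopifnot(inherits(data, "questionnaire_dataset"))
  df <- as.data.frame(data$scores)
  if (!is.null(data$groups)) df <- cbind(df, data$groups)
  write.csv(df, path, row.names = FALSE)
  meta <- list(node_names = data$node_names,
               communities = as.list(data$communities %||% list()),
               group_columns = names(data$groups) %||% character(0),
               truth = serialize_truth(data$truth))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}

#' @noRd
serialize_truth <- function(truth) {
  if (is.null(truth)) return(NULL)
  out <- truth
  for (nm in names(out)) {
    if (is.matrix(out[[nm]])) out[[nm]] <- as.data.frame(out[[nm]])
  }
  out
}

#' @rdname write_questionnaire_csv
#' @export
read_questionnaire_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta_path <- paste0(path, ".json")
  node_names <- NULL; communities <- NULL; group_cols <- character(0)
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    node_names <- meta$node_names
    if (length(meta$communities)) communities <- unlist(meta$communities)
    group_cols <- meta$group_columns %||% character(0)
  }
  if (is.null(node_names))
    node_names <- names(df)[vapply(df, is.numeric, logical(1))]
  groups <- NULL
  if (length(group_cols)) groups <- df[, group_cols, drop = FALSE]
  questionnaire_dataset(as.matrix(df[, node_names, drop = FALSE]),
                        communities = communities, groups = groups)
}
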