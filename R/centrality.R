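#' Node centrality indices of a weighted network
#'
#' Strength is the sum of absolute incident weights, expected influence (EI)
#' the signed sum. Path-based indices use the distance transform
#' `d = 1/|w|` on edges: closeness is the inverse of the summed
#' shortest-path distance to all reachable nodes (a `reachable` count is
#' recorded for disconnected networks), betweenness is Brandes' fractional
#' shortest-path count excluding endpoints.
#'
#' @param net a [weighted_network()].
#' @return data frame with columns `node`, `strength`, `closeness`,
#'   `betweenness`, `expected_influence`, `reachable`.
#' @export
node_centralities <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  W <- net$W
  p <- ncol(W)
  strength <- rowSums(abs(W))
  ei <- rowSums(W)
  D <- distance_matrix(net)
  closeness <- vapply(seq_len(p), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else 1 / sum(d)
  }, numeric(1))
  reachable <- vapply(seq_len(p), function(i) sum(is.finite(D[i, -i])),
                      integer(1))
  g <- network_igraph(net)
  btw <- rep(0, p)
  if (igraph::ecount(g) > 0) {
    ew <- 1 / igraph::E(g)$weight
    btw <- igraph::betweenness(g, directed = FALSE, weights = ew)
  }
  data.frame(node = net$node_names, strength = strength,
             closeness = closeness, betweenness = unname(btw),
             expected_influence = ei, reachable = reachable,
             row.names = NULL)
}

# Shortest-path distance matrix under d = 1/|w|; Inf for unreachable pairs.
#' @noRd
distance_matrix <- function(net) {
  g <- network_igraph(net)
  if (igraph::ecount(g) == 0) {
    p <- length(net$node_names)
    D <- matrix(Inf, p, p); diag(D) <- 0
    return(D)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

#' Node predictability (variance explained by all other nodes)
#'
#' For each node, the R-squared of the least-squares regression of the
#' (z-scored) node on all other (z-scored) nodes.
#'
#' @param data scores ([questionnaire_dataset()], matrix or data frame);
#'   requires `n > p + 1`.
#' @return data frame with columns `node`, `predictability`.
#' @export
predictability <- function(data) {
  X <- as_score_matrix(data)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stop("predictability requires n > p + 1")
  Z <- zscore_columns(X)
  S <- crossprod(Z) / (n - 1)
  r2 <- vapply(seq_len(p), function(i) {
    Sxx <- S[-i, -i, drop = FALSE]
    sxy <- S[-i, i]
    beta <- tryCatch(solve(Sxx, sxy),
                     error = function(e) stop("singular design when predicting ",
                                              colnames(X)[i]))
    max(0, min(1, as.numeric(crossprod(sxy, beta)) / S[i, i]))
  }, numeric(1))
  data.frame(node = colnames(X), predictability = r2, row.names = NULL)
}

#' Bridge centrality indices
#'
#' Centrality restricted to cross-community connections. Bridge strength and
#' bridge EI (1-step) sum absolute and signed weights to nodes outside the
#' node's own community; bridge closeness is the inverse of the mean
#' shortest-path distance (`d = 1/|w|`) to all nodes outside the community;
#' bridge betweenness counts the shortest paths between pairs of nodes from
#' two different communities that pass through the node (each shortest path
#' counted once, endpoints excluded).
#'
#' @param net a [weighted_network()].
#' @param communities named community vector (defaults to the network's own).
#' @return data frame with columns `node`, `bridge_strength`,
#'   `bridge_closeness`, `bridge_betweenness`,
#'   `bridge_expected_influence_1step`.
#' @export
bridge_centralities <- function(net, communities = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  communities <- communities %||% net$communities
  if (is.null(communities)) stop("communities required for bridge indices")
  comm <- communities[net$node_names]
  if (anyNA(comm)) stop("every node needs a community label")
  if (length(unique(comm)) < 2)
    stop("bridge indices undefined with a single community")
  W <- net$W
  p <- ncol(W)
  other <- outer(comm, comm, "!=")
  bs <- rowSums(abs(W) * other)
  bei <- rowSums(W * other)
  D <- distance_matrix(net)
  bcl <- vapply(seq_len(p), function(i) {
    d <- D[i, other[i, ]]
    if (any(!is.finite(d))) 0 else 1 / mean(d)
  }, numeric(1))
  bbw <- bridge_betweenness_counts(net, comm)
  data.frame(node = net$node_names, bridge_strength = bs,
             bridge_closeness = bcl, bridge_betweenness = bbw,
             bridge_expected_influence_1step = bei, row.names = NULL)
}

# For every unordered pair (s, t) with comm(s) != comm(t), enumerate all
# shortest s-t paths (d = 1/|w|) and add, for each interior node, the number
# of those paths passing through it. Exact; intended for the small networks
# (p <= ~15) this package targets.
#' @noRd
bridge_betweenness_counts <- function(net, comm) {
  p <- length(net$node_names)
  counts <- setNames(rep(0, p), net$node_names)
  g <- network_igraph(net)
  if (igraph::ecount(g) == 0) return(unname(counts))
  ew <- 1 / igraph::E(g)$weight
  for (s in seq_len(p - 1)) {
    asp <- NULL
    for (t in (s + 1):p) {
      if (comm[s] == comm[t]) next
      paths <- suppressWarnings(
        igraph::all_shortest_paths(g, from = s, to = t, weights = ew)$vpaths)
      for (pa in paths) {
        interior <- setdiff(as.integer(pa), c(s, t))
        counts[interior] <- counts[interior] + 1
      }
    }
  }
  unname(counts)
}

#' Combined centrality table with z-standardized columns
#'
#' Joins node centralities, predictability (when raw data are supplied) and
#' bridge indices (when communities are available); adds `z_`-prefixed
#' columns standardized across nodes (mean 0, SD 1; constant columns get 0).
#'
#' @param net a [weighted_network()].
#' @param data optional raw scores for predictability.
#' @param communities optional community vector for bridge indices.
#' @return data frame, one row per node.
#' @export
centrality_table <- function(net, data = NULL, communities = NULL) {
  tab <- node_centralities(net)
  tab$reachable <- NULL
  if (!is.null(data)) tab <- merge(tab, predictability(data), by = "node",
                                   sort = FALSE)
  communities <- communities %||% net$communities
  if (!is.null(communities) &&
      length(unique(communities[net$node_names])) > 1) {
    tab <- merge(tab, bridge_centralities(net, communities), by = "node",
                 sort = FALSE)
  }
  num <- setdiff(names(tab), "node")
  for (v in num) {
    s <- sd(tab[[v]])
    tab[[paste0("z_", v)]] <-
      if (is.na(s) || s == 0) rep(0, nrow(tab)) else (tab[[v]] - mean(tab[[v]])) / s
  }
  tab
}

#' Select bridge nodes by percentile cutoff
#'
#' Nodes whose bridge index lies strictly above the given percentile (linear
#' interpolation) of that index across all nodes.
#'
#' @param table a data frame with a `node` column and bridge index columns
#'   (as from [bridge_centralities()] or [centrality_table()]).
#' @param percentile cutoff percentile (default 80).
#' @param indices which bridge columns to use (default: all `bridge_*`
#'   columns present).
#' @return named list (one entry per index) of selected node labels.
#' @export
select_bridge_nodes <- function(table, percentile = 80, indices = NULL) {
  indices <- indices %||% grep("^bridge_", names(table), value = TRUE)
  indices <- setdiff(indices, grep("^z_", names(table), value = TRUE))
  out <- list()
  for (v in indices) {
    cut <- quantile(table[[v]], percentile / 100, type = 7, names = FALSE)
    out[[v]] <- table$node[table[[v]] > cut]
  }
  out
}
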