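# Independent oracles used across the test suite. These deliberately use
# different algorithms from the package code paths they check.

# --- graphical lasso: proximal-gradient (ISTA) solver ------------------------
# minimize  -log det K + tr(RK) + lambda * sum_{i!=j} |K_ij|
# with backtracking on the smooth part; run to tight tolerance.
oracle_glasso_pg <- function(R, lambda, maxit = 100000, tol = 1e-10) {
  p <- nrow(R)
  fsmooth <- function(K) {
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    -2 * sum(log(diag(ch))) + sum(R * K)
  }
  prox <- function(M, t) {
    out <- sign(M) * pmax(abs(M) - t, 0)
    diag(out) <- diag(M)
    out
  }
  K <- diag(1 / diag(R))
  s <- 1
  for (it in seq_len(maxit)) {
    G <- R - solve(K)
    fk <- fsmooth(K)
    repeat {
      Kn <- prox(K - s * G, s * lambda)
      d <- Kn - K
      if (fsmooth(Kn) <= fk + sum(G * d) + sum(d * d) / (2 * s) + 1e-14) break
      s <- s / 2
      if (s < 1e-14) return(K)
    }
    if (max(abs(Kn - K)) < tol) return(Kn)
    K <- Kn
    s <- min(s * 1.1, 10)
  }
  K
}

# --- shortest paths by exhaustive simple-path enumeration --------------------
# Returns, for a weight matrix W and pair (s, t): the shortest distance under
# d = 1/|w| and the list of all shortest paths (node index vectors).
oracle_shortest_paths <- function(W, s, t, tol = 1e-9) {
  p <- nrow(W)
  paths <- list()
  rec <- function(path, v) {
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    for (w in which(W[v, ] != 0)) {
      if (!(w %in% path)) rec(c(path, w), w)
    }
  }
  rec(s, s)
  if (!length(paths)) return(list(dist = Inf, paths = list()))
  lens <- vapply(paths, function(pa) {
    sum(1 / abs(W[cbind(pa[-length(pa)], pa[-1])]))
  }, numeric(1))
  dmin <- min(lens)
  list(dist = dmin, paths = paths[lens <= dmin + tol])
}

# Full centrality oracle: strength, EI, closeness (1/sum of shortest-path
# distances to reachable nodes), fractional Brandes betweenness, and the four
# bridge indices, all from the path enumeration above.
oracle_centralities <- function(W, communities = NULL) {
  p <- nrow(W)
  D <- matrix(Inf, p, p); diag(D) <- 0
  sp <- vector("list", p * p); dim(sp) <- c(p, p)
  for (s in 1:(p - 1)) for (t in (s + 1):p) {
    res <- oracle_shortest_paths(W, s, t)
    D[s, t] <- D[t, s] <- res$dist
    sp[[s, t]] <- res$paths
  }
  strength <- rowSums(abs(W))
  ei <- rowSums(W)
  closeness <- vapply(1:p, function(i) {
    d <- D[i, -i][is.finite(D[i, -i])]
    if (!length(d)) 0 else 1 / sum(d)
  }, numeric(1))
  betweenness <- rep(0, p)
  for (s in 1:(p - 1)) for (t in (s + 1):p) {
    paths <- sp[[s, t]]
    if (!length(paths)) next
    for (pa in paths) {
      interior <- setdiff(pa, c(s, t))
      betweenness[interior] <- betweenness[interior] + 1 / length(paths)
    }
  }
  out <- data.frame(strength = strength, closeness = closeness,
                    betweenness = betweenness, expected_influence = ei)
  if (!is.null(communities)) {
    other <- outer(communities, communities, "!=")
    out$bridge_strength <- rowSums(abs(W) * other)
    out$bridge_expected_influence_1step <- rowSums(W * other)
    out$bridge_closeness <- vapply(1:p, function(i) {
      d <- D[i, other[i, ]]
      if (any(!is.finite(d))) 0 else 1 / mean(d)
    }, numeric(1))
    bbw <- rep(0, p)
    for (s in 1:(p - 1)) for (t in (s + 1):p) {
      if (communities[s] == communities[t]) next
      for (pa in sp[[s, t]]) {
        interior <- setdiff(pa, c(s, t))
        bbw[interior] <- bbw[interior] + 1
      }
    }
    out$bridge_betweenness <- bbw
  }
  out
}

# Random sparse symmetric weight matrix for oracle comparisons.
random_weight_matrix <- function(p, n_edges, seed) {
  withr::with_seed(seed, {
    W <- matrix(0, p, p)
    pairs <- t(combn(p, 2))
    sel <- pairs[sample.int(nrow(pairs), n_edges), , drop = FALSE]
    w <- runif(n_edges, 0.1, 0.45) * sample(c(-1, 1), n_edges, TRUE)
    W[sel] <- w
    W + t(W)
  })
}

# --- DAG enumeration ---------------------------------------------------------
# All 25 acyclic orientations over 3 nodes: each unordered pair is absent,
# forward, or backward; drop the two 3-cycles.
oracle_all_dags3 <- function(nodes = c("A", "B", "C")) {
  out <- list()
  states <- expand.grid(e12 = 0:2, e13 = 0:2, e23 = 0:2)
  for (r in seq_len(nrow(states))) {
    A <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
    st <- states[r, ]
    if (st$e12 == 1) A[1, 2] <- 1L else if (st$e12 == 2) A[2, 1] <- 1L
    if (st$e13 == 1) A[1, 3] <- 1L else if (st$e13 == 2) A[3, 1] <- 1L
    if (st$e23 == 1) A[2, 3] <- 1L else if (st$e23 == 2) A[3, 2] <- 1L
    # acyclic iff some topological order exists
    ok <- tryCatch({
      dag_structure(which(A == 1L, arr.ind = TRUE), nodes = nodes)
    }, error = function(e) NULL)
    if (!is.null(ok)) out[[length(out) + 1]] <- ok
  }
  out
}

dag_skeleton <- function(dag) (dag$amat + t(dag$amat)) > 0

dag_vstructures <- function(dag) {
  A <- dag$amat
  skel <- dag_skeleton(dag)
  vs <- character(0)
  for (k in seq_len(nrow(A))) {
    pa <- which(A[, k] == 1L)
    if (length(pa) < 2) next
    for (a in seq_len(length(pa) - 1)) for (b in (a + 1):length(pa)) {
      if (!skel[pa[a], pa[b]])
        vs <- c(vs, paste(sort(c(pa[a], pa[b]))[1], sort(c(pa[a], pa[b]))[2],
                          k, sep = "-"))
    }
  }
  sort(vs)
}

# --- shared synthetic fixtures ----------------------------------------------
# Canonical 8-node ground truth: five edges with |partial rho| in [0.15, 0.3].
base_truth_spec <- function() {
  precision_spec(8, data.frame(
    i   = c(1, 3, 5, 2, 1),
    j   = c(2, 4, 6, 7, 8),
    rho = c(0.25, 0.30, 0.20, -0.18, 0.15)))
}

true_edge_pairs <- function(spec = base_truth_spec()) {
  cbind(spec$edges$i, spec$edges$j)
}
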