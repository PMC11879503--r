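#' Directed acyclic graph structure
#'
#' @param arcs two-column matrix or data frame of (parent, child) node
#'   indices or names, or `NULL` for the empty DAG.
#' @param nodes character vector of node names.
#' @return an object of class `dag_structure`.
#' @export
dag_structure <- function(arcs = NULL, nodes) {
  p <- length(nodes)
  A <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  if (!is.null(arcs) && NROW(arcs)) {
    arcs <- as.matrix(arcs)
    if (is.character(arcs)) {
      arcs <- cbind(match(arcs[, 1], nodes), match(arcs[, 2], nodes))
      if (anyNA(arcs)) stop("arc references unknown node")
    }
    storage.mode(arcs) <- "integer"
    if (any(arcs[, 1] == arcs[, 2])) stop("self-loop arc")
    if (anyDuplicated(arcs)) stop("duplicate arc")
    A[arcs] <- 1L
  }
  if (is.null(topological_order(A))) {
    cyc <- find_cycle(A)
    stop("arc set is cyclic: ", paste(nodes[cyc], collapse = " -> "))
  }
  structure(list(amat = A, nodes = nodes, p = p), class = "dag_structure")
}

#' @export
print.dag_structure <- function(x, ...) {
  arcs <- which(x$amat == 1L, arr.ind = TRUE)
  cat("dag_structure:", x$p, "nodes,", nrow(arcs), "arcs\n")
  if (nrow(arcs))
    cat(paste0("  ", x$nodes[arcs[, 1]], " -> ", x$nodes[arcs[, 2]],
               collapse = "\n"), "\n")
  invisible(x)
}

#' @noRd
dag_arcs <- function(dag) {
  idx <- which(dag$amat == 1L, arr.ind = TRUE)
  data.frame(parent = dag$nodes[idx[, 1]], child = dag$nodes[idx[, 2]],
             row.names = NULL, stringsAsFactors = FALSE)
}

# Scatter-matrix cache for fast decomposable Gaussian scores: holds the
# centered cross-product matrix so local scores cost O(k^3), independent
# of n, and a per-(node, parent-set) memo.
#' @noRd
make_score_cache <- function(X) {
  X <- scale(X, center = TRUE, scale = TRUE)  # structure is scale-invariant
  n <- nrow(X)
  S <- crossprod(X)  # centered scatter; S/n = MLE covariance
  env <- new.env(parent = emptyenv())
  list(S = S, n = n, p = ncol(X), memo = env, nodes = colnames(X))
}

# Local score of `node` given integer parent set `parents`:
#   loglik - (|parents| + 2)/2 * log n,
# Gaussian log-likelihood at the MLE, sigma2 = RSS/n.
#' @noRd
local_score <- function(cache, node, parents) {
  key <- paste(node, paste(sort(parents), collapse = ","), sep = "|")
  hit <- cache$memo[[key]]
  if (!is.null(hit)) return(hit)
  S <- cache$S; n <- cache$n
  rss <- if (length(parents) == 0) S[node, node] else {
    Sxx <- S[parents, parents, drop = FALSE]
    sxy <- S[parents, node]
    beta <- tryCatch(solve(Sxx, sxy), error = function(e)
      stop("collinear parents for node ", cache$nodes[node]))
    S[node, node] - as.numeric(crossprod(sxy, beta))
  }
  rss <- max(rss, 1e-12)
  sigma2 <- rss / n
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  val <- ll - (length(parents) + 2) / 2 * log(n)
  cache$memo[[key]] <- val
  val
}

#' Decomposable Gaussian BIC score of a DAG (higher is better)
#'
#' Sum over nodes of the Gaussian log-likelihood of the node's least-squares
#' regression on its parents, minus `(|parents| + 2)/2 * log(n)` per node
#' (slope coefficients, intercept, residual variance). Data are z-scored per
#' column before scoring.
#'
#' @param dag a [dag_structure()].
#' @param data scores.
#' @return scalar score.
#' @export
bic_g_score <- function(dag, data) {
  X <- as_score_matrix(data)
  stopifnot(inherits(dag, "dag_structure"), ncol(X) == dag$p)
  cache <- make_score_cache(X)
  sum(vapply(seq_len(dag$p), function(v)
    local_score(cache, v, which(dag$amat[, v] == 1L)), numeric(1)))
}

# would adding arc u->v create a cycle? (path v ~> u in A)
#' @noRd
creates_cycle <- function(A, u, v) {
  if (u == v) return(TRUE)
  seen <- logical(nrow(A))
  frontier <- v
  while (length(frontier)) {
    nxt <- integer(0)
    for (w in frontier) {
      ch <- which(A[w, ] == 1L)
      ch <- ch[!seen[ch]]
      if (u %in% ch) return(TRUE)
      seen[ch] <- TRUE
      nxt <- c(nxt, ch)
    }
    frontier <- nxt
  }
  FALSE
}

# All legal single-arc moves from A: matrix (type, from, to);
# type 1 add, 2 delete, 3 reverse.
#' @noRd
legal_moves <- function(A) {
  p <- nrow(A)
  moves <- NULL
  for (u in seq_len(p)) for (v in seq_len(p)) {
    if (u == v) next
    if (A[u, v] == 1L) {
      moves <- rbind(moves, c(2L, u, v))
      if (!{A2 <- A; A2[u, v] <- 0L; creates_cycle(A2, v, u)})
        moves <- rbind(moves, c(3L, u, v))
    } else if (A[v, u] == 0L) {
      if (!creates_cycle(A, u, v)) moves <- rbind(moves, c(1L, u, v))
    }
  }
  moves
}

#' @noRd
apply_move <- function(A, mv) {
  u <- mv[2]; v <- mv[3]
  if (mv[1] == 1L) A[u, v] <- 1L
  else if (mv[1] == 2L) A[u, v] <- 0L
  else { A[u, v] <- 0L; A[v, u] <- 1L }
  A
}

# Greedy climb from A: accept the best strictly score-improving
# add/delete/reverse move until none exists. Returns list(A, score).
#' @noRd
climb_from <- function(A, cache, local) {
  p <- nrow(A)
  ls <- vapply(seq_len(p), function(v) local(v, which(A[, v] == 1L)),
               numeric(1))
  repeat {
    best_delta <- 1e-10  # strict improvement
    best <- NULL
    for (u in seq_len(p)) for (v in seq_len(p)) {
      if (u == v) next
      if (A[u, v] == 1L) {
        # delete u->v
        d <- local(v, setdiff(which(A[, v] == 1L), u)) - ls[v]
        if (d > best_delta) { best_delta <- d; best <- c(2L, u, v) }
        # reverse u->v
        A2 <- A; A2[u, v] <- 0L
        if (!creates_cycle(A2, v, u)) {
          d <- (local(v, setdiff(which(A[, v] == 1L), u)) - ls[v]) +
            (local(u, c(which(A[, u] == 1L), v)) - ls[u])
          if (d > best_delta) { best_delta <- d; best <- c(3L, u, v) }
        }
      } else if (A[v, u] == 0L && !creates_cycle(A, u, v)) {
        d <- local(v, c(which(A[, v] == 1L), u)) - ls[v]
        if (d > best_delta) { best_delta <- d; best <- c(1L, u, v) }
      }
    }
    if (is.null(best)) break
    A <- apply_move(A, best)
    v <- best[3]; u <- best[2]
    ls[v] <- local(v, which(A[, v] == 1L))
    if (best[1] == 3L) ls[u] <- local(u, which(A[, u] == 1L))
  }
  list(A = A, score = sum(ls))
}

#' Hill-climbing structure search with restarts and perturbations
#'
#' Greedy search over single-arc add/delete/reverse moves accepting the best
#' strictly score-improving move (Gaussian BIC, [bic_g_score()]) until a
#' local optimum is reached; then, per restart, the incumbent optimum is
#' perturbed by a number of random legal moves and re-climbed, keeping the
#' best-scoring DAG found overall. Deterministic given `seed`.
#'
#' @param data scores.
#' @param restarts random restarts (default 5).
#' @param perturbations random legal moves per restart (default 10).
#' @param seed integer seed.
#' @return a [dag_structure()] with attributes `score` and `climbs`.
#' @export
hill_climb <- function(data, restarts = 5, perturbations = 10, seed = 1) {
  X <- as_score_matrix(data)
  cache <- make_score_cache(X)
  local <- function(v, pa) local_score(cache, v, pa)
  p <- ncol(X)
  A0 <- matrix(0L, p, p)
  res <- climb_from(A0, cache, local)
  best <- res
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(restarts)) {
      A <- best$A
      for (k in seq_len(perturbations)) {
        mv <- legal_moves(A)
        if (is.null(mv) || nrow(mv) == 0) break
        A <- apply_move(A, mv[sample.int(nrow(mv), 1), ])
      }
      res <- climb_from(A, cache, local)
      if (res$score > best$score) best <- res
    }
  })
  dimnames(best$A) <- list(colnames(X), colnames(X))
  dag <- dag_structure(which(best$A == 1L, arr.ind = TRUE),
                       nodes = colnames(X))
  attr(dag, "score") <- best$score
  dag
}

#' Completed partially directed acyclic graph (CPDAG) of a DAG
#'
#' Keeps the skeleton, preserves v-structures (colliders with non-adjacent
#' parents) as directed, and orients further edges by Meek's rules to
#' closure; all remaining edges are undirected. Two DAGs share a CPDAG iff
#' they share skeleton and v-structures (Markov equivalence).
#'
#' @param dag a [dag_structure()].
#' @return an object of class `cpdag`: list with `amat` (entry `[i,j] = 1`
#'   and `[j,i] = 0` for a directed edge i→j; both 1 for an undirected edge)
#'   and `nodes`.
#' @export
cpdag <- function(dag) {
  stopifnot(inherits(dag, "dag_structure"))
  A <- dag$amat
  p <- dag$p
  skel <- (A + t(A)) > 0
  # start fully undirected, then orient v-structures
  C <- matrix(0L, p, p, dimnames = dimnames(A))
  C[skel] <- 1L
  for (k in seq_len(p)) {
    pa <- which(A[, k] == 1L)
    if (length(pa) < 2) next
    for (a in seq_len(length(pa) - 1)) for (b in (a + 1):length(pa)) {
      i <- pa[a]; j <- pa[b]
      if (!skel[i, j]) {  # collider i -> k <- j with non-adjacent parents
        C[k, i] <- 0L
        C[k, j] <- 0L
      }
    }
  }
  C <- meek_closure(C)
  structure(list(amat = C, nodes = dag$nodes), class = "cpdag")
}

# Meek's orientation rules R1-R3 applied to a fixpoint. For patterns of DAGs
# (all v-structures already oriented) these rules are complete; R4 only
# arises under external background knowledge, which this package never adds.
#' @noRd
meek_closure <- function(C) {
  p <- nrow(C)
  directed <- function(i, j) C[i, j] == 1L && C[j, i] == 0L
  undirected <- function(i, j) C[i, j] == 1L && C[j, i] == 1L
  adjacent <- function(i, j) C[i, j] == 1L || C[j, i] == 1L
  repeat {
    changed <- FALSE
    for (b in seq_len(p)) for (c in seq_len(p)) {
      if (b == c || !undirected(b, c)) next
      # R1: a -> b, b - c, a and c non-adjacent  =>  b -> c
      for (a in seq_len(p)) {
        if (a == b || a == c) next
        if (directed(a, b) && !adjacent(a, c)) {
          C[c, b] <- 0L; changed <- TRUE; break
        }
      }
      if (!undirected(b, c)) next
      # R2: b -> a -> c and b - c  =>  b -> c
      for (a in seq_len(p)) {
        if (a == b || a == c) next
        if (directed(b, a) && directed(a, c)) {
          C[c, b] <- 0L; changed <- TRUE; break
        }
      }
      if (!undirected(b, c)) next
      # R3: b - a1, b - a2, a1 -> c, a2 -> c, a1/a2 non-adjacent  =>  b -> c
      ins <- which(vapply(seq_len(p), function(a)
        a != b && a != c && undirected(b, a) && directed(a, c), logical(1)))
      if (length(ins) >= 2) {
        done <- FALSE
        for (x in seq_len(length(ins) - 1)) {
          for (y in (x + 1):length(ins)) {
            if (!adjacent(ins[x], ins[y])) {
              C[c, b] <- 0L; changed <- TRUE; done <- TRUE; break
            }
          }
          if (done) break
        }
      }
    }
    if (!changed) break
  }
  C
}

#' @export
print.cpdag <- function(x, ...) {
  A <- x$amat
  dir <- which(A == 1L & t(A) == 0L, arr.ind = TRUE)
  und <- which(A == 1L & t(A) == 1L, arr.ind = TRUE)
  und <- und[und[, 1] < und[, 2], , drop = FALSE]
  cat("cpdag:", length(x$nodes), "nodes,", nrow(dir), "directed,",
      nrow(und), "undirected edges\n")
  invisible(x)
}

#' Bootstrap arc-presence and direction frequencies
#'
#' Learns a DAG by [hill_climb()] on `B` row-resamples (with replacement),
#' converts each to its CPDAG, and accumulates per unordered pair the
#' fraction of bootstrap networks containing the edge in any orientation
#' (presence), and per ordered pair the fraction of edge-containing networks
#' orienting it that way (direction); undirected CPDAG edges contribute 0.5
#' to each direction.
#'
#' @param data scores.
#' @param B bootstrap replicates (default 1000).
#' @param restarts,perturbations passed to [hill_climb()].
#' @param seed integer seed.
#' @return an object of class `arc_strength_table`: data frame with columns
#'   `from, to, presence, direction` for every ordered pair (plus `B` and
#'   `nodes` attributes). `direction(i,j) + direction(j,i) = 1` whenever
#'   `presence > 0`.
#' @export
bootstrap_arcs <- function(data, B = 1000, restarts = 5, perturbations = 10,
                           seed = 1) {
  X <- as_score_matrix(data)
  p <- ncol(X)
  nodes <- colnames(X)
  present <- matrix(0, p, p, dimnames = list(nodes, nodes))  # unordered count
  dircnt <- matrix(0, p, p, dimnames = list(nodes, nodes))   # ordered count
  seeds <- vapply(seq_len(B), function(b) substream_seed(seed, b), integer(1))
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(B)) {
      idx <- resample_rows(X, nrow(X), replace = TRUE)
      dag <- hill_climb(X[idx, , drop = FALSE], restarts, perturbations,
                        seed = seeds[b])
      C <- cpdag(dag)$amat
      edge <- (C + t(C)) > 0
      present <- present + edge
      dircnt <- dircnt + (C == 1L & t(C) == 0L) + 0.5 * (C == 1L & t(C) == 1L)
    }
  })
  idx <- which(upper.tri(present), arr.ind = TRUE)
  tab <- data.frame(
    from = c(nodes[idx[, 1]], nodes[idx[, 2]]),
    to = c(nodes[idx[, 2]], nodes[idx[, 1]]),
    presence = c(present[idx] / B, present[t(apply(idx, 1, rev))] / B),
    direction = NA_real_, row.names = NULL, stringsAsFactors = FALSE)
  pres_pair <- c(present[idx], present[idx])  # symmetric counts
  dirs <- c(dircnt[idx], dircnt[cbind(idx[, 2], idx[, 1])])
  tab$direction <- ifelse(pres_pair > 0, dirs / pres_pair, NA_real_)
  structure(tab, class = c("arc_strength_table", "data.frame"),
            B = B, nodes = nodes)
}

#' Threshold bootstrap arc strengths into a consensus network
#'
#' Keeps unordered pairs whose presence frequency is at least
#' `edge_threshold` and orients each kept pair `i -> j` iff its direction
#' frequency strictly exceeds `direction_threshold`; pairs at exactly
#' 0.5/0.5 are retained undirected and flagged. The full listing of pairs
#' with presence of at least 0.5 is also returned for sensitivity reporting.
#'
#' @param table an [bootstrap_arcs()] result.
#' @param edge_threshold presence threshold (default 0.85).
#' @param direction_threshold direction threshold (default 0.5).
#' @return an object of class `consensus_dag`: list with `arcs` (data frame
#'   `from, to, presence, direction, directed`), `listing_50` (all pairs with
#'   presence >= 0.5), and the thresholds.
#' @export
consensus_network <- function(table, edge_threshold = 0.85,
                              direction_threshold = 0.5) {
  stopifnot(inherits(table, "arc_strength_table"))
  tab <- as.data.frame(table)
  # one row per unordered pair, carrying the dominant direction
  key <- ifelse(tab$from < tab$to, paste(tab$from, tab$to),
                paste(tab$to, tab$from))
  arcs <- NULL
  for (k in unique(key)) {
    rows <- tab[key == k, , drop = FALSE]
    pres <- rows$presence[1]
    if (is.na(pres) || pres < edge_threshold) next
    lead <- rows[which.max(rows$direction), , drop = FALSE]
    directed <- lead$direction > direction_threshold
    arcs <- rbind(arcs, data.frame(
      from = lead$from, to = lead$to, presence = pres,
      direction = lead$direction, directed = directed,
      stringsAsFactors = FALSE))
  }
  listing <- tab[!is.na(tab$presence) & tab$presence >= 0.5 &
                   tab$direction >= 0.5, , drop = FALSE]
  listing <- listing[order(-listing$presence), ]
  rownames(listing) <- NULL
  structure(list(arcs = arcs %||% data.frame(), listing_50 = listing,
                 edge_threshold = edge_threshold,
                 direction_threshold = direction_threshold,
                 nodes = attr(table, "nodes")),
            class = "consensus_dag")
}

#' @export
print.consensus_dag <- function(x, ...) {
  cat("consensus_dag (presence >= ", x$edge_threshold, ", direction > ",
      x$direction_threshold, "): ", NROW(x$arcs), " edges\n", sep = "")
  if (NROW(x$arcs)) {
    sym <- ifelse(x$arcs$directed, "->", "--")
    cat(paste0("  ", x$arcs$from, " ", sym, " ", x$arcs$to,
               sprintf("  [presence %.2f, direction %.2f]",
                       x$arcs$presence, x$arcs$direction), collapse = "\n"),
        "\n")
  }
  invisible(x)
}

#' Export a consensus network
#'
#' Writes the retained arcs as a CSV edge list with presence/direction
#' columns, optionally a Graphviz DOT file, and a JSON metadata sidecar
#' recording the thresholds.
#'
#' @param consensus a [consensus_network()] result.
#' @param csv_path edge-list CSV path.
#' @param dot_path optional DOT output path.
#' @return `csv_path`, invisibly.
#' @export
export_consensus <- function(consensus, csv_path, dot_path = NULL) {
  stopifnot(inherits(consensus, "consensus_dag"))
  write.csv(consensus$arcs, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(edge_threshold = consensus$edge_threshold,
         direction_threshold = consensus$direction_threshold),
    paste0(csv_path, ".json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(dot_path)) {
    lines <- c("digraph consensus {")
    if (NROW(consensus$arcs)) {
      a <- consensus$arcs
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [label=\"%.2f\"%s];", a$from, a$to, a$presence,
        ifelse(a$directed, "", ", dir=none")))
    }
    lines <- c(lines, "}")
    writeLines(lines, dot_path)
  }
  invisible(csv_path)
}
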