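test_that("the Gaussian BIC score is decomposable and well-behaved", {
  X <- withr::with_seed(1, matrix(rnorm(5000 * 3), 5000, 3))
  colnames(X) <- c("A", "B", "C")
  empty <- dag_structure(NULL, colnames(X))
  got <- bic_g_score(empty, X)
  # closed form: sum of univariate Gaussian BICs of the z-scored columns
  Z <- scale(X)
  want <- sum(vapply(1:3, function(j) {
    s2 <- sum(Z[, j]^2) / 5000
    -5000 / 2 * (log(2 * pi * s2) + 1) - (2 / 2) * log(5000)
  }, numeric(1)))
  expect_equal(got, want, tolerance = 1e-9)

  # arc-list order cannot matter (decomposability)
  arcs <- rbind(c(1, 3), c(2, 3))
  d1 <- dag_structure(arcs, colnames(X))
  d2 <- dag_structure(arcs[2:1, ], colnames(X))
  expect_identical(bic_g_score(d1, X), bic_g_score(d2, X))

  # a true strong parent increases the score
  spec <- dag_spec(2, data.frame(parent = 1, child = 2, coef = 1))
  for (s in 1:5) {
    d <- sample_linear_dag(2000, spec, seed = 200 + s)
    s0 <- bic_g_score(dag_structure(NULL, d$node_names), d)
    s1 <- bic_g_score(dag_structure(rbind(c(1, 2)), d$node_names), d)
    expect_gt(s1, s0)
  }

  # collinear parents are reported by node
  Y <- cbind(X[, 1], X[, 1], X[, 1] + X[, 2])
  colnames(Y) <- c("A", "B", "C")
  bad <- dag_structure(rbind(c(1, 3), c(2, 3)), colnames(Y))
  expect_error(bic_g_score(bad, Y), "collinear")
})

test_that("hill climbing returns acyclic DAGs no worse than the empty model", {
  for (s in 1:4) {
    spec <- dag_spec(4, data.frame(parent = c(1, 2), child = c(3, 4),
                                   coef = c(0.7, -0.6)))
    d <- sample_linear_dag(400, spec, seed = 300 + s)
    dag <- hill_climb(d, seed = s)
    expect_s3_class(dag, "dag_structure")  # constructor enforces acyclicity
    expect_gte(attr(dag, "score"),
               bic_g_score(dag_structure(NULL, d$node_names), d))
  }
})

test_that("independent data yield the empty DAG", {
  for (s in 1:3) {
    X <- withr::with_seed(400 + s, matrix(rnorm(2000 * 4), 2000, 4))
    colnames(X) <- paste0("V", 1:4)
    dag <- hill_climb(X, seed = s)
    expect_identical(sum(dag$amat), 0L)
  }
})

test_that("CPDAGs encode Markov equivalence classes", {
  nodes <- c("A", "B", "C")
  chain <- dag_structure(rbind(c(1, 2), c(2, 3)), nodes)
  cp <- cpdag(chain)$amat
  expect_true(all(cp == t(cp)))  # fully undirected
  expect_identical(sum(cp), 4L)

  collider <- dag_structure(rbind(c(1, 3), c(2, 3)), nodes)
  cc <- cpdag(collider)$amat
  expect_identical(cc[1, 3], 1L); expect_identical(cc[3, 1], 0L)
  expect_identical(cc[2, 3], 1L); expect_identical(cc[3, 2], 0L)

  # applying the orientation closure twice changes nothing
  expect_identical(psynet:::meek_closure(cc), cc)
  expect_identical(psynet:::meek_closure(cp), cp)

  # same CPDAG iff same skeleton and same v-structures, over all 25 DAGs
  dags <- oracle_all_dags3()
  expect_length(dags, 25)
  cps <- lapply(dags, function(d) cpdag(d)$amat)
  for (i in 1:24) for (j in (i + 1):25) {
    same_cp <- identical(cps[[i]], cps[[j]])
    same_class <- identical(dag_skeleton(dags[[i]]),
                            dag_skeleton(dags[[j]])) &&
      identical(dag_vstructures(dags[[i]]), dag_vstructures(dags[[j]]))
    expect_identical(same_cp, same_class)
  }
})

test_that("bootstrap arc strengths satisfy the direction invariant", {
  spec <- dag_spec(3, data.frame(parent = c(1, 2), child = c(3, 3),
                                 coef = c(1, 1)))
  d <- sample_linear_dag(800, spec, seed = 5)
  tab <- bootstrap_arcs(d, B = 30, seed = 6)
  t2 <- bootstrap_arcs(d, B = 30, seed = 6)
  expect_identical(as.data.frame(tab), as.data.frame(t2))
  for (r in seq_len(nrow(tab))) {
    if (is.na(tab$direction[r])) next
    rev <- tab$direction[tab$from == tab$to[r] & tab$to == tab$from[r]]
    expect_equal(tab$direction[r] + rev, 1)
  }
  expect_true(all(tab$presence >= 0 & tab$presence <= 1))
  # the strong collider edges are nearly always present
  expect_gte(tab$presence[tab$from == "V1" & tab$to == "V3"], 0.85)
})

test_that("consensus thresholding keeps and orients edges as specified", {
  fake <- structure(data.frame(
    from = c("A", "B", "A", "C"), to = c("B", "A", "C", "A"),
    presence = c(0.90, 0.90, 0.84, 0.84),
    direction = c(0.60, 0.40, 0.70, 0.30)),
    class = c("arc_strength_table", "data.frame"), B = 100,
    nodes = c("A", "B", "C"))
  cn <- consensus_network(fake)
  expect_identical(nrow(cn$arcs), 1L)
  expect_identical(cn$arcs$from, "A")
  expect_identical(cn$arcs$to, "B")
  expect_true(cn$arcs$directed)
  # lowering the edge threshold admits the weaker pair (sensitivity mode)
  cn2 <- consensus_network(fake, edge_threshold = 0.75)
  expect_identical(nrow(cn2$arcs), 2L)
  # raising the threshold never adds arcs
  cn3 <- consensus_network(fake, edge_threshold = 0.95)
  expect_lte(nrow(cn3$arcs), nrow(cn$arcs))
  # an exactly 0.5/0.5 pair is retained undirected
  fake$direction <- c(0.5, 0.5, 0.7, 0.3)
  cn4 <- consensus_network(fake)
  expect_false(cn4$arcs$directed)
})
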