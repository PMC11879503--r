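make_net <- function(W, communities = NULL) {
  p <- ncol(W)
  dimnames(W) <- rep(list(paste0("n", seq_len(p))), 2)
  if (!is.null(communities)) names(communities) <- colnames(W)
  weighted_network(W, communities = communities)
}

test_that("strength and expected influence follow their definitions", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.3
  W[1, 3] <- W[3, 1] <- -0.2
  nc <- node_centralities(make_net(W))
  expect_equal(nc$strength[1], 0.5)
  expect_equal(nc$expected_influence[1], 0.1)
  # handshake identity
  expect_equal(sum(nc$strength), 2 * sum(abs(W[upper.tri(W)])))
  expect_true(all(nc$strength >= abs(nc$expected_influence)))
})

test_that("closeness and betweenness on a chain match hand enumeration", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5   # d = 2
  W[2, 3] <- W[3, 2] <- 0.25  # d = 4
  nc <- node_centralities(make_net(W))
  expect_equal(nc$closeness[2], 1 / 6)
  expect_equal(nc$closeness[1], 1 / 8)  # d(1,2)=2, d(1,3)=6
  expect_equal(nc$betweenness, c(0, 1, 0))
})

test_that("disconnected networks report reachable-node counts", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.5
  nc <- node_centralities(make_net(W))
  expect_identical(nc$reachable, c(1L, 1L, 0L, 0L))
  expect_equal(nc$closeness[3], 0)
})

test_that("rescaling weights transforms centralities predictably", {
  W <- random_weight_matrix(6, 8, seed = 5)
  n1 <- node_centralities(make_net(W))
  n2 <- node_centralities(make_net(0.5 * W))
  expect_equal(n2$strength, 0.5 * n1$strength)
  expect_equal(n2$expected_influence, 0.5 * n1$expected_influence)
  expect_equal(n2$closeness, 0.5 * n1$closeness)
  expect_equal(n2$betweenness, n1$betweenness)
})

test_that("all centralities match the exhaustive path oracle", {
  for (seed in 1:8) {
    p <- 6 + (seed %% 3)
    W <- random_weight_matrix(p, p + 3, seed = 100 + seed)
    comm <- rep(c("X", "Y"), length.out = p)
    net <- make_net(W, comm)
    got <- node_centralities(net)
    bri <- bridge_centralities(net)
    want <- oracle_centralities(W, comm)
    expect_equal(got$strength, want$strength)
    expect_equal(got$expected_influence, want$expected_influence)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-10)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-10)
    expect_equal(bri$bridge_strength, want$bridge_strength)
    expect_equal(bri$bridge_expected_influence_1step,
                 want$bridge_expected_influence_1step)
    expect_equal(bri$bridge_closeness, want$bridge_closeness,
                 tolerance = 1e-10)
    expect_equal(bri$bridge_betweenness, want$bridge_betweenness)
  }
})

test_that("bridge indices reduce to totals and zeros in edge cases", {
  # lone cross-community edge
  W <- matrix(0, 4, 4)
  W[1, 3] <- W[3, 1] <- 0.11
  net <- make_net(W, c("A", "A", "B", "B"))
  bc <- bridge_centralities(net)
  expect_equal(bc$bridge_strength[1], 0.11)
  expect_equal(bc$bridge_expected_influence_1step[1], 0.11)

  # all edges within communities
  W2 <- matrix(0, 4, 4)
  W2[1, 2] <- W2[2, 1] <- 0.4
  W2[3, 4] <- W2[4, 3] <- 0.3
  bc2 <- bridge_centralities(make_net(W2, c("A", "A", "B", "B")))
  expect_equal(bc2$bridge_strength, rep(0, 4))

  # singleton community: its bridge strength equals its total strength
  W3 <- random_weight_matrix(5, 6, seed = 3)
  net3 <- make_net(W3, c("A", "A", "A", "A", "B"))
  nc3 <- node_centralities(net3)
  bc3 <- bridge_centralities(net3)
  expect_equal(bc3$bridge_strength[5], nc3$strength[5])

  expect_error(bridge_centralities(make_net(W3, rep("A", 5))),
               "single community")
})

test_that("predictability matches the precision-matrix closed form", {
  # independent columns: near-zero R^2
  X <- withr::with_seed(4, matrix(rnorm(5000 * 4), 5000, 4))
  expect_true(all(predictability(X)$predictability < 0.02))

  # exact linear dependence: R^2 = 1
  Y <- withr::with_seed(5, matrix(rnorm(600), 200, 3))
  Y <- cbind(Y[, 1:2], y = Y[, 1] + Y[, 2] + 0 * Y[, 3])
  expect_equal(predictability(Y)$predictability[3], 1, tolerance = 1e-12)

  # 3-node system with known precision: R^2_i = 1 - 1/(k_ii * sigma_ii)
  K <- build_precision(precision_spec(3, data.frame(i = c(1, 2), j = c(2, 3),
                                                    rho = c(0.4, -0.3))))
  Sigma <- solve(K)
  ds <- sample_copula(10000, K, seed = 41)
  r2 <- predictability(ds)$predictability
  expect_lt(max(abs(r2 - (1 - 1 / (diag(K) * diag(Sigma))))), 0.02)
})

test_that("bridge-node selection uses a strict percentile cutoff", {
  tab <- data.frame(node = paste0("n", 1:8),
                    bridge_strength = c(1, 2, 3, 4, 5, 6, 7, 8))
  sel <- select_bridge_nodes(tab, 80)
  # at most 2 of 8 nodes can lie strictly above the 80th percentile
  expect_lte(length(sel$bridge_strength), 2)
  expect_identical(sel$bridge_strength, c("n7", "n8"))  # q80 = 6.6

  tab$bridge_strength <- rep(0.5, 8)
  expect_identical(select_bridge_nodes(tab, 80)$bridge_strength, character(0))

  tab$bridge_strength <- c(rep(0.1, 7), 3)
  expect_identical(select_bridge_nodes(tab, 80)$bridge_strength, "n8")
})
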