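test_that("build_precision realizes requested partial correlations", {
  # p = 2: partial equals marginal correlation; invert by hand
  K <- build_precision(precision_spec(2, data.frame(i = 1, j = 2, rho = 0.5)))
  expect_equal(K / K[1, 1], matrix(c(1, -0.5, -0.5, 1), 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  Sigma <- solve(K)
  expect_equal(stats::cov2cor(Sigma)[1, 2], 0.5, tolerance = 1e-12)

  # empty edge set -> identity, zero partials
  K0 <- build_precision(precision_spec(3))
  expect_equal(K0, diag(3), ignore_attr = TRUE)
  expect_equal(partial_corr_from_precision(K0), matrix(0, 3, 3))

  # round trip at p = 8 with 10 random edges in (-0.3, 0.3)
  pairs <- t(combn(8, 2))
  ed <- withr::with_seed(1, {
    sel <- pairs[sample.int(nrow(pairs), 10), ]
    data.frame(i = sel[, 1], j = sel[, 2], rho = runif(10, -0.3, 0.3))
  })
  K8 <- build_precision(precision_spec(8, ed))
  expect_identical(attr(K8, "inflation_steps"), 0L)
  P <- partial_corr_from_precision(K8)
  expect_equal(P[cbind(ed$i, ed$j)], ed$rho, tolerance = 1e-10)
})

test_that("jointly extreme partials trigger diagonal inflation and shrink", {
  # a 3-clique of partials at |0.95| admits no unit-diagonal SPD precision
  # matrix; geometric diagonal inflation restores definiteness at the cost
  # of shrinking the achieved partials, which must be recorded
  ed <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3), rho = c(0.95, 0.95, 0.95))
  K <- build_precision(precision_spec(3, ed))
  expect_gt(attr(K, "inflation_steps"), 0)
  expect_gt(min(eigen(K, symmetric = TRUE)$values), 0)
  ach <- attr(K, "achieved_partials")
  expect_true(all(abs(ach$rho) < abs(ed$rho)))
  P <- partial_corr_from_precision(K)
  expect_equal(P[cbind(ach$i, ach$j)], ach$rho, tolerance = 1e-12)
})

test_that("partial_corr_from_precision matches the regression oracle", {
  expect_equal(
    partial_corr_from_precision(matrix(c(2, -1, -1, 2), 2))[1, 2], 0.5)
  expect_equal(partial_corr_from_precision(diag(5)), matrix(0, 5, 5))
  expect_error(partial_corr_from_precision(diag(c(1, -1))), "positive definite")

  # brute force: partial correlation of (i, j) given rest as the correlation
  # of regression residuals under the implied covariance
  K <- withr::with_seed(7, {
    A <- matrix(rnorm(16), 4)
    crossprod(A) + diag(4)
  })
  P <- partial_corr_from_precision(K)
  Sigma <- solve(K)
  for (i in 1:3) for (j in (i + 1):4) {
    rest <- setdiff(1:4, c(i, j))
    # residual covariance of (i,j) after projecting out `rest`
    S11 <- Sigma[c(i, j), c(i, j)]
    S12 <- Sigma[c(i, j), rest]
    S22 <- Sigma[rest, rest]
    Sc <- S11 - S12 %*% solve(S22) %*% t(S12)
    expect_equal(P[i, j], stats::cov2cor(Sc)[1, 2], tolerance = 1e-12)
  }
})

test_that("copula sampler matches target marginals and respects bounds", {
  t1 <- table1_marginals()
  spq_cp <- t1$marginals[[1]]
  ds <- sample_copula(5000, diag(8), marginals = t1$marginals, seed = 11)
  x <- ds$scores[, "SPQ-CP"]
  expect_true(all(x >= spq_cp$min_score & x <= spq_cp$max_score))
  expect_true(all(ds$scores == round(ds$scores)))
  expect_equal(mean(x), 2.83, tolerance = 0.1)
  # hard bound assertion for every column
  for (j in seq_len(8)) {
    m <- t1$marginals[[j]]
    expect_true(all(ds$scores[, j] >= m$min_score &
                      ds$scores[, j] <= m$max_score))
  }
})

test_that("copula latent dependence survives the rank transform", {
  K <- build_precision(precision_spec(2, data.frame(i = 1, j = 2, rho = 0.5)))
  ds <- sample_copula(2000, K, seed = 21)
  rs <- cor(ds$scores, method = "spearman")[1, 2]
  expect_equal(rs, 6 / pi * asin(0.5 / 2), tolerance = 0.05)
})

test_that("copula draws are reproducible and guard rails fire", {
  a <- sample_copula(50, diag(3), seed = 5)
  b <- sample_copula(50, diag(3), seed = 5)
  expect_identical(a$scores, b$scores)
  expect_warning(sample_copula(20, diag(3), seed = 5), "unstable")
  expect_error(marginal_spec("bad", 0, 8, 12, 1), "infeasible")
})

test_that("monotone latent-to-score transform preserves Spearman sign", {
  t1 <- table1_marginals()
  ed <- data.frame(i = c(1, 4), j = c(6, 6), rho = c(0.3, -0.25))
  K <- build_precision(precision_spec(8, ed))
  lat <- sample_copula(10000, K, seed = 31)
  obs <- sample_copula(10000, K, marginals = t1$marginals, seed = 31)
  rl <- cor(lat$scores, method = "spearman")
  ro <- cor(obs$scores, method = "spearman")
  expect_lt(abs(ro[1, 6] - rl[1, 6]), 0.03)
  expect_lt(abs(ro[4, 6] - rl[4, 6]), 0.03)
  expect_gt(ro[1, 6], 0)
  expect_lt(ro[4, 6], 0)
})

test_that("linear DAG sampler matches closed-form moments", {
  # no arcs: independence
  d0 <- sample_linear_dag(10000, dag_spec(3), seed = 1)
  C0 <- cor(d0$scores)
  expect_lt(max(abs(C0[upper.tri(C0)])), 0.03)

  # X -> Y, unit coefficient: cor = 1/sqrt(2)
  s1 <- dag_spec(2, data.frame(parent = 1, child = 2, coef = 1))
  d1 <- sample_linear_dag(10000, s1, seed = 2)
  expect_equal(cor(d1$scores)[1, 2], 1 / sqrt(2), tolerance = 0.02)

  # collider X -> Z <- Y: marginal cor(X,Y) ~ 0, partial given Z = -0.5
  s2 <- dag_spec(3, data.frame(parent = c(1, 2), child = c(3, 3),
                               coef = c(1, 1)))
  d2 <- sample_linear_dag(10000, s2, seed = 3)
  expect_equal(cor(d2$scores)[1, 2], 0, tolerance = 0.03)
  Pc <- partial_corr_from_precision(solve(cov(d2$scores)))
  expect_equal(Pc[1, 2], -0.5, tolerance = 0.03)

  # covariance equals (I - B)^-T D (I - B)^-1 within Monte-Carlo error
  s3 <- dag_spec(4, data.frame(parent = c(1, 1, 2), child = c(2, 3, 4),
                               coef = c(0.8, -0.5, 0.6)),
                 noise_sd = c(1, 0.7, 1, 1.2))
  d3 <- sample_linear_dag(10000, s3, seed = 4)
  expect_equal(cov(d3$scores), dag_covariance(s3), tolerance = 0.08,
               ignore_attr = TRUE)
})

test_that("cyclic arc specifications are rejected with a named cycle", {
  arcs <- data.frame(parent = c(1, 2, 3), child = c(2, 3, 1), coef = 1)
  expect_error(dag_spec(3, arcs), "cyclic")
})

test_that("descriptive fixture reproduces the study marginals", {
  t1 <- table1_marginals()
  m <- setNames(t1$marginals, vapply(t1$marginals, `[[`, "", "name"))
  expect_equal(m[["SPQ-I"]][c("min_score", "max_score", "mean", "sd")],
               list(min_score = 0L, max_score = 8L, mean = 2.39, sd = 2.06))
  expect_equal(m[["ERQ-R"]][c("min_score", "max_score", "mean", "sd")],
               list(min_score = 6L, max_score = 30L, mean = 18.33, sd = 6.72))
  expect_equal(m[["DASS-D"]][c("min_score", "max_score", "mean", "sd")],
               list(min_score = 0L, max_score = 21L, mean = 2.93, sd = 3.89))
  expect_identical(unname(t1$communities),
                   rep(c("SPQ", "ERQ", "DASS"), c(3, 2, 3)))
})

test_that("grouped sampler injects differences only where requested", {
  base <- precision_spec(4, data.frame(i = 1, j = 2, rho = 0.2))
  ds <- grouped_dataset(c(A = 120, B = 80), base,
                        delta_edges = list(B = data.frame(i = 3, j = 4,
                                                          rho = 0.35)),
                        seed = 9)
  expect_equal(nrow(ds$scores), 200)
  expect_identical(table(ds$groups$group), table(rep(c("A", "B"), c(120, 80))))
  pa <- ds$truth$groups$A$partial_correlations
  pb <- ds$truth$groups$B$partial_correlations
  expect_equal(pa[1, 2], pb[1, 2], tolerance = 1e-12)
  expect_equal(pa[3, 4], 0)
  expect_equal(pb[3, 4], 0.35, tolerance = 1e-12)

  # relabeling groups does not alter the data each group received
  ds2 <- grouped_dataset(c(A = 120, B = 80), base,
                         delta_edges = list(B = data.frame(i = 3, j = 4,
                                                           rho = 0.35)),
                         seed = 9, group_column = "sex")
  expect_identical(ds$scores, ds2$scores)
})

test_that("CSV round trip preserves scores, groups and communities", {
  t1 <- table1_marginals()
  ds <- sample_copula(100, diag(8), marginals = t1$marginals, seed = 2,
                      communities = t1$communities)
  ds$groups <- data.frame(gender = rep(c("boy", "girl"), 50))
  path <- file.path(withr::local_tempdir(), "scores.csv")
  write_questionnaire_csv(ds, path)
  back <- read_questionnaire_csv(path)
  expect_equal(back$scores, ds$scores, ignore_attr = TRUE)
  expect_identical(back$groups$gender, ds$groups$gender)
  expect_identical(back$communities, ds$communities)
})
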