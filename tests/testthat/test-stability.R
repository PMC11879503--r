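# small shared fixture: 8-node network with 5 genuine edges
stability_data <- function(n = 500, seed = 71) {
  K <- build_precision(base_truth_spec())
  sample_copula(n, K, seed = seed,
                communities = setNames(rep(c("SPQ", "ERQ", "DASS"),
                                           c(3, 2, 3)),
                                       paste0("V", 1:8)),
                node_names = paste0("V", 1:8))
}

test_that("edge bootstrap is reproducible and its CIs are ordered", {
  ds <- stability_data(300)
  b1 <- bootstrap_edges(ds, B = 25, seed = 5)
  b2 <- bootstrap_edges(ds, B = 25, seed = 5)
  expect_identical(b1$edge_samples, b2$edge_samples)
  expect_identical(b1$ci, b2$ci)
  expect_true(all(b1$ci$ci_low <= b1$ci$ci_high))
  expect_identical(dim(b1$edge_samples), c(25L, 28L))
})

test_that("a strong true edge keeps a CI excluding zero", {
  K <- build_precision(precision_spec(4, data.frame(i = 1, j = 2, rho = 0.3)))
  ds <- sample_copula(1000, K, seed = 8)
  boot <- bootstrap_edges(ds, B = 200, seed = 88)
  row <- boot$ci[boot$ci$edge == "V1--V2", ]
  expect_gt(row$ci_low, 0)
  # a structurally absent edge keeps a CI containing zero
  row0 <- boot$ci[boot$ci$edge == "V3--V4", ]
  expect_true(row0$ci_low <= 0 && row0$ci_high >= 0)
})

test_that("difference tests are symmetric and reflexively non-significant", {
  ds <- stability_data(400)
  boot <- bootstrap_edges(ds, B = 40, seed = 3)
  for (kind in c("edge", "strength", "EI", "bridge_EI")) {
    dt <- difference_test(boot, kind)
    expect_identical(dt$significant, t(dt$significant))
    expect_false(any(diag(dt$significant)))
  }
})

test_that("clearly different edges are flagged by the difference test", {
  K <- build_precision(precision_spec(4, data.frame(i = c(1, 3), j = c(2, 4),
                                                    rho = c(0.05, 0.35))))
  ds <- sample_copula(1000, K, seed = 12)
  boot <- bootstrap_edges(ds, B = 150, seed = 13)
  dt <- difference_test(boot, "edge")
  expect_true(dt$significant["V1--V2", "V3--V4"])
})

test_that("case-dropping correlations decay and CS follows its definition", {
  ds <- stability_data(600)
  cd <- casedrop_bootstrap(ds, proportions = c(0.1, 0.3, 0.5, 0.7), B = 30,
                           seed = 21)
  cd2 <- casedrop_bootstrap(ds, proportions = c(0.1, 0.3, 0.5, 0.7), B = 30,
                            seed = 21)
  expect_identical(cd$correlations, cd2$correlations)
  med <- apply(cd$correlations$strength, 2, median)
  expect_gt(med[1], med[4])  # heavier dropping degrades agreement
  cs <- cs_coefficient(cd)
  expect_true(all(cs >= 0 & cs <= 0.7))
})

test_that("the CS coefficient picks the largest qualifying grid point", {
  grid <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  fake <- function(frac_ok) {
    # 100 replicates per proportion; frac_ok of them at correlation 1, rest 0
    M <- sapply(frac_ok, function(f) c(rep(1, round(100 * f)),
                                       rep(0, 100 - round(100 * f))))
    structure(list(drop_proportions = grid,
                   correlations = list(strength = M)),
              class = "casedrop_result")
  }
  # degenerate stability: all correlations 1 -> grid maximum
  expect_equal(cs_coefficient(fake(c(1, 1, 1, 1, 1)))[["strength"]], 0.5)
  # no stability at all
  expect_equal(cs_coefficient(fake(c(0, 0, 0, 0, 0)))[["strength"]], 0)
  # 96% at q = 0.3, 94% at q = 0.4 -> CS = 0.3
  expect_equal(cs_coefficient(fake(c(1, 1, 0.96, 0.94, 0.2)))[["strength"]],
               0.3)
  # monotone in threshold and confidence
  res <- fake(c(1, 0.97, 0.96, 0.94, 0.2))
  expect_gte(cs_coefficient(res, threshold = 0.5)[["strength"]],
             cs_coefficient(res, threshold = 0.9)[["strength"]])
  expect_gte(cs_coefficient(res, confidence = 0.9)[["strength"]],
             cs_coefficient(res, confidence = 0.99)[["strength"]])
})

test_that("edge CI width shrinks with sample size", {
  # width measured on the genuine edges; absent edges are shrunk to exact
  # zero in most resamples and carry no width signal
  spec <- base_truth_spec()
  K <- build_precision(spec)
  truth <- pair_idx <- cbind(spec$edges$i, spec$edges$j)
  width <- function(n, seed) {
    ds <- sample_copula(n, K, seed = seed)
    boot <- bootstrap_edges(ds, B = 60, seed = seed + 1)
    nodes <- paste0("V", 1:8)
    sel <- paste(nodes[truth[, 1]], nodes[truth[, 2]], sep = "--")
    rows <- boot$ci[boot$ci$edge %in% sel, ]
    median(rows$ci_high - rows$ci_low)
  }
  w250 <- median(vapply(1:5, function(s) width(250, 500 + s), numeric(1)))
  w2000 <- median(vapply(1:5, function(s) width(2000, 600 + s), numeric(1)))
  expect_lt(w2000, w250)
})

test_that("case-dropping guards against too-small subsamples", {
  ds <- stability_data(100)
  expect_error(casedrop_bootstrap(ds, proportions = c(0.5, 0.8), B = 5,
                                  seed = 1), "3p")
  expect_error(casedrop_bootstrap(ds, proportions = c(0.3, 0.2), B = 5,
                                  seed = 1), "increasing")
})
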