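test_that("configuration errors are caught", {
  expect_error(gn_config(n = 130, q = 4), "divisible")
  expect_error(gn_config(z_out = 20, degree = 16), "z_out")
  ## p_in = (3 - 0) / (2 - 1) = 3 > 1
  expect_error(gn_config(n = 8, q = 4, degree = 3, z_out = 0), "probabilities")
})

test_that("snapshots are deterministic under a fixed seed", {
  cfg <- gn_config(n = 64, q = 4, degree = 10, z_out = 2, seed = 99)
  s1 <- gn_snapshot(cfg, layer = 1)
  s2 <- gn_snapshot(cfg, layer = 1)
  expect_identical(s1$adjacency, s2$adjacency)
  s3 <- gn_snapshot(cfg, layer = 2)
  expect_false(identical(s1$adjacency, s3$adjacency))
})

test_that("zero noise puts every edge inside its community", {
  cfg <- gn_config(n = 64, q = 4, degree = 10, z_out = 0, seed = 3)
  s <- gn_snapshot(cfg)
  truth <- unclass(s$partition)
  idx <- which(s$adjacency > 0, arr.ind = TRUE)
  expect_true(all(truth[idx[, 1]] == truth[idx[, 2]]))
})

test_that("expected vertex degree is conserved across noise levels", {
  for (z in c(1, 4, 8)) {
    degs <- vapply(1:50, function(s) {
      cfg <- gn_config(n = 128, q = 4, degree = 16, z_out = z, seed = s)
      mean(rowSums(gn_snapshot(cfg)$adjacency))
    }, numeric(1))
    ## binomial expectation 16; 3 standard errors of the seed means
    se <- stats::sd(degs) / sqrt(50)
    expect_lt(abs(mean(degs) - 16), max(3 * se, 0.5))
    if (z == 1) expect_true(mean(degs) > 15.5 && mean(degs) < 16.5)
  }
})

test_that("homogeneous layers share truth but differ in edges", {
  cfg <- gn_config(n = 128, q = 4, degree = 16, z_out = 1, M = 2, seed = 17)
  sim <- gn_homo_net(cfg)
  expect_equal(sim$net$M, 2)
  expect_false(identical(sim$net$W[[1]], sim$net$W[[2]]))
  expect_equal(n_modules(sim$partition), 4)

  ## planted partition scores above 100 random 4-partitions even at z_out = 4
  sim4 <- gn_homo_net(gn_config(n = 128, q = 4, degree = 16, z_out = 4, seed = 2))
  s_planted <- partition_score(sim4$net, sim4$partition)
  set.seed(1)
  worse <- replicate(100, {
    suppressWarnings(partition_score(sim4$net, rand_partition(128, 4)))
  })
  expect_true(all(worse < s_planted))
})

test_that("heterogeneous networks mix a fixed and a varying noise level", {
  cfg <- gn_config(n = 128, q = 4, degree = 16, M = 2, seed = 31)
  sim <- gn_heter_net(cfg, z_fixed = 4, z_var = 8)
  truth <- unclass(sim$partition)
  inter_deg <- function(W) {
    idx <- which(W > 0, arr.ind = TRUE)
    sum(truth[idx[, 1]] != truth[idx[, 2]]) / nrow(W)
  }
  ## layer 2 expects 8 inter-community edges per vertex, layer 1 expects 4
  i2 <- mean(vapply(1:20, function(s) {
    cfgs <- gn_config(n = 128, q = 4, degree = 16, M = 2, seed = s)
    inter_deg(gn_heter_net(cfgs, 4, 8)$net$W[[2]])
  }, numeric(1)))
  expect_lt(abs(i2 - 8), 0.5)
  i1 <- mean(vapply(1:20, function(s) {
    cfgs <- gn_config(n = 128, q = 4, degree = 16, M = 2, seed = s)
    inter_deg(gn_heter_net(cfgs, 4, 8)$net$W[[1]])
  }, numeric(1)))
  expect_lt(abs(i1 - 4), 0.5)
})

test_that("at zero noise the planted partition is score-optimal (enumeration)", {
  cfg <- gn_config(n = 12, q = 3, degree = 3, z_out = 0, M = 2, seed = 6)
  sim <- gn_homo_net(cfg)
  truth <- unclass(sim$partition)
  s_truth <- suppressWarnings(partition_score(sim$net, truth))
  ## enumerate all assignments of 12 vertices to 3 labels with vertex 1 pinned
  Ws <- sim$net$W
  ds <- lapply(Ws, rowSums)
  fast_score <- function(a) {
    X <- diag(3)[a, ]
    total <- 0
    Dm <- vapply(seq_along(Ws), function(m) {
      intra <- colSums(X * (Ws[[m]] %*% X))
      deg <- colSums(X * ds[[m]])
      ifelse(deg > 0, (2 * intra - deg) / deg, 0)
    }, numeric(3))
    sum(ifelse(apply(Dm <= 0, 1, any), 0, exp(rowMeans(log(pmax(Dm, 1e-300))))))
  }
  expect_equal(fast_score(truth), s_truth, tolerance = 1e-12)  # oracle sanity
  grid <- as.matrix(expand.grid(rep(list(1:3), 11)))
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    s <- fast_score(c(1L, grid[r, ]))
    if (s > best) best <- s
  }
  expect_equal(s_truth, best, tolerance = 1e-12)
})
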