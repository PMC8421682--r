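test_that("objective matches hand-computed Frobenius sums", {
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  net <- multinet(list(W))
  I2 <- diag(2)
  ## W - I = [[-1, 1], [1, -1]]: squared Frobenius norm 4
  expect_equal(jnmf_objective(net, list(B = I2, H = I2, F = list(I2))), 4)
  expect_equal(jnmf_objective(net, list(B = I2 * 0, H = I2, F = list(I2))),
               sum(W^2))
  ## exact factorization: complete bipartite = B H t(B)-style product
  B <- cbind(c(1, 0), c(0, 1))
  H <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(jnmf_objective(net, list(B = B, H = H, F = list(t(B)))), 0)
  ## bi-factor form: missing H means H = I
  expect_equal(jnmf_objective(net, list(B = B %*% H, F = list(t(B)))), 0)
  expect_error(jnmf_objective(net, list(B = matrix(1, 3, 2), F = list(t(B)))),
               "n x k")
})

test_that("an exact factorization is a fixed point of the update sweep", {
  ## complete bipartite between two blocks of 3: W = B H F exactly
  B <- matrix(0, 6, 2)
  B[1:3, 1] <- 1
  B[4:6, 2] <- 1
  H <- matrix(c(0, 1, 1, 0), 2, 2)
  W <- B %*% H %*% t(B)
  net <- multinet(list(W, W))
  fs <- list(B = B, H = H, F = list(t(B), t(B)))
  out <- jnmf_update(net, fs)
  expect_equal(out$B, fs$B, tolerance = 1e-9)
  expect_equal(out$H, fs$H, tolerance = 1e-9)
  expect_equal(out$F, fs$F, tolerance = 1e-9)
  ## bi-factor fixed point
  fs2 <- list(B = B %*% H, H = NULL, F = list(t(B), t(B)))
  out2 <- jnmf_update(net, fs2)
  expect_equal(out2$B, fs2$B, tolerance = 1e-9)
  expect_equal(out2$F, fs2$F, tolerance = 1e-9)
})

test_that("update sweeps never increase the objective", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(5:20, 1)
    M <- sample(1:3, 1)
    k <- sample(2:4, 1)
    net <- rand_multinet(n, M, seed = 1000 + s)
    fs <- rand_factors(net, k, seed = s, tri = (s %% 2 == 0))
    e0 <- jnmf_objective(net, fs)
    for (it in 1:5) {
      fs <- jnmf_update(net, fs)
      e1 <- jnmf_objective(net, fs)
      expect_lte(e1, e0 + 1e-10 * max(1, e0))
      e0 <- e1
    }
  }
})

test_that("an all-zero network collapses the factors to zero", {
  net <- multinet(list(matrix(0, 4, 4)))
  fs <- rand_factors(net, 2, seed = 1, tri = TRUE)
  fs <- jnmf_update(net, fs)
  expect_equal(jnmf_objective(net, fs), 0)
})

test_that("fitting recovers planted cliques and is deterministic", {
  net <- two_clique_net(2)
  planted <- rep(1:2, each = 4)
  fit <- jnmf(net, k = 2, restarts = 10, seed = 5)
  expect_equal(nmi(fit$partition, planted), 1)
  expect_true(all(diff(fit$objective_trace) <= 1e-10))
  expect_true(all(fit$factors$B >= 0))

  fit2 <- jnmf(net, k = 2, restarts = 10, seed = 5)
  expect_identical(fit$objective_trace, fit2$objective_trace)
  expect_identical(unclass(fit$partition), unclass(fit2$partition))

  ## tri-factor mode converges on the same structure
  fit3 <- jnmf(net, k = 2, mode = "tri", restarts = 10, seed = 5)
  expect_equal(nmi(fit3$partition, planted), 1)

  expect_error(jnmf(net, k = 8), "2 <= k < n")
})

test_that("low-noise benchmark structure is recovered", {
  sim <- gn_homo_net(gn_config(n = 128, q = 4, degree = 16, z_out = 1,
                               M = 2, seed = 77))
  fit <- jnmf(sim$net, k = 4, restarts = 10, seed = 2)
  expect_gte(nmi(fit$partition, sim$partition), 0.95)
})

test_that("a single-layer network reduces to ordinary NMF clustering", {
  net <- two_clique_net(1)
  fit <- jnmf(net, k = 2, restarts = 5, seed = 3)
  expect_equal(nmi(fit$partition, rep(1:2, each = 4)), 1)
})

test_that("scaling all layers scales the objective and keeps the partition", {
  net <- two_clique_net(2)
  c_scale <- 2.5
  net2 <- multinet(lapply(net$W, function(W) W * c_scale))
  ## fix the iteration count so the seeded trajectories align exactly
  f1 <- jnmf(net, k = 2, restarts = 3, seed = 9, tol = 1e-9, max_iter = 60)
  f2 <- jnmf(net2, k = 2, restarts = 3, seed = 9, tol = 1e-9, max_iter = 60)
  expect_equal(f2$objective, c_scale^2 * f1$objective, tolerance = 1e-6)
  expect_identical(unclass(f1$partition), unclass(f2$partition))
})

test_that("module extraction follows the argmax rule with documented edge cases", {
  B <- rbind(c(1, 0), c(0.9, 0.1), c(0.2, 0.2), c(0, 1))
  p <- extract_modules(B)
  expect_equal(unclass(p), c(1L, 1L, 1L, 2L), ignore_attr = TRUE)  # tie -> col 1

  ## empty column dropped
  B2 <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1))
  expect_message(p2 <- extract_modules(B2), "k reduced to 2")
  expect_equal(n_modules(p2), 2)

  ## all-zero row goes to module 1 with a warning
  B3 <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_warning(p3 <- extract_modules(B3), "all zero")
  expect_equal(unclass(p3)[1], 1L, ignore_attr = TRUE)

  expect_error(extract_modules(-B), "non-negative")
})
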