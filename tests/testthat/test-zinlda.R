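test_that("profile estimator evaluates exactly on hand-worked counts", {
  # V = 3, all taxa in support, counts (2, 1, 0), a = b = 1:
  # q1 = (1+2)/(1+2+1+1) = 3/5, q2 = (1+1)/(1+1+1+0) = 2/3
  n <- matrix(c(2, 1, 0), 1)
  delta <- matrix(0L, 1, 3)
  bhat <- zin_estimate_beta(n, delta, a = 1, b = 1)
  expect_equal(unname(bhat[1, ]),
               c(3 / 5, (2 / 3) * (2 / 5), (1 / 3) * (2 / 5)))
  expect_equal(sum(bhat), 1)
})

test_that("profile estimator agrees with numerical integration of the posterior", {
  # independent oracle: E[beta_i | n] via nested quadrature over the two
  # stick-breaking variables, unnormalised ZIGD-multinomial posterior
  cases <- list(list(n = c(2, 1, 0), a = 1, b = 1),
                list(n = c(4, 0, 3), a = 1.5, b = 2),
                list(n = c(0, 2, 5), a = 2, b = 3))
  comp <- function(q1, q2, i) {
    switch(i, q1 + 0 * q2, q2 * (1 - q1), (1 - q1) * (1 - q2))
  }
  int2 <- function(f) {
    outer_fn <- Vectorize(function(q1) {
      stats::integrate(function(q2) f(q1, q2), 0, 1,
                       rel.tol = 1e-11)$value
    })
    stats::integrate(outer_fn, 0, 1, rel.tol = 1e-11)$value
  }
  for (cs in cases) {
    post <- function(q1, q2) {
      comp(q1, q2, 1)^cs$n[1] * comp(q1, q2, 2)^cs$n[2] *
        comp(q1, q2, 3)^cs$n[3] *
        q1^(cs$a - 1) * (1 - q1)^(cs$b - 1) *
        q2^(cs$a - 1) * (1 - q2)^(cs$b - 1)
    }
    Z <- int2(post)
    for (i in 1:3) {
      num <- int2(function(q1, q2) comp(q1, q2, i) * post(q1, q2))
      est <- zin_estimate_beta(matrix(cs$n, 1), matrix(0L, 1, 3),
                               cs$a, cs$b)[1, i]
      expect_equal(est, num / Z, tolerance = 1e-6)
    }
  }
})

test_that("profile estimator handles support restrictions exactly", {
  # off-support entries are exactly zero, rows renormalise over the support
  n <- matrix(c(3, 0, 2, 1), 1)
  delta <- matrix(c(0L, 1L, 0L, 0L), 1)
  bhat <- zin_estimate_beta(n, delta, a = 0.5, b = 2)
  expect_identical(bhat[1, 2], 0)
  expect_equal(sum(bhat), 1)

  # single-support community: that taxon takes all the mass
  n1 <- matrix(c(0, 0, 4), 1)
  d1 <- matrix(c(1L, 1L, 0L), 1)
  expect_equal(unname(zin_estimate_beta(n1, d1, 0.05, 10)[1, ]), c(0, 0, 1))

  # a read on a structural zero is rejected
  expect_error(zin_estimate_beta(matrix(c(1, 0, 1), 1),
                                 matrix(c(1L, 0L, 0L), 1), 1, 1))
})

test_that("mixture-weight estimator evaluates the collapsed formula", {
  m <- matrix(c(3, 1), 1)
  expect_equal(unname(zin_estimate_theta(m, alpha = 1)[1, ]),
               c(4 / 6, 2 / 6))
  # prior dominance: large alpha pushes rows to uniform
  expect_equal(unname(zin_estimate_theta(m, alpha = 1e8)[1, ]), c(0.5, 0.5),
               tolerance = 1e-6)
  # empty sample: exactly uniform
  expect_equal(unname(zin_estimate_theta(matrix(0, 1, 4), alpha = 2)[1, ]),
               rep(0.25, 4))
})

test_that("indicator conditional follows the collapsed closed form", {
  n <- matrix(c(5, 0, 2), 1)
  # occupied cell: probability exactly zero
  expect_identical(zin_conditional_delta(1, 1, n, pi = 0.4, a = 0.05,
                                         b = 10), 0)
  # no inflation in the prior: never a structural zero
  expect_identical(zin_conditional_delta(2, 1, n, pi = 0, a = 0.05, b = 10),
                   0)
  # empty cell with no trailing counts: beta ratio is 1, probability = pi
  n2 <- matrix(c(4, 0, 0), 1)
  expect_equal(zin_conditional_delta(2, 1, n2, pi = 0.4, a = 0.05, b = 10),
               0.4)
  # trailing counts strengthen the evidence for a structural zero
  p_trail <- zin_conditional_delta(2, 1, n, pi = 0.4, a = 0.05, b = 10)
  expect_gt(p_trail, 0.4)
  expect_equal(p_trail,
               0.4 / (0.4 + 0.6 * beta(0.05, 12) / beta(0.05, 10)))
  # the last stick position is never resampled
  expect_error(zin_conditional_delta(3, 1, n, 0.4, 0.05, 10), "last stick")
})

test_that("assignment conditional matches exact joint probability ratios", {
  # brute-force oracle: place one read of taxon i in each community and
  # compare the normalised joint probabilities with the conditional
  K <- 2; V <- 3
  n <- rbind(c(1, 1, 0), c(0, 0, 1))        # read removed already
  m <- rbind(c(2, 1), c(0, 0))
  delta <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L))
  alpha <- 0.7; pi <- 0.4; a <- 0.5; b <- 2
  for (i in 1:3) {
    for (d in 1:2) {
      cond <- zin_conditional_z(i, d, n, m, delta, alpha, a, b)
      joint <- vapply(1:K, function(j) {
        n2 <- n; m2 <- m
        n2[j, i] <- n2[j, i] + 1
        m2[d, j] <- m2[d, j] + 1
        zin_state_logjoint(n2, m2, delta, alpha, pi, a, b)
      }, numeric(1))
      if (all(is.infinite(joint))) next
      expect_equal(cond, exp(joint - max(joint)) / sum(exp(joint - max(joint))),
                   tolerance = 1e-10)
    }
  }
  # a community whose support excludes the taxon gets probability exactly 0
  cond <- zin_conditional_z(1, 1, n, m, delta, alpha, a, b)
  expect_identical(cond[2], 0)
  # single community: trivially 1
  expect_equal(zin_conditional_z(1, 1, n[1, , drop = FALSE],
                                 m[, 1, drop = FALSE],
                                 delta[1, , drop = FALSE], alpha, a, b), 1)
})

test_that("initialisation from an LDA profile respects its support", {
  beta_lda <- rbind(c(1, 0.5, 1e-9), c(1e-9, 0.5, 1))
  beta_lda <- beta_lda / rowSums(beta_lda)
  set.seed(31)
  taxa <- rep(c(1L, 3L), each = 50)
  z0 <- init_from_lda(taxa, beta_lda)
  # essentially all reads of taxon 1 to community 1, taxon 3 to community 2
  expect_true(all(z0[taxa == 1] == 1))
  expect_true(all(z0[taxa == 3] == 2))
  # symmetric profile: roughly balanced assignment
  z0u <- init_from_lda(rep(2L, 4000), beta_lda)
  expect_lt(abs(mean(z0u == 1) - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("finalisation dichotomises inclusively and renormalises exactly", {
  beta_mean <- rbind(c(0.5, 0.3, 0.2), c(0.1, 0.2, 0.7))
  pi_hat <- rbind(c(0.5, 0.2, 0.1), c(1, 0.49999, 0))
  fin <- zin_finalize(beta_mean, pi_hat)
  # tie at 0.5 is zeroed (inclusive indicator); pi_hat = 1 zeroed
  expect_identical(fin$delta, rbind(c(1L, 0L, 0L), c(1L, 0L, 0L)))
  expect_identical(fin$beta[1, 1], 0)
  expect_identical(fin$beta[2, 1], 0)
  expect_equal(unname(fin$beta[1, ]), c(0, 0.6, 0.4))
  expect_true(all(abs(rowSums(fin$beta) - 1) < 1e-12))
  # a fully zeroed community is a hard error with a diagnostic
  expect_error(zin_finalize(beta_mean, matrix(1, 2, 3)),
               "degenerate community")
})

test_that("retained-state frequencies match the enumerated exact posterior", {
  counts <- matrix(c(1L, 1L, 0L, 0L, 1L, 1L), 2, byrow = TRUE)
  alpha <- 0.7; pi <- 0.4; a <- 0.5; b <- 2
  exact <- enum_zin_posterior(counts, K = 2, alpha = alpha, pi = pi,
                              a = a, b = b)
  fit <- zinlda(counts, K = 2, alpha = alpha, pi = pi, a = a, b = b,
                n_iter = 100200, burn_in = 200, seed = 32, init = "random",
                store_draws = FALSE, check = TRUE, trace = TRUE)
  expect_lt(tv_distance(exact, fit$trace), 0.02)
})

test_that("sweeps conserve counts, are deterministic, and honour pi = 0", {
  set.seed(33)
  sim <- simulate_zinlda(D = 10, V = 12, K = 2, depth_min = 80,
                         depth_max = 120)
  f1 <- zinlda(sim, K = 2, n_iter = 60, burn_in = 30, seed = 7,
               check = TRUE)
  f2 <- zinlda(sim, K = 2, n_iter = 60, burn_in = 30, seed = 7,
               check = TRUE)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$pi_hat, f2$pi_hat)
  expect_equal(unname(rowSums(f1$theta)), rep(1, 10))
  expect_true(all(abs(rowSums(f1$beta) - 1) < 1e-12))
  # structural zeros in the final estimate are exact zeros
  expect_identical(f1$beta == 0, f1$delta_hat == 1)

  # pi = 0: the indicator conditional is identically zero, no zeros appear
  f0 <- zinlda(sim, K = 2, pi = 0, n_iter = 40, burn_in = 20, seed = 8,
               check = TRUE)
  expect_true(all(f0$pi_hat == 0))
  expect_true(all(f0$beta > 0))
})

test_that("at the Dirichlet-nesting point the fit agrees with LDA", {
  # V = 2 makes the nesting point scalar: GD(a = eta, b = eta) = Dir(eta).
  # With pi = 0 the two samplers target the same posterior.
  set.seed(34)
  prof <- simulate_profiles(K = 2, V = 2, pi = 0, a = 1, b = 1)
  sim <- simulate_cohort(prof$beta, D = 15, depth_min = 150, depth_max = 250,
                         alpha = 2)
  eta <- 0.3
  fz <- zinlda(sim, K = 2, alpha = 2, pi = 0, a = eta, b = eta,
               n_iter = 1500, burn_in = 500, seed = 9, init = "random",
               store_draws = FALSE)
  fl <- lda_gibbs(sim, K = 2, alpha = 2, eta = eta, n_iter = 1500,
                  burn_in = 500, seed = 10, store_draws = FALSE)
  perm <- match_communities(fz$beta, fl$beta)
  expect_lt(max(abs(fz$beta - fl$beta[perm, ])), 0.05)
  expect_lt(max(abs(fz$theta - fl$theta[, perm])), 0.05)
})
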