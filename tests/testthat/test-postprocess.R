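test_that("community matching recovers identities, swaps and planted permutations", {
  set.seed(41)
  beta <- rdirichlet_test(3, 12)
  expect_identical(as.integer(match_communities(beta, beta)), 1:3)
  expect_identical(as.integer(match_communities(beta, beta[c(2, 1, 3), ])),
                   c(2L, 1L, 3L))

  # noisy permuted copies: greedy matching finds the planted permutation,
  # verified against exhaustive search over all 3! assignments
  for (rep in 1:5) {
    perm_true <- sample(3)
    noisy <- beta[perm_true, ] +
      matrix(stats::runif(36, 0, 0.005), 3, 12)
    noisy <- noisy / rowSums(noisy)
    got <- match_communities(beta, noisy)
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
    cors <- attr(got, "correlations")
    best <- perms[[which.max(vapply(perms, function(p)
      sum(diag(cors[, p])), numeric(1)))]]
    expect_identical(as.integer(got), as.integer(best))
    expect_identical(sort(as.integer(got)), 1:3)   # always a bijection
  }

  # zero-variance row: flagged, still a bijection
  flat <- rbind(rep(1 / 12, 12), beta[2, ])
  expect_warning(got <- match_communities(flat, beta[1:2, ]),
                 "zero-variance")
  expect_identical(sort(as.integer(got)), 1:2)
})

test_that("structural-zero confusion metrics count cells correctly", {
  d <- rbind(c(1L, 1L, 0L, 0L))
  m <- structural_zero_metrics(d, d)
  expect_equal(unlist(m[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))

  # hand-counted confusion: truth (1,1,0,0) vs estimate (1,0,0,1)
  m2 <- structural_zero_metrics(d, rbind(c(1L, 0L, 0L, 1L)))
  expect_equal(m2$sensitivity, 0.5)
  expect_equal(m2$specificity, 0.5)
  expect_equal(m2$ppv, 0.5)
  expect_equal(m2$npv, 0.5)
  expect_identical(m2$tp + m2$fp + m2$tn + m2$fn, length(d))

  # undefined ratios are missing, not zero
  m3 <- structural_zero_metrics(rbind(c(0L, 0L)), rbind(c(0L, 0L)))
  expect_true(is.na(m3$sensitivity))
  expect_true(is.na(m3$ppv))
  expect_equal(m3$specificity, 1)

  # matching permutation is applied to the estimate rows
  dt <- rbind(c(1L, 0L), c(0L, 1L))
  expect_equal(structural_zero_metrics(dt, dt[2:1, ],
                                       match = c(2L, 1L))$sensitivity, 1)
})

test_that("posterior predictive summaries respect ordering and conservation", {
  set.seed(42)
  obs <- matrix(rpois(40, 3), 4, 10,
                dimnames = list(paste0("s", 1:4), paste0("t", 1:10)))
  obs[1, 1:3] <- 0L
  storage.mode(obs) <- "integer"

  # replicates identical to the observation: median equals observed
  ppc <- ppc_summary(obs, list(obs, obs, obs))
  expect_equal(ppc$median, ppc$observed)
  expect_equal(ppc$observed_asinh, asinh(ppc$observed))
  expect_identical(ppc$observed_asinh[ppc$observed == 0],
                   rep(0, sum(obs == 0)))
  # within-sample ordering is ascending in the observed count
  for (s in unique(ppc$sample)) {
    expect_true(!is.unsorted(ppc$observed[ppc$sample == s]))
  }
  expect_error(ppc_summary(obs, list(obs[, 1:3])), "dimensions")

  # replicate generation: dimensions and depths are conserved
  set.seed(43)
  sim <- simulate_zinlda(D = 6, V = 8, K = 2, depth_min = 60, depth_max = 90)
  fit <- zinlda(sim, K = 2, n_iter = 40, burn_in = 20, init = "random")
  reps <- simulate(fit, nsim = 7, seed = 2)
  expect_length(reps, 7)
  expect_true(all(vapply(reps, function(r)
    identical(unname(rowSums(r)), as.numeric(sim$depths)), logical(1))))
  expect_identical(simulate(fit, nsim = 0), list())

  # degenerate draws concentrate where the profile does
  fitd <- fit
  fitd$draws$beta[] <- 0
  fitd$draws$beta[, 8, ] <- 1
  repd <- simulate(fitd, nsim = 2, seed = 3)[[1]]
  expect_equal(unname(colSums(repd)[8]), sum(sim$depths))
})

test_that("zero-position smoothing summary isolates observed zeros", {
  obs <- rbind(c(0L, 5L), c(2L, 3L))
  dimnames(obs) <- list(c("s1", "s2"), c("t1", "t2"))
  rep1 <- rbind(c(4L, 5L), c(2L, 3L))
  ppc <- ppc_summary(obs, list(rep1))
  zm <- ppc_zero_median(ppc)
  expect_equal(unname(zm["s1"]), 4)
  expect_true(is.na(zm["s2"]))
})

test_that("cosine stability behaves at its extremes and beats permutation", {
  set.seed(44)
  beta <- rdirichlet_test(3, 20)
  expect_equal(as.numeric(stability_cosine(beta, beta)), 1)

  # disjoint single-taxon communities are orthogonal
  a1 <- matrix(0, 2, 4); a1[1, 1] <- 1; a1[2, 2] <- 1
  b2 <- matrix(0, 2, 4); b2[1, 3] <- 1; b2[2, 4] <- 1
  expect_equal(as.numeric(stability_cosine(a1, b2)), 0)

  # fits on independent halves of one cohort agree far better than a
  # taxon-permuted baseline
  prof <- simulate_profiles(K = 2, V = 15, pi = 0.3, a = 0.5, b = 5)
  sim <- simulate_cohort(prof$beta, D = 40, depth_min = 400,
                         depth_max = 600, alpha = 1)
  fa <- zinlda(sim$counts[1:20, ], K = 2, a = 0.5, b = 5, n_iter = 150,
               burn_in = 75, seed = 1, store_draws = FALSE)
  fb <- zinlda(sim$counts[21:40, ], K = 2, a = 0.5, b = 5, n_iter = 150,
               burn_in = 75, seed = 2, store_draws = FALSE)
  observed <- as.numeric(stability_cosine(fa, fb))
  permuted <- as.numeric(stability_cosine(fa$beta,
                                          fb$beta[, sample(15)]))
  expect_gt(observed, permuted)
  expect_gt(observed, 0.8)
})

test_that("plug-in log-likelihood matches direct summation and flags zeros", {
  # degenerate single-cell fit: probability one, log-likelihood zero
  fit1 <- structure(list(beta = matrix(1, 1, 1), theta = matrix(1, 1, 1),
                         counts = matrix(10L, 1, 1), hyper = list(K = 1)),
                    class = "zinlda")
  expect_equal(as.numeric(logLik(fit1)), 0)

  set.seed(45)
  sim <- simulate_zinlda(D = 5, V = 6, K = 2, depth_min = 30, depth_max = 50)
  fit <- zinlda(sim, K = 2, n_iter = 40, burn_in = 20, init = "random",
                store_draws = FALSE)
  ll <- logLik(fit)
  # independent direct summation
  direct <- 0
  for (d in 1:5) for (i in 1:6) {
    if (sim$counts[d, i] > 0) {
      p <- sum(fit$theta[d, ] * fit$beta[, i])
      direct <- direct + sim$counts[d, i] * log(p)
    }
  }
  expect_equal(as.numeric(ll), direct, tolerance = 1e-9)

  # observed count on a taxon structurally zeroed everywhere: -Inf, flagged
  fit2 <- fit
  fit2$beta[, 3] <- 0
  fit2$beta <- fit2$beta / rowSums(fit2$beta)
  if (any(sim$counts[, 3] > 0)) {
    ll2 <- logLik(fit2)
    expect_identical(as.numeric(ll2), -Inf)
    expect_true(all(attr(ll2, "zero_cells")[, "col"] == 3))
  }
})
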