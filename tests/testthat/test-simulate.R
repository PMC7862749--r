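test_that("profile simulation matches the requested model", {
  set.seed(3)
  # certain inflation with one community: all mass on the final taxon
  prof <- simulate_profiles(K = 1, V = 6, pi = 1, a = 0.05, b = 10)
  expect_equal(prof$beta[1, ], c(rep(0, 5), 1), ignore_attr = TRUE)

  # marginal inflation rate near pi over repeated draws
  prof <- simulate_profiles(K = 40, V = 30, pi = 0.4, a = 0.05, b = 10)
  frac <- mean(prof$delta[, 1:29])
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / (40 * 29)))
  expect_true(all(abs(rowSums(prof$beta) - 1) < 1e-12))

  # LDA-model profiles are strictly positive
  prof <- simulate_profiles(K = 3, V = 10, eta = 0.1, model = "lda")
  expect_true(all(prof$beta > 0))
  expect_true(all(prof$delta == 0))
})

test_that("cohort generation conserves reads and respects the profiles", {
  set.seed(4)
  # deterministic profile: every read lands on the only supported taxon
  sim <- simulate_cohort(matrix(c(0, 0, 1), 1), D = 1, depth_min = 10,
                         depth_max = 10)
  expect_identical(as.vector(sim$counts), c(0L, 0L, 10L))

  sim <- simulate_zinlda(D = 25, V = 15, K = 3, depth_min = 100,
                         depth_max = 300)
  expect_identical(unname(rowSums(sim$counts)), as.numeric(sim$depths))
  expect_true(all(sim$counts >= 0))
  # bookkeeping identity: community-resolved reads sum to the counts
  expect_identical(apply(sim$z_counts, c(1, 3), sum),
                   unname(`dimnames<-`(sim$counts, NULL)))
  # depths inclusive on both bounds
  expect_true(all(sim$depths >= 100 & sim$depths <= 300))
})

test_that("sampling depths are uniform between the stated bounds", {
  set.seed(5)
  depths <- simulate_zinlda(D = 150, V = 5, K = 1, pi = 0,
                            depth_min = 5000, depth_max = 25000)$depths
  se <- sd(depths) / sqrt(150)
  expect_lt(abs(mean(depths) - 15000), 3 * se)
})

test_that("with one community column frequencies converge to the profile", {
  set.seed(6)
  prof <- simulate_profiles(K = 1, V = 10, pi = 0.3, a = 0.5, b = 3)
  sim <- simulate_cohort(prof$beta, D = 40, depth_min = 2000,
                         depth_max = 2000)
  freq <- colSums(sim$counts) / sum(sim$counts)
  se <- sqrt(prof$beta[1, ] * (1 - prof$beta[1, ]) / sum(sim$counts))
  expect_true(all(abs(freq - prof$beta[1, ]) < 4 * se + 1e-12))
})

test_that("simulation is reproducible and rejects degenerate profiles", {
  set.seed(11)
  s1 <- simulate_zinlda(D = 5, V = 8, K = 2, depth_min = 50, depth_max = 80)
  set.seed(11)
  s2 <- simulate_zinlda(D = 5, V = 8, K = 2, depth_min = 50, depth_max = 80)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$beta, s2$beta)
  expect_error(simulate_cohort(matrix(0, 1, 3), D = 2), "degenerate")
  expect_error(simulate_cohort(matrix(1, 1, 3) / 3, D = 2, depth_min = 10,
                               depth_max = 5), "depth_min")
})

test_that("unobserved-taxon removal drops exactly the all-zero columns", {
  counts <- rbind(c(2, 0, 1), c(1, 0, 3))
  out <- drop_unobserved_taxa(counts)
  expect_identical(attr(out, "taxon_map"), c(1L, 3L))
  expect_identical(ncol(out), 2L)
  # no zero columns: identity map
  out2 <- drop_unobserved_taxa(out)
  expect_identical(attr(out2, "taxon_map"), c(1L, 2L))
  expect_identical(unname(out2[, ]), unname(out[, ]))
  expect_error(drop_unobserved_taxa(matrix(0L, 2, 2)), "zero total")

  # ground truth follows the retained columns without renormalisation
  set.seed(12)
  sim <- simulate_zinlda(D = 6, V = 25, K = 2, pi = 0.6, a = 0.05, b = 10,
                         depth_min = 30, depth_max = 60)
  dropped <- drop_unobserved_taxa(sim)
  keep <- attr(dropped, "taxon_map")
  expect_identical(dropped$beta, sim$beta[, keep])
  expect_identical(dropped$delta, sim$delta[, keep])
})

test_that("prevalence filter applies the strict-inequality boundary", {
  counts <- matrix(0L, 10, 3)
  counts[, 1] <- 5L
  counts[1, 2] <- 2L            # prevalence 0.1 -> removed at 0.2
  counts[1:2, 3] <- 1L          # prevalence 0.2 -> retained (not < 0.2)
  out <- prevalence_filter(counts, 0.2)
  expect_identical(attr(out, "taxon_map"), c(1L, 3L))

  # min_prevalence = 0: only all-zero samples are removed
  counts2 <- rbind(c(1, 0), c(0, 0))
  out2 <- prevalence_filter(counts2, 0)
  expect_identical(attr(out2, "sample_map"), 1L)
  expect_identical(nrow(out2), 1L)

  # idempotence
  out3 <- prevalence_filter(out, 0.2)
  expect_identical(unname(out3[, ]), unname(out[, ]))
  expect_error(prevalence_filter(counts, 2), "min_prevalence")
  expect_error(prevalence_filter(matrix(0L, 3, 2), 0.5), "every taxon")
})
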