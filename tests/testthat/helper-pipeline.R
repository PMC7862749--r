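# Full simulation -> fit -> evaluation pipeline used by the heavier
# validation tests: simulate at a reference-design setting, drop taxa never
# observed, fit the LDA baseline, fit zinLDA initialised from it, match
# communities to the truth.
run_zin_pipeline <- function(seed, V, a, D = 150,
                             depth_min = 5000, depth_max = 25000,
                             n_iter = 250, burn_in = 125,
                             lda_iter = 150, move_reps = 15,
                             store_draws = FALSE) {
  set.seed(seed)
  sim <- simulate_zinlda(D = D, V = V, K = 5, alpha = 10, pi = 0.4,
                         a = a, b = 10,
                         depth_min = depth_min, depth_max = depth_max)
  sim <- drop_unobserved_taxa(sim)
  lfit <- lda_gibbs(sim, K = 5, n_iter = lda_iter,
                    burn_in = lda_iter / 2, store_draws = store_draws)
  fit <- zinlda(sim, K = 5, alpha = 10, pi = 0.4, a = a, b = 10,
                n_iter = n_iter, burn_in = burn_in, init = lfit,
                move_reps = move_reps, store_draws = store_draws)
  perm <- match_communities(sim$beta, fit$beta)
  metrics <- structural_zero_metrics(sim$delta, fit$delta_hat, match = perm)
  list(sim = sim, lda = lfit, fit = fit, match = perm, metrics = metrics)
}

# heavier fixtures shared between test blocks, computed once per run
.pipeline_cache <- new.env(parent = emptyenv())
cached_pipeline <- function(key, ...) {
  if (is.null(.pipeline_cache[[key]])) {
    .pipeline_cache[[key]] <- run_zin_pipeline(...)
  }
  .pipeline_cache[[key]]
}
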