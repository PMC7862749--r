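#' Fit zero-inflated LDA by collapsed Gibbs sampling
#'
#' Fits the zero-inflated latent Dirichlet allocation model: subcommunity
#' taxon profiles carry a zero-inflated generalized Dirichlet prior
#' `ZIGD(pi, a, b)`, so each profile can place probability exactly zero on a
#' taxon (a structural zero, indicator `Delta = 1`), while per-sample mixture
#' weights carry a symmetric `Dirichlet(alpha)` prior. Both conjugate priors
#' are integrated out and the sampler alternates a full scan of per-read
#' subcommunity assignments `z` with a full scan of the structural-zero
#' indicators `Delta`. A read can only be assigned to communities whose
#' support includes its taxon, and an indicator can only switch on where the
#' community currently holds no reads of that taxon.
#'
#' By default the chain is initialised from a standard LDA fit: each read of
#' taxon `i` starts in community `j` with probability proportional to the LDA
#' estimate `beta[j, i]`, and all indicators start at zero.
#'
#' Finalisation: `theta` is the posterior mean over retained draws; `pi_hat`
#' is the posterior mean of the indicator draws; `beta` entries with
#' `pi_hat >= 0.5` are set to exactly zero and the remaining posterior means
#' are renormalised within each community.
#'
#' @inheritParams lda_gibbs
#' @param pi Prior probability that a stick position is zero-inflated.
#' @param a,b Beta shape parameters of the ZIGD prior (positive scalars).
#' @param init Either `"lda"` (default; fits an LDA baseline with the same
#'   chain settings and `eta = 0.1` and samples initial assignments from its
#'   `beta`), `"random"`, an `"lda_fit"` object, or an integer vector of
#'   per-read assignments in `1..K`.
#' @param move_reps Number of repetitions of the block-move pass per
#'   sweep. Each locked indicator needs a specific (source, sample,
#'   target) proposal to be drawn, so repeating the cheap pass sharply
#'   increases the rate at which the chain crosses between the "present"
#'   and "absent" modes of a cell without affecting the target
#'   distribution. Default 10.
#' @param block_moves Include the taxon-block exchange move (a
#'   Metropolis-Hastings step proposing to move all of one community's
#'   reads of one taxon to a community holding none) in every sweep. The
#'   read-level scan alone mixes poorly between the "taxon present" and
#'   "taxon absent" modes of a cell; the block move jumps between them
#'   directly and leaves the posterior invariant. Default `TRUE`.
#' @param init_threshold Pruning threshold for LDA-based initialisation
#'   (see [init_from_lda()]): communities holding less than this share of a
#'   taxon's initial assignment probability start with no reads of that
#'   taxon. Default 0.02; set to 0 for unpruned sampling.
#' @param init_sharpen Sharpening exponent for LDA-based initialisation
#'   (see [init_from_lda()]). Default 1 (probabilities proportional to the
#'   LDA profile estimates).
#' @param check Run internal bookkeeping invariant checks every sweep
#'   (slower; intended for testing).
#' @param trace Record an encoded `(z, Delta)` state per post-burn-in sweep
#'   (tiny instances only; used by enumeration-based validation).
#' @return An object of class `"zinlda"`: `beta` (`K x V`, rows sum to 1,
#'   exact zeros at dichotomised structural zeros), `theta` (`D x K`),
#'   `pi_hat` (`K x V` posterior mean of the indicators), `delta_hat`
#'   (`K x V` binary, `pi_hat >= 0.5`), `beta_mean` (pre-dichotomisation
#'   posterior mean), `draws`, `counts`, `hyper`, `chain`, and `init_fit`
#'   (the initialising LDA fit, when one was fitted internally).
#' @references The zero-inflation construction follows the stick-breaking
#'   representation of the generalized Dirichlet distribution.
#' @export
#' @examples
#' set.seed(11)
#' sim <- simulate_zinlda(D = 12, V = 15, K = 2, depth_min = 200,
#'                        depth_max = 400)
#' fit <- zinlda(sim, K = 2, n_iter = 60, burn_in = 30)
#' round(coef(fit), 3)
zinlda <- function(counts, K, alpha = 50 / K, pi = 0.4, a = 0.05, b = 10,
                   n_iter = 2000, burn_in = 1000, thin = 1, seed = NULL,
                   init = "lda", init_threshold = 0.02, init_sharpen = 1,
                   block_moves = TRUE, move_reps = 10, store_draws = TRUE,
                   check = FALSE, trace = FALSE) {
  counts <- as_count_matrix(counts)
  check_chain_args(K, n_iter, burn_in, thin, counts)
  check_zigd_params(pi, a, b, max(ncol(counts), 2L))
  if (length(pi) != 1L || length(a) != 1L || length(b) != 1L) {
    stop("the fitted model takes scalar (pi, a, b)", call. = FALSE)
  }
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  reads <- expand_reads(counts)
  init_fit <- NULL
  if (is.character(init) && identical(init, "lda")) {
    init_fit <- lda_gibbs(counts, K, alpha = alpha, eta = 0.1,
                          n_iter = n_iter, burn_in = burn_in, thin = thin,
                          store_draws = FALSE)
    z0 <- init_from_lda(reads$taxon, init_fit$beta, init_threshold,
                        init_sharpen)
  } else if (is.character(init) && identical(init, "random")) {
    z0 <- sample.int(K, length(reads$doc), replace = TRUE)
  } else if (inherits(init, "lda_fit")) {
    if (init$hyper$K != K || !identical(init$taxon_order, colnames(counts))) {
      stop("initialising LDA fit must share K and taxon order", call. = FALSE)
    }
    init_fit <- init
    z0 <- init_from_lda(reads$taxon, init_fit$beta, init_threshold,
                        init_sharpen)
  } else if (is.numeric(init)) {
    stopifnot(length(init) == length(reads$doc), all(init %in% seq_len(K)))
    z0 <- as.integer(init)
  } else {
    stop("unknown init", call. = FALSE)
  }

  res <- zinlda_gibbs_cpp(reads$doc - 1L, reads$taxon - 1L, z0 - 1L,
                          nrow(counts), ncol(counts), as.integer(K),
                          alpha, pi, a, b,
                          as.integer(n_iter), as.integer(burn_in),
                          as.integer(thin), block_moves,
                          as.integer(move_reps), store_draws,
                          trace, check)

  fin <- zin_finalize(res$beta_mean, res$pi_hat)
  fit <- build_fit(res, counts, K,
                   hyper = list(alpha = alpha, pi = pi, a = a, b = b, K = K),
                   chain = list(n_iter = n_iter, burn_in = burn_in,
                                thin = thin, seed = seed,
                                n_kept = res$n_kept,
                                n_fallback = res$n_fallback),
                   class = "zinlda",
                   extra = list(init_fit = init_fit))
  fit$beta_mean <- fit$beta
  fit$beta <- fin$beta
  dimnames(fit$beta) <- dimnames(fit$beta_mean)
  fit$pi_hat <- res$pi_hat
  fit$delta_hat <- fin$delta
  if (trace) fit$trace <- res$trace
  dimnames(fit$pi_hat) <- dimnames(fit$delta_hat) <- dimnames(fit$beta)
  if (res$n_fallback > 0) {
    warning(sprintf("conditional fallback used for %d read resamples %s",
                    res$n_fallback,
                    "(taxon transiently excluded from every community)"),
            call. = FALSE)
  }
  fit
}

#' Sample initial read assignments from an LDA profile estimate
#'
#' Each read of taxon `i` is assigned to community `j` with probability
#' proportional to `beta_lda[j, i]`; structural-zero indicators start at
#' zero, so every taxon begins in every community's support.
#'
#' Communities holding less than `threshold` of a taxon's profile mass
#' (after normalising the column) are excluded from that taxon's initial
#' assignment. The Dirichlet smoothing of an LDA fit leaks a small share of
#' every taxon into every community; seeding the chain with those leaked
#' reads leaves candidate structural-zero cells occupied, and an occupied
#' cell is metastable (its posterior-predictive mass grows with its count),
#' so the indicator equilibrates very slowly. Pruning negligible initial
#' shares only changes the starting point — the sampler can reintroduce
#' reads wherever the posterior wants them — but removes the metastable
#' traps. `threshold = 0` reproduces the unpruned assignment.
#'
#' @param taxon Integer vector, the taxon index of each read.
#' @param beta_lda `K x V` matrix of strictly positive profile estimates.
#' @param threshold Minimum within-taxon share for a community to receive
#'   initial reads; the best community is always kept.
#' @param sharpen Exponent applied to the profile columns before
#'   normalising (`1` = use the estimates as-is; larger values concentrate
#'   initial assignments on the communities where the taxon has most of
#'   its estimated mass, reducing seeded leakage the same way the
#'   threshold does, but smoothly).
#' @return Integer vector of initial assignments in `1..K`.
#' @keywords internal
#' @export
init_from_lda <- function(taxon, beta_lda, threshold = 0, sharpen = 1) {
  K <- nrow(beta_lda)
  z0 <- integer(length(taxon))
  for (i in unique(taxon)) {
    idx <- which(taxon == i)
    w <- beta_lda[, i]^sharpen
    w <- w / sum(w)
    w[w < threshold & w < max(w)] <- 0
    z0[idx] <- sample.int(K, length(idx), replace = TRUE, prob = w)
  }
  z0
}

#' Dichotomise and renormalise a posterior-mean profile matrix
#'
#' Implements the two-part final profile estimate: entries whose posterior
#' structural-zero probability `pi_hat` is at least 0.5 (inclusive) are set
#' to exactly zero; remaining entries keep their posterior mean and each row
#' is renormalised to sum to 1.
#'
#' @param beta_mean `K x V` posterior means of the per-draw profile
#'   estimates.
#' @param pi_hat `K x V` posterior means of the structural-zero indicators.
#' @return List with `beta` (rows sum to 1, exact zeros) and `delta`
#'   (binary, the dichotomised indicators).
#' @export
zin_finalize <- function(beta_mean, pi_hat) {
  stopifnot(all(dim(beta_mean) == dim(pi_hat)))
  delta <- matrix(as.integer(pi_hat >= 0.5), nrow(pi_hat), ncol(pi_hat))
  beta <- beta_mean
  beta[delta == 1L] <- 0
  rs <- rowSums(beta)
  if (any(rs == 0)) {
    stop(sprintf("degenerate community: row(s) %s entirely zeroed",
                 paste(which(rs == 0), collapse = ", ")), call. = FALSE)
  }
  list(beta = beta / rs, delta = delta)
}
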