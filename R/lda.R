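#' Fit standard LDA by collapsed Gibbs sampling
#'
#' Baseline latent Dirichlet allocation for a sample-by-taxon count matrix:
#' symmetric `Dirichlet(eta)` prior on the `K` subcommunity taxon profiles
#' and symmetric `Dirichlet(alpha)` prior on per-sample mixture weights.
#' The collapsed sampler resamples each read's subcommunity from
#' `P(z = j) \propto (n_j^{(i)} + eta) / (n_j + V eta) * (m_j^{(d)} + alpha)`,
#' all counts excluding the read itself. Estimates are posterior means of the
#' per-draw smoothed proportions; every entry of `beta` is strictly positive
#' (the Dirichlet over-smoothing that the zero-inflated model removes).
#'
#' @param counts Sample-by-taxon matrix of nonnegative integer counts (or a
#'   `"zinlda_sim"` object, whose `$counts` is used).
#' @param K Number of subcommunities.
#' @param alpha Concentration on mixture weights; default `50 / K`.
#' @param eta Concentration on taxon profiles; default `0.1`.
#' @param n_iter,burn_in,thin Chain length, discarded initial sweeps, and
#'   thinning interval for retained draws.
#' @param seed Optional integer seed (applied via [set.seed()]).
#' @param store_draws Keep the retained per-draw `(beta, theta)` matrices
#'   (needed for posterior predictive checks via [simulate.lda_fit()]).
#' @param init Optional integer vector of initial per-read assignments in
#'   `1..K` (read order: by sample, then taxon, then replicate read);
#'   default is uniform random.
#' @param check Run internal bookkeeping invariant checks every sweep
#'   (slower; intended for testing).
#' @param trace Record an encoded `(z)` state per post-burn-in sweep
#'   (tiny instances only; used by enumeration-based validation).
#' @return An object of class `"lda_fit"` with components `beta` (`K x V`),
#'   `theta` (`D x K`), `draws`, `counts`, `hyper`, and `chain`.
#' @seealso [zinlda()] for the zero-inflated model.
#' @export
lda_gibbs <- function(counts, K, alpha = 50 / K, eta = 0.1,
                      n_iter = 2000, burn_in = 1000, thin = 1,
                      seed = NULL, store_draws = TRUE, init = NULL,
                      check = FALSE, trace = FALSE) {
  counts <- as_count_matrix(counts)
  check_chain_args(K, n_iter, burn_in, thin, counts)
  if (alpha <= 0 || eta <= 0) stop("alpha and eta must be positive",
                                   call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  reads <- expand_reads(counts)
  z0 <- if (is.null(init)) {
    sample.int(K, length(reads$doc), replace = TRUE) - 1L
  } else {
    stopifnot(length(init) == length(reads$doc), all(init %in% seq_len(K)))
    as.integer(init) - 1L
  }
  res <- lda_gibbs_cpp(reads$doc - 1L, reads$taxon - 1L, z0,
                       nrow(counts), ncol(counts), as.integer(K),
                       alpha, eta, as.integer(n_iter), as.integer(burn_in),
                       as.integer(thin), store_draws, trace, check)
  fit <- build_fit(res, counts, K,
                   hyper = list(alpha = alpha, eta = eta, K = K),
                   chain = list(n_iter = n_iter, burn_in = burn_in,
                                thin = thin, seed = seed,
                                n_kept = res$n_kept),
                   class = "lda_fit")
  if (trace) fit$trace <- res$trace
  fit
}

# shared scaffolding -------------------------------------------------------

as_count_matrix <- function(x) {
  if (inherits(x, "zinlda_sim")) x <- x$counts
  x <- as.matrix(x)
  if (any(x < 0) || any(x != round(x))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  storage.mode(x) <- "integer"
  if (is.null(rownames(x))) rownames(x) <- sample_labels(nrow(x))
  if (is.null(colnames(x))) colnames(x) <- taxon_labels(ncol(x))
  x
}

check_chain_args <- function(K, n_iter, burn_in, thin, counts) {
  if (K < 1 || K != round(K)) stop("K must be a positive integer",
                                   call. = FALSE)
  if (sum(counts) < K) {
    stop("degenerate configuration: K exceeds the total number of reads",
         call. = FALSE)
  }
  if (sum(counts) == 0) stop("empty cohort", call. = FALSE)
  if (n_iter <= burn_in || burn_in < 0 || thin < 1) {
    stop("need n_iter > burn_in >= 0 and thin >= 1", call. = FALSE)
  }
  invisible(TRUE)
}

# one row per read, ordered by sample then taxon; reads within a
# (sample, taxon) cell are exchangeable
expand_reads <- function(counts) {
  tc <- t(counts)
  times <- as.vector(tc)
  list(doc = rep.int(as.vector(col(tc)), times),
       taxon = rep.int(as.vector(row(tc)), times))
}

build_fit <- function(res, counts, K, hyper, chain, class,
                      extra = list()) {
  K <- as.integer(K)
  dn_beta <- list(paste0("community_", seq_len(K)), colnames(counts))
  dn_theta <- list(rownames(counts), dn_beta[[1]])
  beta <- res[[if (class == "lda_fit") "beta" else "beta_mean"]]
  dimnames(beta) <- dn_beta
  theta <- res$theta
  dimnames(theta) <- dn_theta
  draws <- NULL
  if (!is.null(res$beta_draws)) {
    draws <- list(beta = res$beta_draws, theta = res$theta_draws,
                  delta = res$delta_draws)
  }
  fit <- c(list(beta = beta, theta = theta, draws = draws,
                counts = counts, depths = rowSums(counts),
                hyper = hyper, chain = chain,
                taxon_order = colnames(counts)),
           extra)
  structure(fit, class = class)
}
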