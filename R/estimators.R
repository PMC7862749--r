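#' Per-draw subcommunity profile estimate under the ZIGD posterior
#'
#' Given current taxon-in-community counts and structural-zero indicators,
#' returns the posterior-predictive taxon distribution of each community:
#' the stick-breaking posterior mean. Writing the support members of
#' community `j` in ascending taxon order, each non-terminal support taxon
#' `i` contributes a factor `(a + n_i) / (a + n_i + b_i)` with
#' `b_i = b + sum of counts after i`, times the product of the complementary
#' factors of the support members before it; the last support taxon receives
#' the remaining stick. Entries off support are exactly zero, and each row
#' sums to 1 over its support.
#'
#' @param n `K x V` matrix of taxon-in-community read counts.
#' @param delta `K x V` binary matrix of structural-zero indicators
#'   (`delta[j, i] = 1` requires `n[j, i] = 0`; the last column must be 0).
#' @param a,b ZIGD beta shape parameters.
#' @return `K x V` matrix of profile estimates.
#' @export
zin_estimate_beta <- function(n, delta, a, b) {
  n <- as.matrix(n); delta <- as.matrix(delta)
  stopifnot(all(dim(n) == dim(delta)), all(n[delta == 1] == 0),
            all(delta[, ncol(delta)] == 0))
  t(vapply(seq_len(nrow(n)), function(j) {
    zigd_posterior_mean(n[j, ], delta[j, ], a, b)
  }, numeric(ncol(n))))
}

zigd_posterior_mean <- function(nj, deltaj, a, b) {
  V <- length(nj)
  trailing <- rev(cumsum(rev(nj)))[-1]  # counts strictly after position i
  trailing <- c(trailing, 0)
  beta <- numeric(V)
  stick <- 1
  for (i in seq_len(V)) {
    if (i == V) {
      beta[i] <- stick
    } else if (deltaj[i] == 1) {
      beta[i] <- 0
    } else {
      q <- (a + nj[i]) / (a + nj[i] + b + trailing[i])
      beta[i] <- q * stick
      stick <- stick * (1 - q)
    }
  }
  beta
}

#' Per-draw mixture-weight estimate
#'
#' The collapsed posterior-predictive community distribution of each sample:
#' `theta[d, j] = (m[d, j] + alpha) / (sum(m[d, ]) + K * alpha)`.
#'
#' @param m `D x K` matrix of community-in-sample read counts.
#' @param alpha Dirichlet concentration.
#' @return `D x K` matrix with rows summing to 1.
#' @export
zin_estimate_theta <- function(m, alpha) {
  m <- as.matrix(m)
  K <- ncol(m)
  (m + alpha) / (rowSums(m) + K * alpha)
}

#' Full conditional for one read's subcommunity assignment
#'
#' Returns the normalised probability over communities for a read of taxon
#' `i` in sample `d`, with the read's own contribution already removed from
#' the count statistics. Component `j` is proportional to the community's
#' posterior-predictive probability of taxon `i` (exactly zero when the
#' taxon is off community `j`'s support) times `m[d, j] + alpha`. If the
#' taxon is excluded from every community (reachable only transiently), the
#' no-inflation conditional is used instead, mirroring the sampler's guard.
#'
#' @param i Taxon index of the read.
#' @param d Sample index of the read.
#' @param n,delta As in [zin_estimate_beta()], excluding the current read.
#' @param m As in [zin_estimate_theta()], excluding the current read.
#' @param alpha,a,b Hyperparameters.
#' @return Length-`K` probability vector.
#' @export
zin_conditional_z <- function(i, d, n, m, delta, alpha, a, b) {
  bhat <- zin_estimate_beta(n, delta, a, b)
  p <- bhat[, i] * (m[d, ] + alpha)
  if (sum(p) == 0) {
    bhat <- zin_estimate_beta(n, 0 * delta, a, b)
    p <- bhat[, i] * (m[d, ] + alpha)
  }
  p / sum(p)
}

#' Full conditional for one structural-zero indicator
#'
#' Probability that taxon `i` is a structural zero of community `j` given
#' the current read assignments: exactly zero whenever the community holds
#' reads of that taxon, and otherwise
#' `pi / (pi + (1 - pi) * B(a, b + T) / B(a, b))` where `T` is the total
#' count assigned to community `j` at taxa after position `i`. The beta
#' function ratio is evaluated in log space.
#'
#' @inheritParams zin_conditional_z
#' @param j Community index.
#' @param pi Prior zero-inflation probability.
#' @return Scalar probability of `delta[j, i] = 1`.
#' @export
zin_conditional_delta <- function(i, j, n, pi, a, b) {
  n <- as.matrix(n)
  V <- ncol(n)
  if (i >= V) stop("the last stick position is never zero-inflated",
                   call. = FALSE)
  if (n[j, i] > 0) return(0)
  if (pi <= 0) return(0)
  trailing <- if (i < V) sum(n[j, (i + 1):V]) else 0
  lratio <- lbeta(a + n[j, i], b + trailing) - lbeta(a, b)
  unname(pi / (pi + (1 - pi) * exp(lratio)))
}
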