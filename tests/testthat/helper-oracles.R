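# Exact-enumeration oracles for tiny instances. These compute posterior
# probabilities by brute force from the collapsed joint (conjugate closed
# forms), independently of the package's samplers, and are used to validate
# chain frequencies and conditional distributions.

# Read layout identical to the fitting functions: by sample, then taxon.
expand_reads_helper <- function(counts) {
  tc <- t(counts)
  times <- as.vector(tc)
  list(doc = rep.int(as.vector(col(tc)), times),
       taxon = rep.int(as.vector(row(tc)), times))
}

# log joint of an LDA state from sufficient statistics (z-independent
# constants dropped; consistent across states of one data set)
lda_state_logjoint <- function(n, m, alpha, eta) {
  V <- ncol(n)
  sum(lgamma(m + alpha)) +
    sum(lgamma(n + eta)) - sum(lgamma(rowSums(n) + V * eta))
}

# Exact posterior over all K^N assignment vectors; names are the sampler's
# trace codes (sum over reads of z_r * K^r, z zero-based).
enum_lda_posterior <- function(counts, K, alpha, eta) {
  reads <- expand_reads_helper(counts)
  N <- length(reads$doc)
  D <- nrow(counts); V <- ncol(counts)
  grid <- as.matrix(expand.grid(rep(list(0:(K - 1)), N)))
  logp <- apply(grid, 1, function(z) {
    n <- matrix(0, K, V); m <- matrix(0, D, K)
    for (r in seq_len(N)) {
      n[z[r] + 1, reads$taxon[r]] <- n[z[r] + 1, reads$taxon[r]] + 1
      m[reads$doc[r], z[r] + 1] <- m[reads$doc[r], z[r] + 1] + 1
    }
    lda_state_logjoint(n, m, alpha, eta)
  })
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  names(p) <- as.character(grid %*% K^(0:(N - 1)))
  p
}

# log joint of a zinLDA state (z, delta) from sufficient statistics:
# Bernoulli(pi) prior on the indicators, generalized-Dirichlet marginal
# likelihood per community over its support, Dirichlet-multinomial sample
# factor. -Inf when a read sits on a structural zero.
zin_state_logjoint <- function(n, m, delta, alpha, pi, a, b) {
  K <- nrow(n); V <- ncol(n)
  lp <- sum(lgamma(m + alpha))
  dsub <- delta[, -V, drop = FALSE]
  if (pi > 0 && pi < 1) {
    lp <- lp + sum(dsub * log(pi) + (1 - dsub) * log(1 - pi))
  } else if ((pi == 0 && any(dsub == 1)) || (pi == 1 && any(dsub == 0))) {
    return(-Inf)
  }
  for (j in seq_len(K)) {
    if (any(n[j, delta[j, ] == 1] > 0)) return(-Inf)
    supp <- c(which(delta[j, -V] == 0), V)
    L <- length(supp)
    if (L > 1) {
      ns <- n[j, supp]
      trailing <- rev(cumsum(rev(ns)))[-1]
      lp <- lp + sum(lbeta(a + ns[-L], b + trailing) - lbeta(a, b))
    }
  }
  lp
}

# Exact posterior over all (z, delta) configurations; names match the
# sampler's trace codes: zcode + K^N * deltacode, with delta bits ordered
# community-major, taxon-minor.
enum_zin_posterior <- function(counts, K, alpha, pi, a, b) {
  reads <- expand_reads_helper(counts)
  N <- length(reads$doc)
  D <- nrow(counts); V <- ncol(counts)
  zgrid <- as.matrix(expand.grid(rep(list(0:(K - 1)), N)))
  dgrid <- as.matrix(expand.grid(rep(list(0:1), K * (V - 1))))
  codes <- numeric(0); probs <- numeric(0)
  for (gd in seq_len(nrow(dgrid))) {
    delta <- cbind(matrix(dgrid[gd, ], K, V - 1, byrow = TRUE), 0)
    dcode <- sum(t(delta[, -V, drop = FALSE]) * 2^(0:(K * (V - 1) - 1)))
    for (gz in seq_len(nrow(zgrid))) {
      z <- zgrid[gz, ]
      n <- matrix(0, K, V); m <- matrix(0, D, K)
      for (r in seq_len(N)) {
        n[z[r] + 1, reads$taxon[r]] <- n[z[r] + 1, reads$taxon[r]] + 1
        m[reads$doc[r], z[r] + 1] <- m[reads$doc[r], z[r] + 1] + 1
      }
      lp <- zin_state_logjoint(n, m, delta, alpha, pi, a, b)
      if (is.finite(lp)) {
        codes <- c(codes, sum(z * K^(0:(N - 1))) + K^N * dcode)
        probs <- c(probs, lp)
      }
    }
  }
  p <- exp(probs - max(probs))
  p <- p / sum(p)
  names(p) <- as.character(codes)
  p
}

# total-variation distance between exact probabilities and a vector of
# observed state codes
tv_distance <- function(exact, trace_codes) {
  emp <- table(as.character(trace_codes)) / length(trace_codes)
  states <- union(names(exact), names(emp))
  pe <- ifelse(states %in% names(exact), exact[states], 0)
  po <- ifelse(states %in% names(emp), emp[states], 0)
  sum(abs(pe - po)) / 2
}

# delta bit ordering shared with the C++ trace encoder
delta_code <- function(delta, K, V) {
  sum(t(delta[, -V, drop = FALSE]) * 2^(0:(K * (V - 1) - 1)))
}

# simple simplex rows for matching/stability tests
rdirichlet_test <- function(k, v, shape = 0.8) {
  g <- matrix(stats::rgamma(k * v, shape), k, v)
  g / rowSums(g)
}
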