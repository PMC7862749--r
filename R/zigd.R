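#' Zero-inflated beta draws for the stick-breaking construction
#'
#' Draws the `V - 1` independent stick-breaking variables underlying a
#' zero-inflated generalized Dirichlet (ZIGD) composition of length `V`.
#' Each variable is exactly 0 with probability `pi` and otherwise a
#' `Beta(a, b)` draw.
#'
#' @param V Integer >= 2, length of the target composition. `V - 1` variables
#'   are drawn.
#' @param pi Zero-inflation probability in `[0, 1]`. May be a scalar or a
#'   vector of length `V - 1` (recycled per position).
#' @param a,b Positive beta shape parameters; scalars or length `V - 1`
#'   vectors. The fitted model uses symmetric scalars; vector values are
#'   supported for simulation only (e.g. to place the generalized Dirichlet at
#'   its Dirichlet-nesting point).
#' @return Numeric vector of length `V - 1` with values in `[0, 1)`; zeros are
#'   exact.
#' @seealso [stick_break()], [rzigd()]
#' @export
#' @examples
#' set.seed(1)
#' rzibeta(6, pi = 0.4, a = 0.05, b = 10)
rzibeta <- function(V, pi, a, b) {
  check_zigd_params(pi, a, b, V)
  n <- V - 1L
  q <- stats::rbeta(n, a, b)
  # rbeta can return 1 only with zero probability; clamp defensively so the
  # stick-breaking map's [0, 1) domain holds.
  q[q >= 1] <- 1 - .Machine$double.eps
  zero <- stats::runif(n) < pi
  q[zero] <- 0
  q
}

#' Stick-breaking map with exact zeros
#'
#' Maps stick-breaking variables `Q` in `[0,1)^(V-1)` to a length-`V`
#' composition: `beta[i] = Q[i] * prod(1 - Q[l < i])` and the last component
#' absorbs the remaining stick, `beta[V] = prod(1 - Q)`. A zero `Q[i]` yields
#' an exact zero `beta[i]`; the final component is always positive. The map is
#' order-sensitive: positions are taken in the given (taxon) order.
#'
#' @param Q Numeric vector in `[0, 1)`.
#' @return A list of class `"zigd_composition"` with components `beta`
#'   (length `length(Q) + 1`, sums to 1), `delta` (binary, `delta[i] = 1`
#'   exactly when `beta[i] == 0`) and `support` (ascending indices with
#'   `delta == 0`).
#' @export
#' @examples
#' stick_break(c(0.5, 0.5))$beta   # 0.50 0.25 0.25
stick_break <- function(Q) {
  Q <- as.numeric(Q)
  if (any(Q < 0 | Q >= 1)) {
    stop("stick-breaking variables must lie in [0, 1)", call. = FALSE)
  }
  V <- length(Q) + 1L
  remaining <- cumprod(c(1, 1 - Q))
  beta <- c(Q * remaining[-V], remaining[V])
  # exact-zero bookkeeping: a zero Q must give a zero beta (no rounding)
  beta[c(Q == 0, FALSE)] <- 0
  delta <- as.integer(beta == 0)
  structure(
    list(beta = beta, delta = delta, support = which(delta == 0L)),
    class = "zigd_composition"
  )
}

#' Sample from the zero-inflated generalized Dirichlet distribution
#'
#' Draws compositions from the ZIGD: `V - 1` independent zero-inflated
#' `Beta(a, b)` variables pushed through the stick-breaking map. Components
#' `1..V-1` are exactly zero (structural zeros) with marginal probability
#' `pi`; the last component is never zero. With `pi = 0` the draw is a
#' generalized Dirichlet, and with `pi = 0`, `a = eta`,
#' `b[i] = eta * (V - i)` it reduces to a symmetric `Dirichlet(eta)`.
#'
#' @inheritParams rzibeta
#' @param n Number of draws.
#' @return If `n == 1` a `"zigd_composition"` (see [stick_break()]); otherwise
#'   a list with matrices `beta` and `delta` of dimension `n x V`.
#' @export
#' @examples
#' set.seed(1)
#' rzigd(1, V = 10, pi = 0.4, a = 0.05, b = 10)$beta
rzigd <- function(n = 1, V, pi, a, b) {
  check_zigd_params(pi, a, b, V)
  if (n == 1) {
    return(stick_break(rzibeta(V, pi, a, b)))
  }
  draws <- lapply(seq_len(n), function(i) stick_break(rzibeta(V, pi, a, b)))
  list(
    beta = do.call(rbind, lapply(draws, `[[`, "beta")),
    delta = do.call(rbind, lapply(draws, `[[`, "delta"))
  )
}

check_zigd_params <- function(pi, a, b, V) {
  if (!is.numeric(V) || length(V) != 1L || V < 2 || V != round(V)) {
    stop("V must be a single integer >= 2", call. = FALSE)
  }
  for (nm in c("pi", "a", "b")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) < 1L ||
        !(length(x) == 1L || length(x) == V - 1L)) {
      stop(sprintf("%s must be a scalar or length V-1 vector", nm),
           call. = FALSE)
    }
  }
  if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]", call. = FALSE)
  if (any(a <= 0)) stop("a must be positive", call. = FALSE)
  if (any(b <= 0)) stop("b must be positive", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.zigd_composition <- function(x, ...) {
  cat("ZIGD composition of length", length(x$beta), "with",
      sum(x$delta), "structural zeros\n")
  print(x$beta, ...)
  invisible(x)
}

# Symmetric Dirichlet draws via the gamma construction.
rdirichlet <- function(n, alpha, k) {
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n)
  # alpha < 1 can underflow all gammas to 0 in double precision; resample
  bad <- rowSums(g) == 0
  while (any(bad)) {
    g[bad, ] <- matrix(stats::rgamma(sum(bad) * k, shape = alpha),
                       nrow = sum(bad))
    bad <- rowSums(g) == 0
  }
  g / rowSums(g)
}
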