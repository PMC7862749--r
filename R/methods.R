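#' @export
print.zinlda <- function(x, ...) {
  cat("Zero-inflated LDA fit\n")
  cat(sprintf("  %d samples x %d taxa, K = %d subcommunities\n",
              nrow(x$counts), ncol(x$counts), x$hyper$K))
  cat(sprintf("  hyperparameters: alpha = %g, pi = %g, a = %g, b = %g\n",
              x$hyper$alpha, x$hyper$pi, x$hyper$a, x$hyper$b))
  cat(sprintf("  chain: %d iterations (%d burn-in, thin %d, %d retained)\n",
              x$chain$n_iter, x$chain$burn_in, x$chain$thin, x$chain$n_kept))
  cat(sprintf("  structural zeros in beta-hat: %d of %d entries\n",
              sum(x$delta_hat), length(x$delta_hat)))
  invisible(x)
}

#' @export
print.lda_fit <- function(x, ...) {
  cat("LDA fit (collapsed Gibbs)\n")
  cat(sprintf("  %d samples x %d taxa, K = %d subcommunities\n",
              nrow(x$counts), ncol(x$counts), x$hyper$K))
  cat(sprintf("  hyperparameters: alpha = %g, eta = %g\n",
              x$hyper$alpha, x$hyper$eta))
  cat(sprintf("  chain: %d iterations (%d burn-in, thin %d, %d retained)\n",
              x$chain$n_iter, x$chain$burn_in, x$chain$thin, x$chain$n_kept))
  invisible(x)
}

#' Summarise a fitted model's subcommunities
#'
#' Lists, per subcommunity, the leading taxa with their estimated membership
#' probabilities, plus (for the zero-inflated model) the number of
#' structural zeros.
#'
#' @param object A `"zinlda"` or `"lda_fit"` object.
#' @param n_top Number of leading taxa to show per community.
#' @param ... Unused.
#' @export
summary.zinlda <- function(object, n_top = 8, ...) {
  out <- list(top = top_taxa(object$beta, n_top),
              n_structural = rowSums(object$delta_hat),
              loglik = as.numeric(logLik(object)))
  class(out) <- "summary.zinlda"
  out
}

#' @rdname summary.zinlda
#' @export
summary.lda_fit <- function(object, n_top = 8, ...) {
  out <- list(top = top_taxa(object$beta, n_top), n_structural = NULL,
              loglik = as.numeric(logLik(object)))
  class(out) <- "summary.zinlda"
  out
}

#' @export
print.summary.zinlda <- function(x, ...) {
  for (j in seq_along(x$top)) {
    cat(names(x$top)[j])
    if (!is.null(x$n_structural)) {
      cat(sprintf("  (%d structural zeros)", x$n_structural[j]))
    }
    cat("\n")
    print(round(x$top[[j]], 4))
  }
  cat(sprintf("plug-in log-likelihood: %.2f\n", x$loglik))
  invisible(x)
}

top_taxa <- function(beta, n_top) {
  res <- lapply(seq_len(nrow(beta)), function(j) {
    v <- sort(beta[j, ], decreasing = TRUE)
    v[seq_len(min(n_top, length(v)))]
  })
  names(res) <- rownames(beta)
  res
}

#' @export
coef.zinlda <- function(object, ...) object$beta

#' @export
coef.lda_fit <- function(object, ...) object$beta

#' Plug-in log-likelihood of counts under a fitted mixture
#'
#' Total multinomial log-likelihood
#' `sum_{d,i} counts[d,i] * log(sum_j theta[d,j] beta[j,i])` with the point
#' estimates plugged in. If an observed taxon has zero probability under the
#' fit (possible when it is structurally zeroed in every community), the
#' value is `-Inf` and the offending cells are attached as attribute
#' `"zero_cells"`.
#'
#' @param object Fitted `"zinlda"` or `"lda_fit"` model.
#' @param newdata Optional count matrix; defaults to the training counts.
#' @param ... Unused.
#' @return A `"logLik"` object.
#' @export
logLik.zinlda <- function(object, newdata = NULL, ...) {
  mixture_loglik(if (is.null(newdata)) object$counts else newdata,
                 object$theta, object$beta, object$hyper$K)
}

#' @rdname logLik.zinlda
#' @export
logLik.lda_fit <- function(object, newdata = NULL, ...) {
  mixture_loglik(if (is.null(newdata)) object$counts else newdata,
                 object$theta, object$beta, object$hyper$K)
}

mixture_loglik <- function(counts, theta, beta, K) {
  counts <- as_count_matrix(counts)
  stopifnot(nrow(counts) == nrow(theta), ncol(counts) == ncol(beta))
  p <- theta %*% beta
  bad <- which(counts > 0 & p == 0, arr.ind = TRUE)
  ll <- if (nrow(bad)) -Inf else sum(counts[counts > 0] * log(p[counts > 0]))
  val <- structure(ll, df = K * (ncol(beta) - 1) + nrow(theta) * (K - 1),
                   nobs = sum(counts), class = "logLik")
  if (nrow(bad)) attr(val, "zero_cells") <- bad
  val
}

#' Expected taxon proportions per sample
#'
#' @param object Fitted model.
#' @param ... Unused.
#' @return `D x V` matrix `theta %*% beta` of fitted proportions.
#' @export
fitted.zinlda <- function(object, ...) object$theta %*% object$beta

#' @rdname fitted.zinlda
#' @export
fitted.lda_fit <- function(object, ...) object$theta %*% object$beta

#' Raw residuals of observed counts against fitted expectations
#'
#' @param object Fitted model.
#' @param ... Unused.
#' @return `D x V` matrix `counts - depths * fitted`.
#' @export
residuals.zinlda <- function(object, ...) {
  object$counts - object$depths * fitted(object)
}

#' @rdname residuals.zinlda
#' @export
residuals.lda_fit <- function(object, ...) {
  object$counts - object$depths * fitted(object)
}

#' Simulate cohorts from the posterior predictive distribution
#'
#' Each simulated data set selects one retained posterior draw uniformly at
#' random and generates a cohort of the original dimensions from that draw's
#' `(beta, theta)` at the given depths. Requires the fit to have been run
#' with `store_draws = TRUE`.
#'
#' @param object Fitted `"zinlda"` or `"lda_fit"` model.
#' @param nsim Number of simulated data sets.
#' @param seed Optional integer seed.
#' @param depths Per-sample read depths; defaults to the observed depths.
#' @param ... Unused.
#' @return List of `nsim` count matrices (`D x V`).
#' @export
simulate.zinlda <- function(object, nsim = 100, seed = NULL,
                            depths = object$depths, ...) {
  posterior_predictive(object, nsim, seed, depths)
}

#' @rdname simulate.zinlda
#' @export
simulate.lda_fit <- function(object, nsim = 100, seed = NULL,
                             depths = object$depths, ...) {
  posterior_predictive(object, nsim, seed, depths)
}

posterior_predictive <- function(object, nsim, seed, depths) {
  if (is.null(object$draws)) {
    stop("posterior predictive simulation needs store_draws = TRUE",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (nsim == 0) return(list())
  n_draws <- dim(object$draws$beta)[3]
  D <- nrow(object$theta); V <- ncol(object$beta); K <- object$hyper$K
  lapply(seq_len(nsim), function(s) {
    g <- sample.int(n_draws, 1)
    beta <- matrix(object$draws$beta[, , g], K, V)
    theta <- matrix(object$draws$theta[, , g], D, K)
    counts <- matrix(0L, D, V, dimnames = dimnames(object$counts))
    for (d in seq_len(D)) {
      m <- stats::rmultinom(1, depths[d], theta[d, ])[, 1]
      for (j in seq_len(K)) {
        if (m[j] > 0) {
          counts[d, ] <- counts[d, ] + stats::rmultinom(1, m[j], beta[j, ])[, 1]
        }
      }
    }
    counts
  })
}
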