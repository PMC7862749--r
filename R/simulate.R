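#' Simulate subcommunity taxon profiles
#'
#' Draws `K` independent subcommunity profiles. Under `model = "zinlda"` each
#' row is a ZIGD draw (structural zeros possible); under `model = "lda"` each
#' row is a symmetric `Dirichlet(eta)` draw (strictly positive).
#'
#' @param K Number of subcommunities.
#' @param V Number of taxa.
#' @param pi,a,b ZIGD hyperparameters (see [rzigd()]).
#' @param eta Dirichlet concentration for `model = "lda"`.
#' @param model `"zinlda"` or `"lda"`.
#' @return List with `beta` (`K x V`, rows sum to 1) and `delta` (`K x V`
#'   binary, `delta == 1` exactly where `beta == 0`).
#' @export
simulate_profiles <- function(K, V, pi = 0.4, a = 0.05, b = 10, eta = 0.1,
                              model = c("zinlda", "lda")) {
  model <- match.arg(model)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (model == "zinlda") {
    draws <- lapply(seq_len(K), function(j) rzigd(1, V, pi, a, b))
    beta <- do.call(rbind, lapply(draws, `[[`, "beta"))
    delta <- do.call(rbind, lapply(draws, `[[`, "delta"))
  } else {
    beta <- rdirichlet(K, eta, V)
    delta <- matrix(0L, K, V)
  }
  dimnames(beta) <- dimnames(delta) <-
    list(paste0("community_", seq_len(K)), taxon_labels(V))
  list(beta = beta, delta = delta)
}

#' Simulate a cohort of samples from fixed subcommunity profiles
#'
#' Generates a sample-by-taxon count matrix from the two-stage mixture:
#' per-sample depths are discrete-uniform on `[depth_min, depth_max]`
#' (inclusive bounds), mixture weights `theta` are symmetric
#' `Dirichlet(alpha)`, each read picks a subcommunity from `theta` and then a
#' taxon from that subcommunity's profile. Reads are exchangeable, so the
#' draw is realised as nested multinomials (per-sample community totals, then
#' per-community taxon counts), which is exactly equidistributed with a
#' read-by-read loop.
#'
#' @param beta `K x V` matrix of subcommunity profiles, rows on the simplex.
#' @param D Number of samples.
#' @param depth_min,depth_max Inclusive bounds of the per-sample read depth.
#' @param alpha Symmetric Dirichlet concentration on the mixture weights.
#' @return An object of class `"zinlda_sim"`: list with `counts` (`D x V`
#'   integer matrix), `depths`, ground truth `theta` (`D x K`), `beta`,
#'   `delta`, and `z_counts` (`D x K x V` reads by sample/community/taxon).
#' @export
simulate_cohort <- function(beta, D, depth_min = 5000, depth_max = 25000,
                            alpha = 10) {
  if (depth_min > depth_max || depth_min < 1) {
    stop("need 1 <= depth_min <= depth_max", call. = FALSE)
  }
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  beta <- as.matrix(beta)
  K <- nrow(beta); V <- ncol(beta)
  if (any(rowSums(beta) == 0)) {
    stop("degenerate profile: a community row is all zero", call. = FALSE)
  }
  depths <- depth_min - 1L +
    sample.int(depth_max - depth_min + 1L, D, replace = TRUE)
  theta <- rdirichlet(D, alpha, K)
  z_counts <- array(0L, dim = c(D, K, V))
  counts <- matrix(0L, D, V)
  for (d in seq_len(D)) {
    m <- stats::rmultinom(1, depths[d], theta[d, ])[, 1]
    zc <- matrix(0L, K, V)
    for (j in seq_len(K)) {
      if (m[j] > 0) zc[j, ] <- stats::rmultinom(1, m[j], beta[j, ])[, 1]
    }
    z_counts[d, , ] <- zc
    counts[d, ] <- colSums(zc)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_labels(D),
                           colnames(beta) %||% taxon_labels(V))
  delta <- matrix(as.integer(beta == 0), K, V, dimnames = dimnames(beta))
  structure(
    list(counts = counts, depths = depths, theta = theta, beta = beta,
         delta = delta, z_counts = z_counts),
    class = "zinlda_sim"
  )
}

#' Simulate a full cohort from the zinLDA (or LDA) generative process
#'
#' Convenience wrapper drawing subcommunity profiles and then a cohort.
#' The defaults are the reference simulation design for genus-level
#' microbiome data: `V = 120` taxa, `D = 150` samples, depths uniform on
#' `[5000, 25000]`, `K = 5` subcommunities, `alpha = 50/K`, and ZIGD
#' hyperparameters `pi = 0.4`, `a = 0.05`, `b = 10`.
#'
#' @inheritParams simulate_profiles
#' @inheritParams simulate_cohort
#' @param D Number of samples.
#' @param alpha Dirichlet concentration on mixture weights; default `50 / K`.
#' @return A `"zinlda_sim"` object (see [simulate_cohort()]).
#' @export
#' @examples
#' set.seed(7)
#' sim <- simulate_zinlda(D = 20, V = 30, depth_min = 500, depth_max = 1500)
#' dim(sim$counts)
simulate_zinlda <- function(D = 150, V = 120, K = 5, alpha = 50 / K,
                            pi = 0.4, a = 0.05, b = 10,
                            depth_min = 5000, depth_max = 25000,
                            eta = 0.1, model = c("zinlda", "lda")) {
  model <- match.arg(model)
  prof <- simulate_profiles(K, V, pi = pi, a = a, b = b, eta = eta,
                            model = model)
  sim <- simulate_cohort(prof$beta, D, depth_min, depth_max, alpha)
  sim$params <- list(model = model, D = D, V = V, K = K, alpha = alpha,
                     pi = pi, a = a, b = b, eta = eta,
                     depth_min = depth_min, depth_max = depth_max)
  sim
}

#' @export
print.zinlda_sim <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$counts), "samples x", ncol(x$counts),
      "taxa,", nrow(x$beta), "subcommunities\n")
  cat("depths:", min(x$depths), "-", max(x$depths),
      " structural zeros in truth:", sum(x$delta), "\n")
  invisible(x)
}

#' Remove taxa never observed in any sample
#'
#' Drops count-matrix columns whose total over all samples is zero (taxa a
#' real study could never have observed). For simulated cohorts the ground
#' truth is subset to the retained columns without renormalising `beta`:
#' diagnostics compare on the retained support via the recorded index map.
#'
#' @param x A count matrix (samples x taxa) or a `"zinlda_sim"` object.
#' @return Same type as `x`, with attribute `"taxon_map"` giving the original
#'   column indices of the retained taxa.
#' @export
drop_unobserved_taxa <- function(x) {
  counts <- if (inherits(x, "zinlda_sim")) x$counts else x
  keep <- which(colSums(counts) > 0)
  if (length(keep) == 0) stop("all taxa have zero total count", call. = FALSE)
  subset_taxa(x, keep)
}

#' Filter taxa by prevalence, then drop empty samples
#'
#' Removes taxa whose prevalence (fraction of samples with a nonzero count)
#' is strictly below `min_prevalence`, then removes samples whose remaining
#' total count is zero; the taxa step runs first. Boundary prevalences equal
#' to the threshold are retained.
#'
#' @inheritParams drop_unobserved_taxa
#' @param min_prevalence Fraction in `[0, 1]`; default 0.2.
#' @return Same type as `x`, with attributes `"taxon_map"` and
#'   `"sample_map"` (original indices retained).
#' @export
prevalence_filter <- function(x, min_prevalence = 0.2) {
  if (min_prevalence < 0 || min_prevalence > 1) {
    stop("min_prevalence must lie in [0, 1]", call. = FALSE)
  }
  counts <- if (inherits(x, "zinlda_sim")) x$counts else x
  prev <- colMeans(counts > 0)
  keep_taxa <- which(prev >= min_prevalence)
  if (length(keep_taxa) == 0) {
    stop("prevalence filter removed every taxon", call. = FALSE)
  }
  out <- subset_taxa(x, keep_taxa)
  counts <- if (inherits(out, "zinlda_sim")) out$counts else out
  keep_samples <- which(rowSums(counts) > 0)
  if (length(keep_samples) == 0) {
    stop("prevalence filter removed every sample", call. = FALSE)
  }
  out <- subset_samples(out, keep_samples)
  attr(out, "taxon_map") <- keep_taxa
  attr(out, "sample_map") <- keep_samples
  out
}

subset_taxa <- function(x, keep) {
  if (inherits(x, "zinlda_sim")) {
    x$counts <- x$counts[, keep, drop = FALSE]
    x$beta <- x$beta[, keep, drop = FALSE]
    x$delta <- x$delta[, keep, drop = FALSE]
    x$z_counts <- x$z_counts[, , keep, drop = FALSE]
  } else {
    x <- x[, keep, drop = FALSE]
  }
  attr(x, "taxon_map") <- keep
  x
}

subset_samples <- function(x, keep) {
  if (inherits(x, "zinlda_sim")) {
    x$counts <- x$counts[keep, , drop = FALSE]
    x$depths <- x$depths[keep]
    x$theta <- x$theta[keep, , drop = FALSE]
    x$z_counts <- x$z_counts[keep, , , drop = FALSE]
  } else {
    x <- x[keep, , drop = FALSE]
  }
  x
}

taxon_labels <- function(V) sprintf("taxon_%03d", seq_len(V))
sample_labels <- function(D) sprintf("sample_%03d", seq_len(D))

`%||%` <- function(a, b) if (is.null(a)) b else a
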