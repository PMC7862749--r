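#' Match estimated subcommunities to reference subcommunities
#'
#' Resolves label switching by greedy Pearson-correlation matching: the
#' correlation of every reference/estimate row pair is computed, the highest
#' pair is matched, then the highest among the remaining rows, until all `K`
#' pairs are matched. Ties are broken by lowest reference index, then lowest
#' estimate index, so the matching is deterministic. A zero-variance row has
#' undefined correlation; such pairs are treated as having correlation
#' `-Inf` and a warning is issued.
#'
#' @param beta_ref Reference `K x V` profile matrix (e.g. simulation truth).
#' @param beta_est Estimated `K x V` profile matrix.
#' @return Integer permutation `perm` of `1..K`: `perm[k]` is the estimated
#'   community matched to reference community `k`. The correlation matrix is
#'   attached as attribute `"correlations"`.
#' @export
match_communities <- function(beta_ref, beta_est) {
  beta_ref <- as.matrix(beta_ref); beta_est <- as.matrix(beta_est)
  stopifnot(all(dim(beta_ref) == dim(beta_est)))
  K <- nrow(beta_ref)
  cors <- suppressWarnings(stats::cor(t(beta_ref), t(beta_est)))
  if (anyNA(cors)) {
    warning("zero-variance profile row(s): undefined correlations treated ",
            "as -Inf", call. = FALSE)
    cors[is.na(cors)] <- -Inf
  }
  perm <- integer(K)
  work <- cors
  for (step in seq_len(K)) {
    best <- which(work == max(work), arr.ind = TRUE)
    # deterministic tie-break: lowest reference row, then lowest estimate col
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    perm[best[1]] <- best[2]
    work[best[1], ] <- -Inf
    work[, best[2]] <- -Inf
  }
  structure(perm, correlations = cors)
}

#' Structural-zero classification metrics
#'
#' Entry-wise confusion summary of estimated against true structural-zero
#' indicators over all (community, taxon) cells, after aligning the
#' estimated communities to the truth. A positive outcome is a structural
#' zero (`delta = 1`). Undefined ratios (empty denominator) are reported as
#' `NA`, not 0.
#'
#' @param delta_true,delta_est `K x V` binary indicator matrices.
#' @param match Optional permutation from [match_communities()] aligning
#'   estimate rows to truth rows; identity if omitted.
#' @return An object of class `"confusion_summary"`: list with `tp`, `fp`,
#'   `tn`, `fn`, `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
structural_zero_metrics <- function(delta_true, delta_est, match = NULL) {
  delta_true <- as.matrix(delta_true); delta_est <- as.matrix(delta_est)
  if (!is.null(match)) delta_est <- delta_est[match, , drop = FALSE]
  stopifnot(all(dim(delta_true) == dim(delta_est)),
            all(delta_true %in% 0:1), all(delta_est %in% 0:1))
  tp <- sum(delta_true == 1 & delta_est == 1)
  fp <- sum(delta_true == 0 & delta_est == 1)
  tn <- sum(delta_true == 0 & delta_est == 0)
  fn <- sum(delta_true == 1 & delta_est == 0)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = ratio(tp, tp + fn),
         specificity = ratio(tn, tn + fp),
         ppv = ratio(tp, tp + fp),
         npv = ratio(tn, tn + fn)),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("structural-zero confusion: tp %d fp %d tn %d fn %d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("sensitivity %.3f  specificity %.3f  ppv %.3f  npv %.3f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' Posterior predictive check on per-taxon counts
#'
#' Compares observed counts to posterior-predictive replicates via the test
#' statistic `T(X) = X_i.`, the count of taxon `i` in a sample. Within each
#' sample, taxa are ordered by increasing observed count (ties by taxon
#' index); replicate counts are reported in that fixed order together with
#' their per-taxon median across replicates. Counts are reported on the
#' `asinh` scale.
#'
#' @param observed `D x V` count matrix (or `"zinlda_sim"`).
#' @param replicates List of `D x V` count matrices, e.g. from
#'   [simulate.zinlda()].
#' @return An object of class `"zinlda_ppc"`: data frame with columns
#'   `sample`, `rank`, `taxon`, `observed`, `median` (counts) and their
#'   `asinh` transforms, plus attribute `"replicates_asinh"`, a
#'   `D x V x R` array in rank order.
#' @export
ppc_summary <- function(observed, replicates) {
  observed <- as_count_matrix(observed)
  D <- nrow(observed); V <- ncol(observed)
  if (!length(replicates)) stop("no replicates supplied", call. = FALSE)
  ok <- vapply(replicates, function(r) all(dim(r) == c(D, V)), logical(1))
  if (!all(ok)) stop("replicate dimensions do not match observed",
                     call. = FALSE)
  R <- length(replicates)
  rep_arr <- array(0, dim = c(D, V, R))
  med <- matrix(0, D, V)
  obs_sorted <- matrix(0, D, V)
  ord <- matrix(0L, D, V)
  for (d in seq_len(D)) {
    o <- order(observed[d, ], seq_len(V))
    ord[d, ] <- o
    obs_sorted[d, ] <- observed[d, o]
    for (r in seq_len(R)) rep_arr[d, , r] <- replicates[[r]][d, o]
    med[d, ] <- apply(rep_arr[d, , , drop = FALSE], 2, stats::median)
  }
  df <- data.frame(
    sample = rep(rownames(observed), each = V),
    rank = rep(seq_len(V), D),
    taxon = as.vector(t(matrix(colnames(observed)[ord], D, V))),
    observed = as.vector(t(obs_sorted)),
    median = as.vector(t(med))
  )
  df$observed_asinh <- asinh(df$observed)
  df$median_asinh <- asinh(df$median)
  structure(df, replicates_asinh = asinh(rep_arr), class = c("zinlda_ppc",
                                                             "data.frame"))
}

#' Median posterior-predictive count at observed zeros, per sample
#'
#' Summarises over-smoothing: for each sample, the mean of the median
#' replicate counts at positions where the observed count is zero (smaller
#' is better; a well-calibrated sparse fit reproduces observed zeros).
#'
#' @param ppc A `"zinlda_ppc"` object.
#' @return Named numeric vector, one value per sample (`NA` for samples
#'   without observed zeros).
#' @export
ppc_zero_median <- function(ppc) {
  stopifnot(inherits(ppc, "zinlda_ppc"))
  vapply(split(ppc, ppc$sample), function(s) {
    z <- s$median[s$observed == 0]
    if (length(z)) mean(z) else NA_real_
  }, numeric(1))[unique(ppc$sample)]
}

#' Plot a posterior predictive check
#'
#' One panel per selected sample: asinh-transformed observed counts (black
#' line) in increasing order, with the per-taxon replicate medians of one or
#' two fits overlaid, mirroring the usual taxon-count calibration display.
#'
#' @param x A `"zinlda_ppc"` object.
#' @param ppc2 Optional second `"zinlda_ppc"` (e.g. the LDA baseline) to
#'   overlay.
#' @param samples Sample names or indices to plot (default: first 4).
#' @param labels Legend labels for the one or two fits.
#' @param ... Passed to [plot()].
#' @export
plot.zinlda_ppc <- function(x, ppc2 = NULL, samples = NULL,
                            labels = c("fit 1", "fit 2"), ...) {
  ids <- unique(x$sample)
  if (is.null(samples)) samples <- ids[seq_len(min(4, length(ids)))]
  if (is.numeric(samples)) samples <- ids[samples]
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(samples)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (s in samples) {
    xs <- x[x$sample == s, ]
    plot(xs$rank, xs$observed_asinh, type = "l", lwd = 2,
         xlab = "taxa (increasing observed count)", ylab = "asinh(count)",
         main = s, ...)
    graphics::lines(xs$rank, xs$median_asinh, col = "blue", lwd = 2)
    if (!is.null(ppc2)) {
      x2 <- ppc2[ppc2$sample == s, ]
      graphics::lines(x2$rank, x2$median_asinh, col = "deeppink", lwd = 2)
    }
    if (s == samples[1]) {
      graphics::legend("topleft", bty = "n", lwd = 2,
                       col = c("black", "blue", "deeppink")[
                         seq_len(2 + !is.null(ppc2))],
                       legend = c("observed", labels)[
                         seq_len(2 + !is.null(ppc2))])
    }
  }
  invisible(x)
}

#' Plot leading taxa of each fitted subcommunity
#'
#' Bar plot of the `n_top` highest-probability taxa per subcommunity.
#'
#' @param x A `"zinlda"` or `"lda_fit"` object.
#' @param n_top Taxa per community.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.zinlda <- function(x, n_top = 8, ...) {
  top <- top_taxa(x$beta, n_top)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(top)),
                       mar = c(7, 4, 2, 1))
  on.exit(graphics::par(old))
  for (j in seq_along(top)) {
    graphics::barplot(top[[j]], las = 2, ylab = "beta", main = names(top)[j],
                      ...)
  }
  invisible(x)
}

#' @rdname plot.zinlda
#' @export
plot.lda_fit <- plot.zinlda

#' Cross-fit stability of fitted subcommunities
#'
#' Matches the subcommunities of two fits on the same taxon set by greedy
#' Pearson correlation, then reports the average cosine similarity of the
#' matched profile pairs. A pair involving an all-zero row has undefined
#' cosine and is reported as `NA` (and omitted from the average).
#'
#' @param fit_a,fit_b Fitted models (or bare `K x V` profile matrices) on
#'   the same taxa in the same order.
#' @return Average cosine similarity; the per-pair similarities are attached
#'   as attribute `"pairs"` and the matching as `"match"`.
#' @export
stability_cosine <- function(fit_a, fit_b) {
  ba <- if (is.matrix(fit_a)) fit_a else fit_a$beta
  bb <- if (is.matrix(fit_b)) fit_b else fit_b$beta
  stopifnot(all(dim(ba) == dim(bb)))
  perm <- match_communities(ba, bb)
  pairs <- vapply(seq_len(nrow(ba)), function(k) {
    u <- ba[k, ]; v <- bb[perm[k], ]
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) NA_real_ else sum(u * v) / (nu * nv)
  }, numeric(1))
  structure(mean(pairs, na.rm = TRUE), pairs = pairs, match = as.integer(perm))
}
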