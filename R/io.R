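#' Read a sample-by-taxon count matrix
#'
#' Reads a TSV or CSV file whose first column holds sample IDs and whose
#' header row holds taxon IDs. Entries must be nonnegative integers;
#' offending cells are named in the error. Column order is preserved — the
#' ZIGD stick-breaking construction depends on taxon order, which is
#' recorded in fit manifests.
#'
#' @param path File path. Delimiter is inferred from the extension
#'   (`.csv` = comma, otherwise tab) unless `sep` is given.
#' @param sep Optional field separator.
#' @return Integer count matrix with sample row names and taxon column
#'   names; the file's MD5 checksum is attached as attribute `"md5"`.
#' @export
read_counts <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  taxa <- colnames(df)[-1]
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon IDs: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-count entry at sample '%s', taxon '%s'",
                 ids[bad[1, 1]], taxa[bad[1, 2]]), call. = FALSE)
  }
  storage.mode(num) <- "integer"
  dimnames(num) <- list(ids, taxa)
  attr(num, "md5") <- unname(tools::md5sum(path))
  num
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]: first column `sample_id`, header row taxon
#' IDs, tab- (or comma-) separated.
#'
#' @param counts Count matrix (or `"zinlda_sim"`).
#' @param path Output file.
#' @param sep Field separator; inferred from the extension by default.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, sep = NULL) {
  counts <- as_count_matrix(counts)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fitted model to a directory
#'
#' Serialises a fit as plain text: `beta.tsv`, `theta.tsv` and, for the
#' zero-inflated model, `pi.tsv` and `delta_hat.tsv`, plus `manifest.json`
#' recording hyperparameters, chain settings, seed, taxon order and package
#' version, so the run can be reproduced exactly.
#'
#' @param fit A `"zinlda"` or `"lda_fit"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, c("zinlda", "lda_fit")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mat <- function(m, file) {
    utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                       file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_mat(fit$beta, "beta.tsv")
  write_mat(fit$theta, "theta.tsv")
  if (inherits(fit, "zinlda")) {
    write_mat(fit$pi_hat, "pi.tsv")
    write_mat(fit$delta_hat, "delta_hat.tsv")
  }
  manifest <- list(
    model = if (inherits(fit, "zinlda")) "zinlda" else "lda",
    package_version = as.character(utils::packageVersion("zinlda")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    hyperparameters = fit$hyper,
    chain = fit$chain,
    taxon_order = fit$taxon_order,
    input_md5 = attr(fit$counts, "md5")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

#' Write a simulated cohort and its ground truth
#'
#' Writes `counts.tsv` plus a ground-truth sidecar (`theta.tsv`, `beta.tsv`,
#' `delta.tsv`) and a `manifest.json` with the generator parameters.
#'
#' @param sim A `"zinlda_sim"` object.
#' @param dir Output directory.
#' @param seed Optional seed to record in the manifest.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir, seed = NULL) {
  stopifnot(inherits(sim, "zinlda_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  wm <- function(m, file) {
    utils::write.table(m, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  wm(sim$theta, "theta.tsv")
  wm(sim$beta, "beta.tsv")
  wm(sim$delta, "delta.tsv")
  manifest <- c(sim$params,
                list(seed = seed,
                     package_version =
                       as.character(utils::packageVersion("zinlda"))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}
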