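# Count preprocessing: CPM filter, TMM normalization, log2-CPM transform,
# flow-cell residualization, and PC-based outlier screening.

#' Filter lowly expressed genes by CPM
#'
#' Keeps genes with at least `cpm_threshold` counts per million in at least
#' `ceil(sample_fraction * n_samples)` samples.
#'
#' @param counts Genes x samples non-negative integer matrix.
#' @param cpm_threshold CPM cutoff.
#' @param sample_fraction Minimum fraction of samples at or above the cutoff.
#' @return Filtered count matrix.
#' @export
filter_low_expression <- function(counts, cpm_threshold = 1,
                                  sample_fraction = 0.10) {
  check_that(is.matrix(counts) && ncol(counts) >= 2,
             "counts must be a matrix with >= 2 samples")
  check_that(all(counts >= 0) && all(is.finite(counts)),
             "counts must be finite and non-negative")
  lib <- colSums(counts)
  check_that(all(lib > 0), "every sample needs a positive library size")
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  need <- ceiling(sample_fraction * ncol(counts))
  keep <- rowSums(cpm >= cpm_threshold) >= need
  if (!any(keep)) stop("no genes pass the CPM filter", call. = FALSE)
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors: the reference sample is the one
#' whose upper-quartile CPM is closest to the mean upper quartile; each
#' sample's factor is the precision-weighted mean of doubly trimmed
#' log-ratios (M) against the reference, exponentiated; factors are rescaled
#' so their geometric mean is 1. Computed via edgeR.
#'
#' @param counts Filtered count matrix.
#' @param trim_m Fraction of extreme M values trimmed (each tail combined).
#' @param trim_a Fraction of extreme A (abundance) values trimmed.
#' @return Named positive factor vector with geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  check_that(all(colSums(counts) > 0), "positive library sizes required")
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  if (any(!is.finite(f))) {
    warning("non-finite TMM factor(s) reset to 1")
    f[!is.finite(f)] <- 1
    f <- f / exp(mean(log(f)))
  }
  setNames(f, colnames(counts))
}

#' log2-CPM transform on TMM-effective library sizes
#'
#' `log2((count + prior) / (lib * factor + 2 * prior) * 1e6)`; the doubled
#' prior in the denominator keeps values finite and monotone in the count.
#'
#' @param counts Count matrix.
#' @param factors TMM factors (as from [tmm_factors()]).
#' @param prior_count Prior count added to the numerator.
#' @return Genes x samples log2-CPM matrix.
#' @export
log_cpm_transform <- function(counts, factors, prior_count = 0.5) {
  check_that(all(factors > 0), "normalization factors must be positive")
  eff <- colSums(counts) * factors[colnames(counts)]
  check_that(all(eff > 0), "non-positive effective library size")
  log2(sweep(counts + prior_count, 2, eff + 2 * prior_count, "/") * 1e6)
}

#' Residualize expression on batch (flow-cell) covariates
#'
#' Per-gene least squares on batch indicators; groups smaller than
#' `min_group` are merged into a pooled level; collinear columns are dropped
#' by pivoted QR; the per-gene grand mean is added back so the output stays
#' on the log2-CPM scale. Additional categorical covariates (e.g. hardware
#' identifiers) may be supplied as extra columns of a data.frame and are
#' regressed out jointly.
#'
#' @param expr Genes x samples matrix.
#' @param batches Factor/character batch label per sample (named or in
#'   column order), or a data.frame of categorical covariates with samples
#'   as rows.
#' @param min_group Minimum batch size before pooling (applied to the
#'   first covariate).
#' @return Matrix of residuals plus gene means, with a `batch_model`
#'   attribute describing merged/dropped levels.
#' @export
residualize_batch <- function(expr, batches, min_group = 10) {
  samples <- colnames(expr)
  extra <- NULL
  if (is.data.frame(batches)) {
    df <- batches[samples, , drop = FALSE]
    extra <- df[, -1, drop = FALSE]
    batches <- setNames(df[[1]], rownames(df))
  }
  if (!is.null(names(batches))) batches <- batches[samples]
  check_that(length(batches) == ncol(expr) && !any(is.na(batches)),
             "batch labels must cover all samples")
  b <- as.character(batches)
  small <- names(which(table(b) < min_group))
  if (length(small)) b[b %in% small] <- "pooled"
  b <- factor(b)
  if (nlevels(b) < 2 && (is.null(extra) || !ncol(extra))) {
    message("single batch level: residualization is the identity")
    attr(expr, "batch_model") <- list(levels = levels(b), dropped = character())
    return(expr)
  }
  X <- if (nlevels(b) >= 2) model.matrix(~b) else
    matrix(1, length(b), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(extra))
    for (cl in colnames(extra)) {
      f <- factor(extra[[cl]])
      if (nlevels(f) >= 2)
        X <- cbind(X, model.matrix(~f)[, -1, drop = FALSE])
    }
  qrX <- qr(X)
  dropped <- colnames(X)[-seq_len(qrX$rank)]
  X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  fit <- lm.fit(X, t(expr))
  out <- t(fit$residuals) + rowMeans(expr)
  dimnames(out) <- dimnames(expr)
  attr(out, "batch_model") <- list(levels = levels(b),
                                   merged = small, dropped = dropped)
  out
}

#' Remove principal-component outlier samples
#'
#' Samples beyond `sd_threshold` standard deviations on PC1 or PC2 of the
#' sample scores are removed; after removal the data are re-residualized on
#' batch (when given) and screened again, up to `max_iterations` rounds.
#'
#' @param expr Genes x samples matrix.
#' @param sd_threshold SD cutoff on each of PC1/PC2.
#' @param max_iterations Screening rounds.
#' @param batches Optional batch labels for re-correction between rounds.
#' @param min_group Passed to [residualize_batch()].
#' @return List with `matrix` and `removed` (sample ids).
#' @export
remove_pc_outliers <- function(expr, sd_threshold = 3, max_iterations = 2,
                               batches = NULL, min_group = 10) {
  check_that(ncol(expr) >= 10, "need >= 10 samples for outlier screening")
  removed <- character()
  cur <- expr
  for (it in seq_len(max_iterations)) {
    pc <- prcomp(t(cur), center = TRUE, scale. = FALSE, rank. = 2)
    sco <- pc$x
    out <- abs(sco[, 1]) > sd_threshold * sd(sco[, 1]) |
      abs(sco[, 2]) > sd_threshold * sd(sco[, 2])
    if (!any(out)) break
    removed <- c(removed, colnames(cur)[out])
    if (length(removed) > 0.2 * ncol(expr))
      stop(sprintf("PC outlier screen flagged %d of %d samples; input looks degenerate",
                   length(removed), ncol(expr)), call. = FALSE)
    cur <- cur[, !out, drop = FALSE]
    if (!is.null(batches))
      cur <- residualize_batch(cur, batches[colnames(cur)], min_group)
  }
  list(matrix = cur, removed = removed)
}

#' Full count-preprocessing pipeline
#'
#' CPM filter -> TMM -> log2-CPM -> batch residualization -> PC outlier
#' removal with one re-correction.
#'
#' @param counts Genes x samples integer counts.
#' @param batches Sample batch labels (optional).
#' @param cpm_threshold,sample_fraction,prior_count,sd_threshold,min_group
#'   Stage parameters.
#' @return A `NormalizedExpression` object: list with `matrix`,
#'   `tmm_factors`, `kept_genes`, `kept_samples`, `removed_outliers`,
#'   `batch_model`.
#' @export
preprocess_counts <- function(counts, batches = NULL, cpm_threshold = 1,
                              sample_fraction = 0.10, prior_count = 0.5,
                              sd_threshold = 3, min_group = 10) {
  filt <- filter_low_expression(counts, cpm_threshold, sample_fraction)
  f <- tmm_factors(filt)
  lc <- log_cpm_transform(filt, f, prior_count)
  bm <- NULL
  if (!is.null(batches)) {
    lc <- residualize_batch(lc, batches, min_group)
    bm <- attr(lc, "batch_model")
  }
  scr <- remove_pc_outliers(lc, sd_threshold, max_iterations = 2,
                            batches = batches, min_group = min_group)
  out <- list(matrix = scr$matrix,
              tmm_factors = f,
              kept_genes = rownames(filt),
              kept_samples = colnames(scr$matrix),
              removed_outliers = scr$removed,
              batch_model = bm)
  class(out) <- "NormalizedExpression"
  out
}

#' @export
print.NormalizedExpression <- function(x, ...) {
  cat(sprintf("NormalizedExpression: %d genes x %d samples (%d outlier(s) removed)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$removed_outliers)))
  invisible(x)
}
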