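# Trait-correlated differential-expression signatures and Fisher
# enrichment of gene sets against functional annotation.

#' Associate expression with a clinical trait
#'
#' Per-gene ordinary least squares of normalized expression on the trait
#' (plus optional covariates), two-sided t test on the trait coefficient,
#' Benjamini-Hochberg correction across genes. Samples with a missing trait
#' value are dropped.
#'
#' @param expr Genes x samples normalized matrix, or a
#'   `NormalizedExpression`.
#' @param trait Numeric (or 0/1 coded) trait vector named by sample or in
#'   column order.
#' @param covariates Optional numeric matrix/data.frame of per-sample
#'   covariates.
#' @param fdr Signature q-value threshold.
#' @param trait_name Label used in messages and output.
#' @return A `SignatureResult`: list with `table` (gene, beta, t, p, q,
#'   direction), `signature` (genes with q <= fdr), `trait`, `n`.
#' @export
associate_trait <- function(expr, trait, covariates = NULL, fdr = 0.05,
                            trait_name = deparse(substitute(trait))) {
  if (inherits(expr, "NormalizedExpression")) expr <- expr$matrix
  if (!is.null(names(trait))) trait <- trait[colnames(expr)]
  keep <- !is.na(trait)
  check_that(sum(keep) >= 20,
             sprintf("trait '%s' has fewer than 20 non-missing values", trait_name))
  y <- trait[keep]
  if (sd(y) == 0)
    stop(sprintf("trait '%s' is constant", trait_name), call. = FALSE)
  E <- expr[, keep, drop = FALSE]
  X <- matrix(1, nrow = length(y), ncol = 1,
              dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)[keep, , drop = FALSE]
    X <- cbind(X, cv)
  }
  X <- cbind(X, trait = y)
  fit <- lm.fit(X, t(E))
  cf <- if (is.matrix(fit$coefficients)) fit$coefficients else
    matrix(fit$coefficients, ncol = 1)
  beta <- cf["trait", ]
  df <- nrow(X) - ncol(X)
  rss <- colSums(as.matrix(fit$residuals)^2)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  v_trait <- xtx_inv[ncol(X), ncol(X)]
  se <- sqrt(rss / df * v_trait)
  tstat <- beta / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  tab <- data.frame(gene = rownames(E), beta = beta, t = tstat, p = p,
                    q = q, direction = sign(beta), row.names = NULL,
                    stringsAsFactors = FALSE)
  res <- list(trait = trait_name, table = tab,
              signature = tab$gene[tab$q <= fdr], fdr = fdr, n = sum(keep))
  class(res) <- "SignatureResult"
  res
}

#' @export
print.SignatureResult <- function(x, ...) {
  cat(sprintf("Signature for '%s': %d of %d genes at FDR <= %g (n = %d)\n",
              x$trait, length(x$signature), nrow(x$table), x$fdr, x$n))
  invisible(x)
}

#' z-normalize a metabolite matrix
#'
#' Per-metabolite (row) mean 0, SD 1; zero-variance metabolites are dropped
#' with a warning.
#'
#' @param metabolites Metabolites x samples matrix.
#' @return z-scored matrix.
#' @export
znormalize_metabolites <- function(metabolites) {
  sds <- apply(metabolites, 1, sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance metabolite(s)", sum(sds == 0)))
    metabolites <- metabolites[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (metabolites - rowMeans(metabolites)) / sds
}

#' Read gene sets from a GMT file
#' @param path GMT path (name, description, tab-separated genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Fisher enrichment of a foreground gene set against annotation categories
#'
#' One-tailed (enrichment) exact p per category via the hypergeometric tail,
#' BH correction across categories, fold enrichment
#' `(fg_in / |fg|) / (bg_in / |bg|)`.
#'
#' @param foreground Gene set of interest (must be a subset of background).
#' @param background Universe gene set.
#' @param annotation Named list of category gene sets (e.g. from
#'   [read_gmt()]); genes outside the background are ignored.
#' @return Data frame: category, overlap, fg_size, cat_size, bg_size,
#'   fold_enrichment, odds_ratio, p, q.
#' @export
fisher_enrichment <- function(foreground, background, annotation) {
  foreground <- unique(foreground)
  background <- unique(background)
  check_that(all(foreground %in% background),
             "foreground must be a subset of background")
  n_bg <- length(background)
  n_fg <- length(foreground)
  rows <- lapply(names(annotation), function(cat) {
    members <- intersect(annotation[[cat]], background)
    k <- length(intersect(members, foreground))
    m <- length(members)
    fe <- if (m == 0 || n_fg == 0) 0 else (k / n_fg) / (m / n_bg)
    data.frame(category = cat, overlap = k, fg_size = n_fg, cat_size = m,
               bg_size = n_bg,
               fold_enrichment = fe,
               odds_ratio = odds_ratio(k, n_fg - k, m - k,
                                       n_bg - n_fg - m + k),
               p = if (m == 0) 1 else hyper_p(k, n_fg, m, n_bg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}

#' Overlap statistics between gene sets
#'
#' Pairwise one-tailed Fisher tests of set overlap within a universe, plus
#' the count of genes shared across all sets.
#'
#' @param sets Named list of gene sets.
#' @param universe Universe gene set (all sets must be subsets).
#' @return List with `pairwise` (data frame: set_a, set_b, overlap,
#'   odds_ratio, p, q) and `shared_all` (character vector).
#' @export
signature_overlap <- function(sets, universe) {
  check_that(length(universe) > 0, "empty universe")
  check_that(all(vapply(sets, function(s) all(s %in% universe), TRUE)),
             "all sets must be subsets of the universe")
  N <- length(unique(universe))
  nm <- names(sets)
  pairs <- if (length(sets) >= 2) utils::combn(seq_along(sets), 2) else
    matrix(numeric(0), nrow = 2)
  rows <- apply(pairs, 2, function(ij) {
    a <- unique(sets[[ij[1]]]); b <- unique(sets[[ij[2]]])
    k <- length(intersect(a, b))
    data.frame(set_a = nm[ij[1]], set_b = nm[ij[2]], overlap = k,
               odds_ratio = odds_ratio(k, length(a) - k, length(b) - k,
                                       N - length(a) - length(b) + k),
               p = hyper_p(k, length(a), length(b), N),
               stringsAsFactors = FALSE)
  })
  pw <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set_a = character(), set_b = character(), overlap = integer(),
               odds_ratio = numeric(), p = numeric())
  if (nrow(pw)) pw$q <- p.adjust(pw$p, method = "BH")
  list(pairwise = pw, shared_all = Reduce(intersect, sets))
}
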