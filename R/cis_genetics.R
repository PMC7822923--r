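# cis-eQTL mapping and SNP-gene-metabolite trio assembly.

#' Read genotype dosages from a VCF (GT field) or a dosage TSV
#'
#' VCF files are parsed with vcfR and diploid GT calls converted to
#' alternate-allele dosage counts; a dosage TSV is expected variants x
#' samples with a leading variant-id column (as written by
#' [write_cohort()]).
#'
#' @param path File path (`.vcf` / `.vcf.gz` or TSV).
#' @return Samples x variants integer dosage matrix.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, 2, function(g) {
      alleles <- strsplit(g, "[/|]")
      vapply(alleles, function(a) sum(a == "1"), 0L)
    })
    rownames(dos) <- rownames(gt)
    t(dos)
  } else {
    dos <- read_matrix_tsv(path)  # variants x samples
    out <- t(dos)
    storage.mode(out) <- "integer"
    out
  }
}

#' Map cis-eQTLs
#'
#' For every gene, dosages of variants within `window_bp` of the gene
#' position are regressed on expression after both sides are residualized
#' on the top `n_expr_pcs` expression principal components (standing in for
#' latent-factor covariates). Within-gene multiplicity is handled by
#' Bonferroni over the tested cis variants; BH is then applied across genes
#' on the per-gene minimum corrected p. The most significant variant per
#' gene is its top eSNP. With `n_expr_pcs = "auto"` the covariate count is
#' chosen, as in surrogate-variable practice, as the number of PCs (0 to
#' `max_expr_pcs`) at which cis-eQTL discovery is maximal -- guarding
#' against factors that absorb broad biological signal rather than
#' technical structure.
#'
#' @param expr Genes x samples normalized matrix or `NormalizedExpression`.
#' @param genotypes Samples x variants dosage matrix (values in \[0, 2\]).
#' @param gene_map Data frame: gene, chrom, pos.
#' @param variant_map Data frame: variant, chrom, pos.
#' @param window_bp cis window half-width.
#' @param n_expr_pcs Number of expression PC covariates, or `"auto"`.
#' @param max_expr_pcs Candidate ceiling for `"auto"`.
#' @param fdr Gene-level FDR threshold.
#' @return An `EqtlResult`: list with `pairs` (gene, variant, beta, se, t,
#'   p), `genes` (gene, top_esnp, beta, p, p_bonf, q, n_cis, significant),
#'   `fdr`, `n_expr_pcs`.
#' @export
map_cis_eqtl <- function(expr, genotypes, gene_map, variant_map,
                         window_bp = 1e6, n_expr_pcs = 7,
                         max_expr_pcs = 7, fdr = 0.05) {
  if (inherits(expr, "NormalizedExpression")) expr <- expr$matrix
  if (identical(n_expr_pcs, "auto")) {
    fits <- lapply(0:max_expr_pcs, function(k)
      map_cis_eqtl(expr, genotypes, gene_map, variant_map, window_bp,
                   n_expr_pcs = k, fdr = fdr))
    n_sig <- vapply(fits, function(f) sum(f$genes$significant), 1L)
    return(fits[[which.max(n_sig)]])
  }
  samples <- intersect(colnames(expr), rownames(genotypes))
  check_that(length(samples) >= 30, "need >= 30 shared samples")
  E <- expr[, samples, drop = FALSE]
  Gt <- genotypes[samples, , drop = FALSE]
  check_that(all(Gt >= 0 & Gt <= 2), "dosages must lie in [0, 2]")

  n_expr_pcs <- min(n_expr_pcs, ncol(E) - 3, nrow(E) - 1)
  X <- matrix(1, nrow = length(samples), ncol = 1)
  if (n_expr_pcs > 0)
    X <- cbind(X, prcomp(t(E), center = TRUE, scale. = FALSE,
                         rank. = n_expr_pcs)$x)
  # residualize expression and dosage on the covariate space once
  P <- X %*% chol2inv(chol(crossprod(X))) %*% t(X)
  Er <- E - E %*% t(P)
  poly <- apply(Gt, 2, sd) > 0
  if (any(!poly)) message(sprintf("skipping %d monomorphic variant(s)",
                                  sum(!poly)))
  Gr <- Gt[, poly, drop = FALSE] - P %*% Gt[, poly, drop = FALSE]

  df <- length(samples) - ncol(X) - 1
  pair_rows <- list(); gene_rows <- list()
  for (i in seq_len(nrow(gene_map))) {
    gene <- gene_map$gene[i]
    if (!gene %in% rownames(Er)) next
    cis <- variant_map$variant[variant_map$chrom == gene_map$chrom[i] &
                                 abs(variant_map$pos - gene_map$pos[i]) <= window_bp]
    cis <- intersect(cis, colnames(Gr))
    if (!length(cis)) next
    y <- Er[gene, ]
    Xc <- Gr[, cis, drop = FALSE]
    sxx <- colSums(Xc^2)
    sxy <- as.numeric(crossprod(Xc, y))
    beta <- sxy / sxx
    rss <- sum(y^2) - beta * sxy
    se <- sqrt(pmax(rss, 0) / df / sxx)
    tstat <- beta / se
    p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
    pair_rows[[gene]] <- data.frame(gene = gene, variant = cis, beta = beta,
                                    se = se, t = tstat, p = p,
                                    row.names = NULL, stringsAsFactors = FALSE)
    best <- which.min(p)
    gene_rows[[gene]] <- data.frame(gene = gene, top_esnp = cis[best],
                                    beta = beta[best], p = p[best],
                                    p_bonf = min(1, p[best] * length(cis)),
                                    n_cis = length(cis),
                                    stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)
  if (is.null(genes)) stop("no gene had a testable cis variant", call. = FALSE)
  genes$q <- p.adjust(genes$p_bonf, method = "BH")
  genes$significant <- genes$q <= fdr
  res <- list(pairs = do.call(rbind, pair_rows), genes = genes, fdr = fdr,
              n_expr_pcs = n_expr_pcs, window_bp = window_bp)
  class(res) <- "EqtlResult"
  res
}

#' @export
print.EqtlResult <- function(x, ...) {
  cat(sprintf("cis-eQTL scan: %d genes tested, %d significant at FDR <= %g\n",
              nrow(x$genes), sum(x$genes$significant), x$fdr))
  invisible(x)
}

#' Assemble SNP-gene-metabolite trio candidates
#'
#' For each FDR-significant eQTL gene, its top eSNP is tested against every
#' metabolite (linear model, BH across the whole SNP x metabolite family);
#' surviving pairs are joined with a gene-metabolite Pearson correlation
#' screen (BH across tested pairs). A trio is emitted when all three
#' pairwise associations pass.
#'
#' @param eqtl An `EqtlResult`.
#' @param metabolites Metabolites x samples matrix (z-normalized or raw).
#' @param expr Genes x samples normalized matrix or `NormalizedExpression`.
#' @param genotypes Samples x variants dosage matrix.
#' @param fdr FDR for the SNP-metabolite screen.
#' @param gene_met_fdr FDR for the gene-metabolite correlation screen.
#' @return Data frame of trios: variant, gene, metabolite,
#'   snp_metabolite_q, gene_metabolite_r, gene_metabolite_q.
#' @export
assemble_trios <- function(eqtl, metabolites, expr, genotypes, fdr = 0.05,
                           gene_met_fdr = 0.05) {
  if (inherits(expr, "NormalizedExpression")) expr <- expr$matrix
  sig <- eqtl$genes[eqtl$genes$significant, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(variant = character(), gene = character(),
                      metabolite = character()))
  samples <- Reduce(intersect, list(colnames(expr), rownames(genotypes),
                                    colnames(metabolites)))
  M <- metabolites[, samples, drop = FALSE]

  sm <- do.call(rbind, lapply(seq_len(nrow(sig)), function(i) {
    d <- genotypes[samples, sig$top_esnp[i]]
    ps <- apply(M, 1, function(m) {
      ct <- suppressWarnings(cor.test(d, m))
      ct$p.value
    })
    data.frame(gene = sig$gene[i], variant = sig$top_esnp[i],
               metabolite = rownames(M), p_sm = ps, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  sm$q_sm <- p.adjust(sm$p_sm, method = "BH")
  sm <- sm[sm$q_sm <= fdr, , drop = FALSE]
  if (!nrow(sm))
    return(data.frame(variant = character(), gene = character(),
                      metabolite = character()))

  gm <- t(mapply(function(g, m) {
    ct <- suppressWarnings(cor.test(expr[g, samples], M[m, ]))
    c(r = unname(ct$estimate), p = ct$p.value)
  }, sm$gene, sm$metabolite))
  sm$gene_metabolite_r <- gm[, "r"]
  sm$p_gm <- gm[, "p"]
  sm$q_gm <- p.adjust(sm$p_gm, method = "BH")
  out <- sm[sm$q_gm <= gene_met_fdr,
            c("variant", "gene", "metabolite", "q_sm",
              "gene_metabolite_r", "q_gm")]
  names(out)[c(4, 6)] <- c("snp_metabolite_q", "gene_metabolite_q")
  rownames(out) <- NULL
  out
}
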