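# Causal inference test on instrument-mediator-outcome trios and the
# causal-vs-reactive direction call that produces prior edges for the
# multiscale network.

# Two-sided p for the last coefficient of y ~ X (with intercept).
ols_coef_p <- function(y, X) {
  X <- cbind(1, X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    # the tested column is collinear with the others: zero partial effect
    return(list(beta = 0, p = 1, se = NA_real_))
  }
  cf <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qx$qr[seq_len(ncol(X)), , drop = FALSE])
  se <- sqrt(sigma2 * xtx_inv[ncol(X), ncol(X)])
  beta <- cf[ncol(X)]
  if (se == 0)
    return(list(beta = unname(beta),
                p = if (abs(beta) < 1e-12) 1 else 0, se = 0))
  tval <- beta / se
  list(beta = unname(beta), p = 2 * pt(abs(tval), df, lower.tail = FALSE),
       se = unname(se))
}

#' Causal inference test for one direction (L -> G -> T)
#'
#' Intersection-union test with four component p-values:
#' \enumerate{
#'   \item association of instrument and outcome (`T ~ L`);
#'   \item association of instrument and mediator given the outcome
#'     (`G ~ L + T`, coefficient of L);
#'   \item association of mediator and outcome given the instrument
#'     (`T ~ G + L`, coefficient of G);
#'   \item an equivalence-style test that the outcome is independent of the
#'     instrument given the mediator: the observed L coefficient in
#'     `T ~ L + G` is compared against draws obtained by permuting L within
#'     mediator strata and shifted by the residual-dependence margin the
#'     reactive model would leave behind
#'     (`|beta_marginal| * (1 - cor(G, T)^2)`); the resulting p is small
#'     only when the observed coefficient is consistent with conditional
#'     independence.
#' }
#' The omnibus p is the maximum of the four.
#'
#' @param L Instrument (dosage) vector.
#' @param G Candidate mediator vector.
#' @param T_ Candidate outcome vector.
#' @param n_perm Number of within-stratum permutations (>= 20).
#' @param n_strata Mediator quantile strata for the permutation.
#' @param seed Integer seed for the permutations.
#' @return List with `p_omnibus` and `components` (p1..p4).
#' @export
cit_test <- function(L, G, T_, n_perm = 100, n_strata = 10, seed = 1L) {
  check_that(n_perm >= 20, "n_perm must be >= 20")
  ok <- complete.cases(L, G, T_)
  check_that(sum(ok) >= 30, "need >= 30 aligned observations")
  L <- L[ok]; G <- G[ok]; T_ <- T_[ok]
  check_that(sd(G) > 0 && sd(T_) > 0, "constant mediator or outcome")

  p1 <- ols_coef_p(T_, cbind(L))$p
  p2 <- ols_coef_p(G, cbind(T_, L))$p
  p3 <- ols_coef_p(T_, cbind(L, G))$p  # last column (G) tested

  fit_obs <- ols_coef_p(T_, cbind(G, L))  # coefficient of L given G
  beta_obs <- fit_obs$beta
  beta_marg <- ols_coef_p(T_, cbind(L))$beta
  r_gt <- suppressWarnings(cor(G, T_))
  if (is.na(r_gt)) r_gt <- 0
  delta <- abs(beta_marg) * (1 - r_gt^2)

  resid_sd <- sd(lm.fit(cbind(1, G), T_)$residuals)
  if (resid_sd < 1e-10 * sd(T_)) {
    # the mediator explains the outcome exactly: conditional independence
    # of instrument and outcome holds by construction
    p4 <- 1 / (n_perm + 1)
  } else {
    # strata on the mediator; permuting L within strata preserves the L-G
    # association structure while enforcing L independent of T given G
    strata <- cut(rank(G, ties.method = "first"),
                  breaks = n_strata, labels = FALSE)
    set.seed(seed)
    idx <- split(seq_along(G), strata)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      Lp <- L
      for (s in idx) Lp[s] <- L[sample(s)]
      beta_b <- ols_coef_p(T_, cbind(G, Lp))$beta
      if (abs(beta_obs) > abs(delta + beta_b)) exceed <- exceed + 1L
    }
    p4 <- (1 + exceed) / (n_perm + 1)
  }

  comp <- c(p1 = unname(p1), p2 = unname(p2), p3 = unname(p3),
            p4 = unname(p4))
  list(p_omnibus = max(comp), components = comp)
}

#' Run the CIT in both directions over a trio table
#'
#' For each trio, `p_causal` tests SNP -> gene -> metabolite and
#' `p_reactive` tests SNP -> metabolite -> gene (the same function with the
#' mediator and outcome roles swapped); BH is applied over trios separately
#' per direction.
#'
#' @param trios Data frame with columns variant, gene, metabolite.
#' @param genotypes Samples x variants dosage matrix.
#' @param expr Genes x samples normalized matrix or `NormalizedExpression`.
#' @param metabolites Metabolites x samples matrix.
#' @param n_perm,n_strata Passed to [cit_test()].
#' @param seed Run seed (each trio gets a derived sub-seed).
#' @param fdr FDR for the direction call.
#' @param reactive_alpha Raw-p threshold for "the other direction is not
#'   significant".
#' @return A `CitResult` data frame: trio columns plus p_causal,
#'   p_reactive, q_causal, q_reactive, call.
#' @export
run_cit <- function(trios, genotypes, expr, metabolites, n_perm = 100,
                    n_strata = 10, seed = 1L, fdr = 0.05,
                    reactive_alpha = 0.05) {
  if (inherits(expr, "NormalizedExpression")) expr <- expr$matrix
  if (!nrow(trios)) {
    trios$p_causal <- numeric(); trios$p_reactive <- numeric()
    trios$q_causal <- numeric(); trios$q_reactive <- numeric()
    trios$call <- character()
    return(trios)
  }
  samples <- Reduce(intersect, list(colnames(expr), rownames(genotypes),
                                    colnames(metabolites)))
  res <- t(vapply(seq_len(nrow(trios)), function(i) {
    L <- genotypes[samples, trios$variant[i]]
    G <- expr[trios$gene[i], samples]
    M <- metabolites[trios$metabolite[i], samples]
    s <- stage_seed(seed, paste0("cit", i))
    c(p_causal = cit_test(L, G, M, n_perm, n_strata, seed = s)$p_omnibus,
      p_reactive = cit_test(L, M, G, n_perm, n_strata, seed = s)$p_omnibus)
  }, c(p_causal = 0, p_reactive = 0)))
  out <- cbind(trios, res)
  out$q_causal <- p.adjust(out$p_causal, method = "BH")
  out$q_reactive <- p.adjust(out$p_reactive, method = "BH")
  out$call <- mapply(call_direction, out$p_causal, out$p_reactive,
                     out$q_causal, out$q_reactive,
                     MoreArgs = list(fdr = fdr,
                                     reactive_alpha = reactive_alpha))
  class(out) <- c("CitResult", class(out))
  out
}

#' Direction call from the causal and reactive omnibus p-values
#'
#' `gene -> metabolite` when the causal omnibus survives multiple testing
#' and the reactive omnibus is not significant (raw p); the mirrored rule
#' gives `metabolite -> gene`; both significant is `ambiguous`; neither is
#' `none`.
#'
#' @param p_causal,p_reactive Raw omnibus p-values.
#' @param q_causal,q_reactive BH-adjusted omnibus p-values (over trios).
#' @param fdr FDR threshold on q.
#' @param reactive_alpha Raw threshold for non-significance of the other
#'   direction.
#' @return One of "gene->metabolite", "metabolite->gene", "ambiguous",
#'   "none".
#' @export
call_direction <- function(p_causal, p_reactive, q_causal, q_reactive,
                           fdr = 0.05, reactive_alpha = 0.05) {
  causal_sig <- q_causal <= fdr
  reactive_sig <- q_reactive <= fdr
  if (causal_sig && reactive_sig) return("ambiguous")
  if (causal_sig && p_reactive > reactive_alpha) return("gene->metabolite")
  if (reactive_sig && p_causal > reactive_alpha) return("metabolite->gene")
  "none"
}

#' Collect deduplicated directed prior edges from CIT calls
#'
#' Trios with a directional call are reduced to unique (source, target)
#' edges; a gene-metabolite pair with conflicting calls across trios is
#' dropped with a warning.
#'
#' @param cit A `CitResult` (or data frame with gene, metabolite, call).
#' @return Data frame: from, to, direction.
#' @export
collect_prior_edges <- function(cit) {
  called <- cit[cit$call %in% c("gene->metabolite", "metabolite->gene"), ,
                drop = FALSE]
  if (!nrow(called))
    return(data.frame(from = character(), to = character(),
                      direction = character()))
  key <- paste(called$gene, called$metabolite)
  conflict <- tapply(called$call, key, function(x) length(unique(x)) > 1)
  if (any(conflict)) {
    warning(sprintf("dropping %d gene-metabolite pair(s) with conflicting calls",
                    sum(conflict)))
    called <- called[!conflict[key], , drop = FALSE]
  }
  uniq <- unique(called[, c("gene", "metabolite", "call")])
  data.frame(
    from = ifelse(uniq$call == "gene->metabolite", uniq$gene, uniq$metabolite),
    to = ifelse(uniq$call == "gene->metabolite", uniq$metabolite, uniq$gene),
    direction = uniq$call, stringsAsFactors = FALSE)
}
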