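# Weighted coexpression modules: soft-threshold selection, topological
# overlap, tree-cut module detection, eigengenes, trait correlation, the
# inverse lipid/glucose sign rule, and split-cohort module conservation.

#' Unsigned soft-thresholded adjacency
#' @param expr Genes x samples matrix.
#' @param power Soft-thresholding power.
#' @return Genes x genes adjacency `|cor|^power` with zero diagonal.
#' @export
soft_adjacency <- function(expr, power) {
  a <- abs(cor(t(expr)))^power
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal, where `k` is node connectivity.
#'
#' @param adjacency Symmetric adjacency with zero diagonal.
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(adjacency) {
  k <- rowSums(adjacency)
  shared <- adjacency %*% adjacency
  kmin <- outer(k, k, pmin)
  tom <- (shared + adjacency) / (kmin + 1 - adjacency)
  diag(tom) <- 1
  tom
}

#' Choose the soft-thresholding power by scale-free topology fit
#'
#' For each candidate power the connectivity distribution is binned
#' (log-log) and the model R-squared of `log10(freq) ~ log10(k)` with a
#' negative slope is the fit index; the smallest power reaching
#' `target_rsq` is selected, falling back to 5 when none qualifies.
#'
#' @param expr Genes x samples matrix.
#' @param powers Candidate powers.
#' @param target_rsq Required scale-free fit.
#' @param n_bins Connectivity histogram bins (>= 8 used).
#' @return List with `power`, `fit_table` (power, rsq, slope), `fallback`.
#' @export
pick_soft_power <- function(expr, powers = 1:20, target_rsq = 0.8,
                            n_bins = 10) {
  check_that(nrow(expr) >= 3, "need >= 3 genes")
  if (ncol(expr) < 20)
    warning("fewer than 20 samples: soft-power fit may be unstable")
  ac <- abs(cor(t(expr)))
  diag(ac) <- 0
  fits <- t(vapply(powers, function(p) {
    k <- rowSums(ac^p)
    k <- k[k > 0]
    if (length(unique(k)) < 3) return(c(rsq = 0, slope = 0))
    br <- seq(min(k), max(k), length.out = n_bins + 1)  # equal-width bins
    if (length(unique(br)) < 4) return(c(rsq = 0, slope = 0))
    bins <- cut(k, breaks = br, include.lowest = TRUE)
    freq <- tapply(k, bins, length)
    kmean <- tapply(k, bins, mean)
    ok <- !is.na(freq) & freq > 0 & kmean > 0
    if (sum(ok) < 3) return(c(rsq = 0, slope = 0))
    fit <- lm(log10(freq[ok]) ~ log10(kmean[ok]))
    # degenerate bins can produce an exact fit; the summary warning is noise
    rsq <- suppressWarnings(summary(fit)$r.squared)
    c(rsq = rsq, slope = unname(coef(fit)[2]))
  }, c(rsq = 0, slope = 0)))
  ft <- data.frame(power = powers, rsq = fits[, "rsq"],
                   slope = fits[, "slope"])
  ft$rsq[ft$slope >= 0] <- 0  # scale-free requires a decreasing fit
  hit <- which(ft$rsq >= target_rsq)
  if (length(hit)) {
    list(power = powers[hit[1]], fit_table = ft, fallback = FALSE)
  } else {
    message("no candidate power reached the scale-free target; using 5")
    list(power = 5, fit_table = ft, fallback = TRUE)
  }
}

#' Detect coexpression modules by tree cut on the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on `1 - TOM`; the tree is cut at
#' `cut_height` and clusters smaller than `min_module_size` are assigned to
#' "grey" (unassigned). Constant genes are sent to grey up front (their
#' correlations are undefined).
#'
#' @param expr Genes x samples matrix.
#' @param power Soft power (e.g. from [pick_soft_power()]).
#' @param min_module_size Minimum module size.
#' @param cut_height Static cut height on the 1 - TOM scale.
#' @return A `ModuleSet`: list with `assignment` (gene -> label, "grey" =
#'   unassigned), `modules`, `eigengenes`, `variance_explained`,
#'   `dendrogram`, `soft_power`.
#' @export
detect_modules <- function(expr, power = 6, min_module_size = 30,
                           cut_height = 0.99) {
  check_that(!anyNA(expr), "expression matrix must have no missing values")
  sds <- apply(expr, 1, sd)
  if (any(sds == 0))
    warning(sprintf("%d constant gene(s) assigned to grey", sum(sds == 0)))
  use <- rownames(expr)[sds > 0]
  adj <- soft_adjacency(expr[use, , drop = FALSE], power)
  tom <- tom_similarity(adj)
  diss <- 1 - tom
  hc <- hclust(as.dist(diss), method = "average")
  cl <- cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep_cl <- names(sizes)[sizes >= min_module_size]
  assignment <- setNames(rep("grey", nrow(expr)), rownames(expr))
  if (length(keep_cl)) {
    ord <- keep_cl[order(-sizes[keep_cl])]
    for (i in seq_along(ord))
      assignment[use[cl == as.integer(ord[i])]] <- paste0("M", i)
  }
  ms <- build_module_set(expr, assignment)
  ms$soft_power <- power
  ms$dendrogram <- hc
  ms
}

# Assemble eigengenes and variance explained for a given assignment.
build_module_set <- function(expr, assignment) {
  modules <- setdiff(unique(assignment), "grey")
  eig <- list(); ve <- numeric()
  for (m in modules) {
    genes <- names(assignment)[assignment == m]
    e <- module_eigengene(expr, genes)
    eig[[m]] <- e$score
    ve[m] <- e$variance_explained
  }
  out <- list(assignment = assignment, modules = modules,
              eigengenes = eig, variance_explained = ve,
              samples = colnames(expr))
  class(out) <- "ModuleSet"
  out
}

#' @export
print.ModuleSet <- function(x, ...) {
  cat(sprintf("ModuleSet: %d module(s), %d of %d genes assigned\n",
              length(x$modules), sum(x$assignment != "grey"),
              length(x$assignment)))
  for (m in x$modules)
    cat(sprintf("  %s: %d genes, eigengene variance explained %.2f\n", m,
                sum(x$assignment == m), x$variance_explained[m]))
  invisible(x)
}

#' Module eigengene (first principal component of the module submatrix)
#'
#' Genes are standardized before the SVD; the eigengene sign is oriented so
#' its mean correlation with the module genes is positive.
#'
#' @param expr Genes x samples matrix.
#' @param genes Module gene ids (>= 2).
#' @return List with `score` (per-sample eigengene) and
#'   `variance_explained` (first eigenvalue fraction).
#' @export
module_eigengene <- function(expr, genes) {
  check_that(length(genes) >= 2, "module must contain >= 2 genes")
  sub <- expr[genes, , drop = FALSE]
  sub <- t(scale(t(sub)))
  sub[is.na(sub)] <- 0  # constant genes carry no signal
  sv <- svd(sub, nu = 0, nv = 1)
  score <- sv$v[, 1]
  mc <- mean(cor(score, t(sub)), na.rm = TRUE)
  if (!is.na(mc) && mc < 0) score <- -score
  names(score) <- colnames(expr)
  list(score = score,
       variance_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Correlate module eigengenes with traits and metabolites
#'
#' Pearson correlation with a two-sided p per (eigengene, variable); BH is
#' applied within the clinical-trait family and the metabolite family
#' separately.
#'
#' @param module_set A `ModuleSet`.
#' @param traits Samples x traits data.frame (numeric / 0-1 columns used).
#' @param metabolites Optional metabolites x samples matrix.
#' @param min_pairs Minimum paired observations per test.
#' @return Data frame: module, variable, family, r, p, q.
#' @export
correlate_modules_with_traits <- function(module_set, traits,
                                          metabolites = NULL,
                                          min_pairs = 10) {
  samples <- module_set$samples
  one_family <- function(vars, family) {
    rows <- list()
    for (m in module_set$modules) {
      e <- module_set$eigengenes[[m]]
      for (v in colnames(vars)) {
        x <- vars[samples, v]
        ok <- !is.na(x)
        if (sum(ok) < min_pairs) {
          warning(sprintf("skipping %s ~ %s: < %d paired observations",
                          m, v, min_pairs))
          next
        }
        ct <- suppressWarnings(cor.test(e[ok], x[ok]))
        rows[[length(rows) + 1]] <-
          data.frame(module = m, variable = v, family = family,
                     r = unname(ct$estimate), p = ct$p.value,
                     stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    if (!is.null(out)) out$q <- p.adjust(out$p, method = "BH")
    out
  }
  num <- traits[, vapply(traits, is.numeric, TRUE), drop = FALSE]
  res <- one_family(num, "trait")
  if (!is.null(metabolites)) {
    met <- as.data.frame(t(metabolites))
    res <- rbind(res, one_family(met, "metabolite"))
  }
  res
}

#' Identify GLD-pattern modules by the inverse lipid/glucose sign rule
#'
#' Flags modules whose eigengene is significantly negatively correlated with
#' at least one lipid trait AND significantly positively correlated with at
#' least one glucose trait (or the exact mirror pattern, which is the same
#' module with a flipped eigengene orientation; such modules are flagged
#' `flipped`).
#'
#' @param trait_correlations Output of [correlate_modules_with_traits()].
#' @param lipid_traits,glucose_traits Trait names for each family.
#' @param fdr Significance threshold on q.
#' @return Data frame: module, flipped.
#' @export
find_gld_modules <- function(trait_correlations,
                             lipid_traits = c("LDL", "TotalChol"),
                             glucose_traits = c("HbA1c", "Glucose"),
                             fdr = 0.05) {
  tc <- trait_correlations[trait_correlations$family == "trait", ]
  out <- list()
  for (m in unique(tc$module)) {
    sub <- tc[tc$module == m & tc$q <= fdr, ]
    lip <- sub[sub$variable %in% lipid_traits, ]
    glu <- sub[sub$variable %in% glucose_traits, ]
    if (nrow(lip) && nrow(glu)) {
      if (any(lip$r < 0) && any(glu$r > 0))
        out[[length(out) + 1]] <- data.frame(module = m, flipped = FALSE)
      else if (any(lip$r > 0) && any(glu$r < 0))
        out[[length(out) + 1]] <- data.frame(module = m, flipped = TRUE)
    }
  }
  if (!length(out))
    return(data.frame(module = character(), flipped = logical()))
  do.call(rbind, out)
}

#' Fisher overlap between two module assignments
#'
#' Each non-grey module of `assignment` is tested against each non-grey
#' reference module by a one-tailed Fisher test on the shared gene universe;
#' the best match per reference module is reported.
#'
#' @param assignment,reference Gene -> module label vectors.
#' @param universe Optional gene universe (default: intersection of names).
#' @return List with `table` (ref_module, module, overlap, ref_size,
#'   mod_size, odds_ratio, p, q) and `best_match` (per reference module).
#' @export
module_overlap <- function(assignment, reference, universe = NULL) {
  if (is.null(universe))
    universe <- intersect(names(assignment), names(reference))
  a <- assignment[universe]
  r <- reference[universe]
  rows <- list()
  for (rm in setdiff(unique(r), "grey")) {
    rg <- universe[r == rm]
    for (am in setdiff(unique(a), "grey")) {
      ag <- universe[a == am]
      k <- length(intersect(rg, ag))
      rows[[length(rows) + 1]] <- data.frame(
        ref_module = rm, module = am, overlap = k,
        ref_size = length(rg), mod_size = length(ag),
        odds_ratio = odds_ratio(k, length(rg) - k, length(ag) - k,
                                length(universe) - length(rg) - length(ag) + k),
        p = hyper_p(k, length(rg), length(ag), length(universe)),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    return(list(table = NULL, best_match = NULL))
  tab$q <- p.adjust(tab$p, method = "BH")
  best <- do.call(rbind, lapply(split(tab, tab$ref_module),
                                function(d) d[which.min(d$p), ]))
  list(table = tab, best_match = best)
}

#' Module conservation under a cohort split
#'
#' Re-detects modules separately in each level of a grouping variable and
#' Fisher-overlaps each group's modules against a reference module set over
#' the common gene universe.
#'
#' @param expr Genes x samples matrix.
#' @param split_by Factor/vector with one level per sample (named or in
#'   column order).
#' @param reference A reference `ModuleSet`.
#' @param min_group Minimum samples per group.
#' @param power,min_module_size,cut_height Passed to [detect_modules()].
#' @return Named list (one per group) of [module_overlap()] results plus
#'   the group `ModuleSet`s.
#' @export
split_and_conserve <- function(expr, split_by, reference, min_group = 30,
                               power = NULL, min_module_size = 30,
                               cut_height = 0.99) {
  if (!is.null(names(split_by))) split_by <- split_by[colnames(expr)]
  split_by <- factor(split_by)
  sizes <- table(split_by)
  if (any(sizes < min_group))
    stop(sprintf("split group(s) below the %d-sample floor: %s", min_group,
                 paste(names(sizes)[sizes < min_group], collapse = ", ")),
         call. = FALSE)
  out <- list()
  for (g in levels(split_by)) {
    sub <- expr[, split_by == g, drop = FALSE]
    pw <- if (is.null(power)) pick_soft_power(sub)$power else power
    ms <- detect_modules(sub, pw, min_module_size, cut_height)
    out[[g]] <- list(module_set = ms,
                     overlap = module_overlap(ms$assignment,
                                              reference$assignment))
  }
  out
}
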