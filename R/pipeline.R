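# End-to-end orchestration of the synthetic-cohort analysis: simulate ->
# preprocess -> trait signatures -> coexpression -> eQTL -> CIT -> four
# causal networks (module, multiscale, expanded, global) -> key drivers ->
# composite ranking -> report.

#' Build and validate a pipeline configuration
#'
#' @param seed Run seed; all stage seeds derive from it.
#' @param n_samples Cohort size.
#' @param fdr Global FDR threshold.
#' @param cpm_threshold,sample_fraction CPM filter settings.
#' @param consensus_threshold Consensus edge-frequency cutoff.
#' @param n_reconstructions MCMC reconstructions per network.
#' @param max_path Key-driver downstream path bound.
#' @param window_bp cis window half-width.
#' @param n_expr_pcs Expression PC covariates for the eQTL scan
#'   (`"auto"` picks the count maximizing cis-eQTL discovery).
#' @param cit_n_perm CIT permutations.
#' @param lipid_traits,glucose_traits Trait names for the module sign rule.
#' @param out_dir Optional artifact directory (NULL = in-memory only).
#' @return A validated `gld_config` list.
#' @export
gld_config <- function(seed = 1L, n_samples = 300L, fdr = 0.05,
                       cpm_threshold = 1, sample_fraction = 0.10,
                       consensus_threshold = 0.3,
                       n_reconstructions = 50L, max_path = 7L,
                       window_bp = 1e6, n_expr_pcs = "auto",
                       cit_n_perm = 100L,
                       lipid_traits = c("LDL", "TotalChol"),
                       glucose_traits = c("HbA1c", "Glucose"),
                       out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              fdr = fdr, cpm_threshold = cpm_threshold,
              sample_fraction = sample_fraction,
              consensus_threshold = consensus_threshold,
              n_reconstructions = as.integer(n_reconstructions),
              max_path = max_path, window_bp = window_bp,
              n_expr_pcs = n_expr_pcs,
              cit_n_perm = as.integer(cit_n_perm),
              lipid_traits = lipid_traits,
              glucose_traits = glucose_traits, out_dir = out_dir)
  check_that(cfg$fdr > 0 && cfg$fdr < 1, "fdr must be in (0, 1)")
  check_that(cfg$consensus_threshold > 0 && cfg$consensus_threshold <= 1,
             "consensus_threshold must be in (0, 1]")
  check_that(cfg$sample_fraction > 0 && cfg$sample_fraction <= 1,
             "sample_fraction must be in (0, 1]")
  check_that(cfg$max_path >= 1, "max_path must be >= 1")
  check_that(cfg$n_reconstructions >= 1, "need >= 1 reconstruction")
  class(cfg) <- "gld_config"
  cfg
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes every stage on a cohort simulated from `truth` (or a supplied
#' cohort) and returns all stage artifacts plus, when ground truth is
#' available, recovery summaries. When `config$out_dir` is set, stage
#' outputs are also written as TSV with a JSON provenance record.
#'
#' @param config A `gld_config`.
#' @param cohort Optional pre-built `gld_cohort` (otherwise simulated with
#'   the config seed).
#' @param truth Ground truth used when simulating (default
#'   [default_ground_truth()]).
#' @return A `gld_run` list: cohort, normalized, signatures, modules,
#'   trait_correlations, gld_modules, eqtl, trios, cit, prior_edges,
#'   networks (gld, multiscale, expanded, global), kda, composite,
#'   recovery.
#' @export
run_pipeline <- function(config = gld_config(), cohort = NULL,
                         truth = default_ground_truth()) {
  seed <- config$seed
  if (is.null(cohort))
    cohort <- simulate_cohort(truth, n_samples = config$n_samples,
                              seed = seed)
  truth <- cohort$truth

  norm <- preprocess_counts(cohort$counts, cohort$batches,
                            cpm_threshold = config$cpm_threshold,
                            sample_fraction = config$sample_fraction)
  samples <- norm$kept_samples
  expr <- norm$matrix

  # trait-correlated DE signatures
  sig_traits <- c(config$lipid_traits, config$glucose_traits)
  signatures <- lapply(sig_traits, function(tn)
    associate_trait(norm, setNames(cohort$traits[samples, tn], samples),
                    fdr = config$fdr, trait_name = tn))
  names(signatures) <- sig_traits

  # coexpression modules and the inverse-sign rule
  sp <- pick_soft_power(expr)
  modules <- detect_modules(expr, sp$power)
  met_z <- znormalize_metabolites(cohort$metabolites[, samples, drop = FALSE])
  tc <- correlate_modules_with_traits(modules, cohort$traits[samples, ,
                                                             drop = FALSE],
                                      met_z, min_pairs = 10)
  gld_flag <- find_gld_modules(tc, config$lipid_traits,
                               config$glucose_traits, config$fdr)
  gld_module <- if (nrow(gld_flag)) gld_flag$module[1] else NA_character_
  gld_genes <- if (!is.na(gld_module))
    names(modules$assignment)[modules$assignment == gld_module] else
      character()

  # cis-eQTLs and trios
  eqtl <- map_cis_eqtl(norm, cohort$genotypes, cohort$gene_map,
                       cohort$variant_map, window_bp = config$window_bp,
                       n_expr_pcs = config$n_expr_pcs, fdr = config$fdr)
  trios <- assemble_trios(eqtl, met_z, norm, cohort$genotypes,
                          fdr = config$fdr)
  cit <- run_cit(trios, cohort$genotypes, norm, met_z,
                 n_perm = config$cit_n_perm,
                 seed = stage_seed(seed, "cit"), fdr = config$fdr)
  prior_edges <- collect_prior_edges(cit)

  eqtl_genes <- eqtl$genes$gene[eqtl$genes$significant]

  # four networks: module-only, multiscale, expanded, global
  networks <- list()
  if (length(gld_genes) >= 5) {
    disc_gld <- discretize(expr[gld_genes, , drop = FALSE],
                           seed = stage_seed(seed, "disc_gld"))
    pri_gld <- make_structure_priors(gld_genes,
                                     intersect(eqtl_genes, gld_genes))
    pri_gld <- add_instrument_orientation(pri_gld, expr, cohort$genotypes,
                                          eqtl)
    networks$gld <- learn_consensus_network(
      disc_gld, pri_gld, config$n_reconstructions,
      config$consensus_threshold, seed = stage_seed(seed, "bn_gld"))

    cit_gene_edges <- prior_edges[prior_edges$from %in% gld_genes |
                                    prior_edges$to %in% gld_genes, ,
                                  drop = FALSE]
    networks$multiscale <- build_multiscale(
      expr[gld_genes, , drop = FALSE], met_z,
      cohort$traits[samples, , drop = FALSE],
      continuous_traits = intersect(c(config$lipid_traits,
                                      config$glucose_traits),
                                    colnames(cohort$traits)),
      categorical_traits = intersect(c("Statin", "T2D"),
                                     colnames(cohort$traits)),
      eqtl_genes = eqtl_genes, cit_edges = cit_gene_edges,
      genotypes = cohort$genotypes, eqtl = eqtl,
      n_reconstructions = config$n_reconstructions,
      threshold = config$consensus_threshold,
      seed = stage_seed(seed, "bn_multiscale"))

    correlated <- correlated_with_eigengene(modules, gld_module, expr,
                                            config$fdr)
    expanded_genes <- expand_seed_pexa(gld_genes, correlated,
                                       cohort$pathways, cohort$ppi)
    expanded_genes <- intersect(expanded_genes, rownames(expr))
    disc_exp <- discretize(expr[expanded_genes, , drop = FALSE],
                           seed = stage_seed(seed, "disc_expanded"))
    pri_exp <- make_structure_priors(expanded_genes,
                                     intersect(eqtl_genes, expanded_genes))
    pri_exp <- add_instrument_orientation(pri_exp, expr, cohort$genotypes,
                                          eqtl)
    networks$expanded <- learn_consensus_network(
      disc_exp, pri_exp, config$n_reconstructions,
      config$consensus_threshold, seed = stage_seed(seed, "bn_expanded"))
  }
  all_genes <- rownames(expr)
  disc_all <- discretize(expr, seed = stage_seed(seed, "disc_global"))
  pri_all <- make_structure_priors(all_genes,
                                   intersect(eqtl_genes, all_genes))
  pri_all <- add_instrument_orientation(pri_all, expr, cohort$genotypes,
                                        eqtl)
  networks$global <- learn_consensus_network(
    disc_all, pri_all, config$n_reconstructions,
    config$consensus_threshold, seed = stage_seed(seed, "bn_global"))

  # key drivers of the GLD genes in every network, then the composite
  kda_results <- list(); ranks <- list()
  if (length(gld_genes)) {
    for (nm in names(networks)) {
      kr <- kda(networks[[nm]], gld_genes, max_path = config$max_path,
                fdr = config$fdr)
      kda_results[[nm]] <- kr
      if (any(kr$kdg)) ranks[[nm]] <- weighted_rank(kr)
    }
  }
  composite <- if (length(ranks)) composite_score(ranks) else
    data.frame(node = character(), score = numeric(),
               n_networks = integer())

  run <- list(config = config, cohort = cohort, normalized = norm,
              signatures = signatures, soft_power = sp$power,
              modules = modules, trait_correlations = tc,
              gld_modules = gld_flag, gld_module = gld_module,
              gld_genes = gld_genes, eqtl = eqtl, trios = trios,
              cit = cit, prior_edges = prior_edges, networks = networks,
              kda = kda_results, composite = composite)
  run$recovery <- recovery_summary(run)
  class(run) <- "gld_run"
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

# Genes outside the module whose expression correlates with its eigengene.
correlated_with_eigengene <- function(modules, module, expr, fdr = 0.05) {
  eig <- modules$eigengenes[[module]]
  others <- names(modules$assignment)[modules$assignment != module]
  if (!length(others)) return(character())
  ct <- apply(expr[others, , drop = FALSE], 1, function(x)
    suppressWarnings(cor.test(x, eig))$p.value)
  q <- p.adjust(ct, method = "BH")
  others[q <= fdr]
}

# Truth-vs-inferred summaries: module recovery, directed-edge precision /
# recall within the planted module, master-regulator composite rank.
recovery_summary <- function(run) {
  truth <- run$cohort$truth
  if (is.null(truth)) return(NULL)
  true_gld <- names(truth$module_labels)[truth$module_labels ==
                                           truth$gld_module]
  module_jaccard <- if (length(run$gld_genes))
    length(intersect(run$gld_genes, true_gld)) /
      length(union(run$gld_genes, true_gld)) else 0

  pr <- c(precision = NA_real_, recall = NA_real_)
  if (!is.null(run$networks$gld)) {
    te <- truth$causal_graph
    te <- te[te$from %in% true_gld & te$to %in% true_gld, ]
    true_keys <- paste(te$from, te$to)
    ie <- run$networks$gld$edges
    ie <- ie[ie$from %in% true_gld & ie$to %in% true_gld, ]
    inf_keys <- paste(ie$from, ie$to)
    if (length(inf_keys))
      pr["precision"] <- mean(inf_keys %in% true_keys)
    pr["recall"] <- mean(true_keys %in% inf_keys)
  }
  mr_rank <- match(truth$master_regulator, run$composite$node)
  list(module_jaccard = module_jaccard,
       gld_flagged = !is.na(run$gld_module),
       edge_precision = unname(pr["precision"]),
       edge_recall = unname(pr["recall"]),
       master_regulator_rank = mr_rank)
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(run$normalized$matrix,
                   file.path(dir, "normalized_expression.tsv"), "gene")
  write.table(data.frame(gene = names(run$modules$assignment),
                         module = run$modules$assignment),
              file.path(dir, "module_assignment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(run$trait_correlations,
              file.path(dir, "module_trait_correlations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(run$eqtl$genes, file.path(dir, "eqtl_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(run$cit))
    write.table(as.data.frame(run$cit), file.path(dir, "cit_trios.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(run$networks))
    write.table(run$networks[[nm]]$edges,
                file.path(dir, sprintf("network_%s_edges.tsv", nm)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(run$composite, file.path(dir, "composite_ranking.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- list(seed = run$config$seed,
               n_samples = run$config$n_samples,
               n_reconstructions = run$config$n_reconstructions,
               consensus_threshold = run$config$consensus_threshold,
               package_version = as.character(utils::packageVersion("gldnet")))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  writeLines(report_markdown(run), file.path(dir, "report.md"))
  invisible(dir)
}

#' Render a run report as markdown
#'
#' Module/trait sign grid, the composite key-driver ranking, and (when
#' ground truth is present) recovery summaries.
#'
#' @param run A `gld_run`.
#' @return Character vector of markdown lines.
#' @export
report_markdown <- function(run) {
  lines <- c("# GLD network analysis report", "",
             sprintf("Seed %d, %d samples, %d reconstructions per network.",
                     run$config$seed, run$config$n_samples,
                     run$config$n_reconstructions), "")
  lines <- c(lines, "## Module-trait correlations", "",
             "| module | trait | r | q |", "|---|---|---|---|")
  tc <- run$trait_correlations
  tc <- tc[tc$family == "trait" & tc$q <= run$config$fdr, , drop = FALSE]
  if (nrow(tc))
    lines <- c(lines, sprintf("| %s | %s | %+.2f | %.2g |", tc$module,
                              tc$variable, tc$r, tc$q))
  lines <- c(lines, "",
             sprintf("GLD-pattern module(s): %s",
                     if (nrow(run$gld_modules))
                       paste(run$gld_modules$module, collapse = ", ") else
                         "none"), "")
  lines <- c(lines, "## Composite key-driver ranking", "",
             "| rank | node | score | networks |", "|---|---|---|---|")
  cp <- head(run$composite, 10)
  if (nrow(cp))
    lines <- c(lines, sprintf("| %d | %s | %.2f | %d |", seq_len(nrow(cp)),
                              cp$node, cp$score, cp$n_networks))
  rec <- run$recovery
  if (!is.null(rec)) {
    lines <- c(lines, "", "## Ground-truth recovery", "",
               sprintf("- planted module flagged: %s", rec$gld_flagged),
               sprintf("- module Jaccard vs truth: %.2f", rec$module_jaccard),
               sprintf("- directed edge precision / recall in module: %.2f / %.2f",
                       rec$edge_precision, rec$edge_recall),
               sprintf("- master regulator composite rank: %s",
                       ifelse(is.na(rec$master_regulator_rank), "unranked",
                              rec$master_regulator_rank)))
  }
  lines
}

#' @export
print.gld_run <- function(x, ...) {
  cat("GLD pipeline run\n")
  cat(sprintf("  modules: %d; GLD-pattern module: %s (%d genes)\n",
              length(x$modules$modules),
              ifelse(is.na(x$gld_module), "none", x$gld_module),
              length(x$gld_genes)))
  cat(sprintf("  eQTL genes at FDR: %d; trios: %d; prior edges: %d\n",
              sum(x$eqtl$genes$significant), nrow(x$trios),
              nrow(x$prior_edges)))
  cat(sprintf("  networks: %s\n", paste(names(x$networks), collapse = ", ")))
  if (nrow(x$composite))
    cat(sprintf("  top key driver: %s (score %.2f)\n", x$composite$node[1],
                x$composite$score[1]))
  invisible(x)
}
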