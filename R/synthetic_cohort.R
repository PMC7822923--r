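# Synthetic multiomic cohort generator.
#
# The generator plants a known causal structure -- a glucose- and
# lipid-determining ("GLD-like") coexpression module rooted at a master
# regulator, a second glucose-associated module, cis-eQTLs on the upstream
# module genes, metabolites downstream of module genes, and clinical traits
# loading on the module eigensignals with opposite signs for lipid and
# glucose traits -- so that every inference stage of the pipeline can be
# validated against ground truth.

#' Construct the default ground truth for the synthetic cohort
#'
#' The default truth contains a 60-gene GLD-like module whose causal graph is
#' a ternary tree rooted at the master regulator, with the 22 genes closest
#' to the root carrying cis-eQTLs (so genetic anchors sit upstream, as the
#' DNA-to-RNA prior assumes); a 40-gene glucose module with 8 eQTL genes; and
#' 50 unconnected background genes. Lipid traits load negatively and glucose
#' traits positively on the GLD-like module eigensignal. Five metabolites are
#' direct children of eQTL-bearing GLD genes (providing recoverable
#' SNP-gene-metabolite causal chains), three descend from glucose-module
#' genes, and seven are pure noise.
#'
#' @param seed Integer seed controlling the randomized edge weights.
#' @param gld_size,glucose_size,n_noise_genes Module and background sizes.
#' @param n_gld_eqtl,n_glucose_eqtl Number of eQTL-bearing genes per module.
#' @param eqtl_effect Effect of one dosage unit on latent expression (latent
#'   SD units).
#' @param statin_effect Optional effect of the statin flag on the GLD
#'   eigensignal (0 = independent, the default, so module conservation under
#'   statin splits is testable).
#' @return A `gld_ground_truth` object.
#' @export
default_ground_truth <- function(seed = 1L,
                                 gld_size = 60L, glucose_size = 40L,
                                 n_noise_genes = 50L,
                                 n_gld_eqtl = 22L, n_glucose_eqtl = 8L,
                                 eqtl_effect = 0.8,
                                 statin_effect = 0) {
  set.seed(stage_seed(seed, "ground_truth"))
  gld_genes <- sprintf("G%03d", seq_len(gld_size))
  glu_genes <- sprintf("B%03d", seq_len(glucose_size))
  noise_genes <- sprintf("N%03d", seq_len(n_noise_genes))

  # chain-plus-branches module graph; edge weights carry random signs so
  # modules contain both activated and repressed targets (as real
  # coexpression modules do, and so that no module shifts the library
  # composition or the trimmed mean of M-values in one direction)
  ternary_tree <- function(genes) {
    n <- length(genes)
    if (n < 2) return(data.frame(from = character(), to = character(),
                                 weight = numeric()))
    child <- 2:n
    parent <- ((child - 2L) %/% 3L) + 1L
    data.frame(from = genes[parent], to = genes[child],
               weight = runif(n - 1, 0.85, 1.0) *
                 sample(c(-1, 1), n - 1, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  edges <- rbind(ternary_tree(gld_genes), ternary_tree(glu_genes))

  module_labels <- c(setNames(rep("gld", gld_size), gld_genes),
                     setNames(rep("glucose", glucose_size), glu_genes),
                     setNames(rep("noise", n_noise_genes), noise_genes))

  eqtl_genes <- c(gld_genes[seq_len(n_gld_eqtl)],
                  glu_genes[seq_len(n_glucose_eqtl)])
  eqtl_map <- data.frame(gene = eqtl_genes,
                         variant = paste0("v", eqtl_genes),
                         effect = eqtl_effect,
                         stringsAsFactors = FALSE)

  trait_loadings <- data.frame(
    trait = c("LDL", "TotalChol", "HDL", "Triglycerides",
              "HbA1c", "Glucose", "Insulin", "HbA1c", "Glucose"),
    module = c(rep("gld", 7), "glucose", "glucose"),
    sign = c(-1, -1, -1, -1, 1, 1, 1, 1, 1),
    magnitude = c(0.6, 0.6, 0.25, 0.3, 0.6, 0.6, 0.3, 0.3, 0.3),
    stringsAsFactors = FALSE)

  # metabolites: 5 children of eQTL-bearing GLD genes (planted causal
  # chains for the CIT stage), 3 of glucose genes, 7 pure noise
  metab <- sprintf("M%02d", 1:15)
  metabolite_parents <- c(
    setNames(as.list(gld_genes[2:6]), metab[1:5]),
    setNames(as.list(glu_genes[2:4]), metab[6:8]),
    setNames(rep(list(character(0)), 7), metab[9:15]))

  truth <- list(
    genes = c(gld_genes, glu_genes, noise_genes),
    causal_graph = edges,
    module_labels = module_labels,
    gld_module = "gld",
    glucose_module = "glucose",
    master_regulator = gld_genes[1],
    eqtl_map = eqtl_map,
    trait_loadings = trait_loadings,
    metabolite_parents = metabolite_parents,
    statin_effect = statin_effect,
    seed = as.integer(seed))
  class(truth) <- "gld_ground_truth"
  validate_ground_truth(truth)
  truth
}

validate_ground_truth <- function(truth) {
  g <- igraph::graph_from_data_frame(truth$causal_graph[, 1:2],
                                     directed = TRUE)
  check_that(igraph::is_dag(g), "ground-truth causal graph must be acyclic")
  mod <- truth$module_labels[truth$master_regulator]
  in_mod <- names(truth$module_labels)[truth$module_labels == mod]
  parents <- truth$causal_graph$from[truth$causal_graph$to ==
                                       truth$master_regulator]
  check_that(!any(parents %in% in_mod),
             "master regulator must have no parents within its module")
  lo <- truth$trait_loadings
  gld <- lo[lo$module == truth$gld_module, ]
  lipid <- c("LDL", "TotalChol", "HDL", "Triglycerides")
  gluc <- c("HbA1c", "Glucose", "Insulin")
  check_that(all(gld$sign[gld$trait %in% lipid] < 0) &&
               all(gld$sign[gld$trait %in% gluc] > 0),
             "GLD loadings must be negative for lipid, positive for glucose traits")
  invisible(truth)
}

#' Simulate genotype dosages under Hardy-Weinberg proportions
#'
#' @param n_samples,n_variants Panel dimensions.
#' @param maf_range Interval in (0, 0.5] from which per-variant minor allele
#'   frequencies are drawn uniformly.
#' @param seed Integer seed.
#' @param variant_ids Optional variant names.
#' @return Samples x variants integer dosage matrix (0/1/2) with a
#'   `maf` attribute.
#' @export
simulate_genotypes <- function(n_samples, n_variants,
                               maf_range = c(0.05, 0.5), seed = 1L,
                               variant_ids = NULL) {
  check_that(n_samples >= 2 && n_variants >= 1, "need >= 2 samples, >= 1 variant")
  check_that(length(maf_range) == 2 && maf_range[1] > 0 &&
               maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2],
             "maf_range must lie within (0, 0.5]")
  set.seed(seed)
  maf <- runif(n_variants, maf_range[1], maf_range[2])
  dos <- vapply(maf, function(p) rbinom(n_samples, 2L, p),
                integer(n_samples))
  dos <- matrix(as.integer(dos), nrow = n_samples)
  rownames(dos) <- sprintf("S%03d", seq_len(n_samples))
  colnames(dos) <- if (is.null(variant_ids))
    sprintf("rs%04d", seq_len(n_variants)) else variant_ids
  attr(dos, "maf") <- maf
  dos
}

# Latent expression by linear-Gaussian propagation in topological order:
# value = sum(parent * weight) + eqtl_effect * dosage + N(0, noise_sd);
# exogenous nodes (roots, background genes) get unit-SD innovations.
# `intervention` (gene, shift) adds a constant to the gene's latent value
# BEFORE propagation to its descendants -- the in-silico perturbation hook.
simulate_latent <- function(truth, genotypes, noise_sd = 0.35,
                            intervention = NULL) {
  genes <- truth$genes
  n <- nrow(genotypes)
  edges <- truth$causal_graph
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = TRUE,
                                     vertices = genes)
  ord <- names(igraph::topo_sort(g))
  latent <- matrix(0, nrow = length(genes), ncol = n,
                   dimnames = list(genes, rownames(genotypes)))
  eqtl <- truth$eqtl_map
  has_parent <- genes %in% edges$to
  names(has_parent) <- genes
  for (gene in ord) {
    par_rows <- edges[edges$to == gene, , drop = FALSE]
    val <- rep(0, n)
    if (nrow(par_rows)) {
      for (r in seq_len(nrow(par_rows)))
        val <- val + par_rows$weight[r] * latent[par_rows$from[r], ]
    }
    i <- match(gene, eqtl$gene)
    if (!is.na(i) && eqtl$variant[i] %in% colnames(genotypes))
      val <- val + eqtl$effect[i] * genotypes[, eqtl$variant[i]]
    sdv <- if (has_parent[gene]) noise_sd else 1
    val <- val + rnorm(n, 0, sdv)
    if (!is.null(intervention) && identical(gene, intervention$gene))
      val <- val + intervention$shift
    latent[gene, ] <- val
  }
  latent
}

#' Simulate expression counts from a ground-truth causal graph
#'
#' Latent log-scale expression propagates through the causal graph (linear
#' structural equations with Gaussian noise and additive cis-eQTL dosage
#' effects); additive per-batch offsets are applied on the latent scale to a
#' fixed 20% subset of genes; read counts are Poisson draws around
#' `exp(baseline + latent)` scaled by a per-sample library-size factor.
#'
#' @param truth A `gld_ground_truth` object.
#' @param genotypes Samples x variants dosage matrix containing the eQTL
#'   variants.
#' @param noise_sd Innovation SD for non-root genes.
#' @param library_size_range Relative library-size factor range.
#' @param seed Integer seed.
#' @param n_batches Number of flow-cell batches.
#' @param batch_sd SD of per-(gene, batch) additive offsets (log scale).
#' @param expression_scale Log-fold-change per latent SD unit: controls how
#'   strongly the latent causal signal moves the count scale (0.5 keeps
#'   per-gene variation in a realistic ~1.5-2 fold range and prevents one
#'   module from dominating the library composition).
#' @param intervention Optional `list(gene=, shift=)` latent-scale
#'   perturbation applied before propagation.
#' @return List with `counts` (genes x samples integers), `latent`
#'   (biological signal, no batch), `latent_batch`, `batches`.
#' @export
simulate_expression <- function(truth, genotypes, noise_sd = 0.35,
                                library_size_range = c(0.7, 1.3),
                                seed = 1L, n_batches = 3L, batch_sd = 0.8,
                                expression_scale = 0.5,
                                intervention = NULL) {
  g <- igraph::graph_from_data_frame(truth$causal_graph[, 1:2],
                                     directed = TRUE, vertices = truth$genes)
  check_that(igraph::is_dag(g), "causal graph must be acyclic")
  if (!is.null(intervention))
    check_that(intervention$gene %in% truth$genes,
               paste("unknown gene:", intervention$gene))
  set.seed(seed)
  genes <- truth$genes
  n <- nrow(genotypes)
  latent <- simulate_latent(truth, genotypes, noise_sd, intervention)

  # batch offsets on ~20% of genes, additive on the latent (log) scale
  batches <- factor(sample(paste0("FC", seq_len(n_batches)), n,
                           replace = TRUE, prob = c(0.4, 0.35, 0.25)[seq_len(n_batches)]))
  names(batches) <- rownames(genotypes)
  affected <- sample(genes, ceiling(0.2 * length(genes)))
  offsets <- matrix(rnorm(length(affected) * n_batches, 0, batch_sd),
                    nrow = length(affected),
                    dimnames = list(affected, levels(batches)))
  latent_batch <- expression_scale * latent
  latent_batch[affected, ] <- latent_batch[affected, ] +
    offsets[, as.integer(batches), drop = FALSE]

  # module genes get moderate baselines; unconnected background genes are
  # highly expressed (housekeeping-like), so -- as in real libraries -- no
  # single module dominates the library mass and CPM normalization does not
  # cancel the module's own eigensignal
  in_module <- truth$module_labels[genes] != "noise"
  baseline <- ifelse(in_module,
                     runif(length(genes), log(50), log(500)),
                     runif(length(genes), log(1000), log(10000)))
  libfac <- runif(n, library_size_range[1], library_size_range[2])
  mu <- exp(baseline + latent_batch) %*% diag(libfac)
  counts <- matrix(rpois(length(mu), lambda = mu), nrow = length(genes),
                   dimnames = list(genes, rownames(genotypes)))
  list(counts = counts, latent = latent, latent_batch = latent_batch,
       batches = batches)
}

# Standardized module eigensignal used to wire traits to modules: the
# scaled per-sample mean of the module's latent expression after aligning
# each gene by its ground-truth response sign (the product of edge-weight
# signs on the path from the module root).
module_eigensignal <- function(truth, latent, module) {
  genes <- names(truth$module_labels)[truth$module_labels == module]
  signs <- gene_path_signs(truth)[genes]
  as.numeric(scale(colMeans(signs * latent[genes, , drop = FALSE])))
}

#' Ground-truth response sign of every gene
#'
#' The product of edge-weight signs along the path from the gene's module
#' root (roots and unconnected genes are +1). Multiple parents multiply
#' through the first parent encountered in topological order.
#'
#' @param truth A `gld_ground_truth`.
#' @return Named sign vector (+1/-1) over all genes.
#' @export
gene_path_signs <- function(truth) {
  edges <- truth$causal_graph
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = TRUE,
                                     vertices = truth$genes)
  ord <- names(igraph::topo_sort(g))
  signs <- setNames(rep(1, length(truth$genes)), truth$genes)
  for (gene in ord) {
    i <- which(edges$to == gene)
    if (length(i))
      signs[gene] <- signs[edges$from[i[1]]] * sign(edges$weight[i[1]])
  }
  signs
}

#' Simulate clinical traits and metabolites from latent expression
#'
#' Continuous traits are linear combinations of module eigensignals
#' (`sign * magnitude`) plus Gaussian noise scaled so the loading magnitude
#' approximates the trait-eigensignal correlation. Binary traits: the statin
#' flag is drawn independently of expression (unless the truth carries a
#' statin effect); T2D, hyperlipidemia and oral anti-diabetic use are
#' logistic functions of the glucose/lipid traits. Metabolites are linear
#' functions of their ground-truth gene parents plus noise.
#'
#' @param truth A `gld_ground_truth` object.
#' @param latent Genes x samples latent expression (biological scale).
#' @param seed Integer seed.
#' @return List with `traits` (samples x traits data.frame) and
#'   `metabolites` (metabolites x samples matrix).
#' @export
simulate_traits_and_metabolites <- function(truth, latent, seed = 1L) {
  lo <- truth$trait_loadings
  check_that(all(lo$module %in% truth$module_labels),
             "trait loading references unknown module")
  set.seed(seed)
  n <- ncol(latent)
  eig <- sapply(unique(lo$module), function(m)
    module_eigensignal(truth, latent, m))

  traits <- unique(lo$trait)
  tr <- sapply(traits, function(t) {
    rows <- lo[lo$trait == t, , drop = FALSE]
    signal <- rep(0, n)
    for (r in seq_len(nrow(rows)))
      signal <- signal + rows$sign[r] * rows$magnitude[r] * eig[, rows$module[r]]
    resid_sd <- sqrt(max(0.1, 1 - sum(rows$magnitude^2)))
    signal + rnorm(n, 0, resid_sd)
  })
  tr <- as.data.frame(tr)
  rownames(tr) <- colnames(latent)

  statin_lin <- -0.6 + truth$statin_effect * eig[, truth$gld_module]
  tr$Statin <- rbinom(n, 1, plogis(statin_lin))
  tr$T2D <- rbinom(n, 1, plogis(-1 + 1.2 * scale(tr$HbA1c)[, 1]))
  tr$Hyperlipidemia <- rbinom(n, 1, plogis(-0.5 + 1.2 * scale(tr$LDL)[, 1]))
  tr$OralAntiDiab <- rbinom(n, 1, plogis(-2.5 + 2.5 * tr$T2D))

  mp <- truth$metabolite_parents
  met <- t(sapply(names(mp), function(m) {
    parents <- mp[[m]]
    if (length(parents) == 0) return(rnorm(n))
    sig <- colSums(latent[parents, , drop = FALSE])
    # noise scaled to give parent-metabolite r around 0.75: strong enough
    # to screen into trios, noisy enough that mediation is not degenerate
    0.9 * sig + rnorm(n, 0, 0.8 * max(sd(sig), 1e-8))
  }))
  colnames(met) <- colnames(latent)
  list(traits = tr, metabolites = met)
}

#' Simulate a complete synthetic multiomic cohort
#'
#' Assembles genotypes (each gene receives three cis variants, one of which
#' is causal for eQTL-bearing genes), expression counts, metabolites,
#' clinical traits, batch labels, gene/variant position maps (genes spaced
#' 2 Mb apart so +/- 1 Mb cis windows are disjoint), and a synthetic pathway
#' annotation / protein-interaction edge list derived from the truth for the
#' enrichment and network-expansion stages.
#'
#' @param truth A `gld_ground_truth` object.
#' @param n_samples Cohort size.
#' @param seed Integer seed.
#' @param noise_sd,library_size_range,n_batches,batch_sd Passed to
#'   [simulate_expression()].
#' @return A `gld_cohort` object.
#' @export
simulate_cohort <- function(truth = default_ground_truth(),
                            n_samples = 300L, seed = 1L,
                            noise_sd = 0.35,
                            library_size_range = c(0.7, 1.3),
                            n_batches = 3L, batch_sd = 0.8) {
  genes <- truth$genes
  n_genes <- length(genes)
  gene_map <- data.frame(gene = genes, chrom = "chr1",
                         pos = seq_len(n_genes) * 2e6,
                         stringsAsFactors = FALSE)

  # 3 cis variants per gene; the first is the causal one for eQTL genes
  variant_ids <- as.vector(t(cbind(paste0("v", genes),
                                   paste0("n1", genes), paste0("n2", genes))))
  variant_pos <- as.vector(t(cbind(gene_map$pos + 1e4,
                                   gene_map$pos - 3e5, gene_map$pos + 5e5)))
  variant_map <- data.frame(variant = variant_ids, chrom = "chr1",
                            pos = variant_pos, stringsAsFactors = FALSE)

  genotypes <- simulate_genotypes(n_samples, length(variant_ids),
                                  maf_range = c(0.1, 0.5),
                                  seed = stage_seed(seed, "genotypes"),
                                  variant_ids = variant_ids)
  ex <- simulate_expression(truth, genotypes, noise_sd = noise_sd,
                            library_size_range = library_size_range,
                            seed = stage_seed(seed, "expression"),
                            n_batches = n_batches, batch_sd = batch_sd)
  tm <- simulate_traits_and_metabolites(truth, ex$latent,
                                        seed = stage_seed(seed, "traits"))
  ann <- simulate_annotation(truth, seed = stage_seed(seed, "annotation"))

  cohort <- list(genotypes = genotypes, counts = ex$counts,
                 latent = ex$latent, batches = ex$batches,
                 metabolites = tm$metabolites, traits = tm$traits,
                 gene_map = gene_map, variant_map = variant_map,
                 pathways = ann$pathways, ppi = ann$ppi,
                 truth = truth, seed = as.integer(seed),
                 sim_params = list(noise_sd = noise_sd,
                                   library_size_range = library_size_range,
                                   n_batches = n_batches,
                                   batch_sd = batch_sd))
  class(cohort) <- "gld_cohort"
  cohort
}

# Synthetic functional annotation: one pathway per true module plus random
# gene sets; PPI = undirected true edges plus random pairs.
simulate_annotation <- function(truth, seed = 1L, n_random_pathways = 10L,
                                n_random_ppi = 100L) {
  set.seed(seed)
  genes <- truth$genes
  pathways <- list(
    PW_STEROL = names(truth$module_labels)[truth$module_labels == truth$gld_module],
    PW_PYRUVATE = names(truth$module_labels)[truth$module_labels == truth$glucose_module])
  for (i in seq_len(n_random_pathways))
    pathways[[sprintf("PW_RND%02d", i)]] <- sample(genes, sample(10:30, 1))
  ppi <- truth$causal_graph[, c("from", "to")]
  rnd <- data.frame(from = sample(genes, n_random_ppi, replace = TRUE),
                    to = sample(genes, n_random_ppi, replace = TRUE),
                    stringsAsFactors = FALSE)
  ppi <- rbind(ppi, rnd[rnd$from != rnd$to, ])
  list(pathways = pathways, ppi = unique(ppi))
}

#' In-silico perturbation of a gene in the causal graph
#'
#' Re-simulates the cohort under the same seeds with the target gene's
#' latent value shifted by `shift` before propagation, so only the gene and
#' its causal descendants (and traits/metabolites downstream of them) change
#' in expectation -- the computational analogue of pharmacological
#' inhibition of a candidate master regulator.
#'
#' @param cohort A `gld_cohort` object.
#' @param gene Gene to perturb.
#' @param shift Latent-scale shift.
#' @return A perturbed `gld_cohort`.
#' @export
perturb_key_driver <- function(cohort, gene, shift) {
  check_that(gene %in% cohort$truth$genes, paste("unknown gene:", gene))
  sp <- cohort$sim_params
  ex <- simulate_expression(cohort$truth, cohort$genotypes,
                            noise_sd = sp$noise_sd,
                            library_size_range = sp$library_size_range,
                            n_batches = sp$n_batches, batch_sd = sp$batch_sd,
                            seed = stage_seed(cohort$seed, "expression"),
                            intervention = list(gene = gene, shift = shift))
  tm <- simulate_traits_and_metabolites(cohort$truth, ex$latent,
                                        seed = stage_seed(cohort$seed, "traits"))
  out <- cohort
  out$counts <- ex$counts
  out$latent <- ex$latent
  out$batches <- ex$batches
  out$metabolites <- tm$metabolites
  out$traits <- tm$traits
  out
}

#' Write a cohort to plain-text files
#'
#' Counts, metabolites and traits as TSV; genotypes as a dosage TSV plus a
#' minimal VCF (GT field only); the ground-truth causal graph as an
#' edge-list TSV with JSON metadata.
#'
#' @param cohort A `gld_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(cohort$counts, file.path(dir, "counts.tsv"), "gene")
  write_matrix_tsv(cohort$metabolites, file.path(dir, "metabolites.tsv"),
                   "metabolite")
  tr <- data.frame(sample = rownames(cohort$traits), cohort$traits,
                   check.names = FALSE)
  write.table(tr, file.path(dir, "traits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = names(cohort$batches),
                         batch = as.character(cohort$batches)),
              file.path(dir, "batches.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_matrix_tsv(t(cohort$genotypes), file.path(dir, "dosages.tsv"),
                   "variant")
  write.table(cohort$gene_map, file.path(dir, "gene_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$variant_map, file.path(dir, "variant_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$truth$causal_graph, file.path(dir, "truth_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_minimal_vcf(cohort, file.path(dir, "genotypes.vcf"))
  meta <- list(seed = cohort$seed,
               master_regulator = cohort$truth$master_regulator,
               gld_module = cohort$truth$gld_module,
               n_samples = nrow(cohort$genotypes))
  jsonlite::write_json(meta, file.path(dir, "truth_meta.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

# Minimal VCF 4.2 with GT only; dosage d -> 0/0, 0/1, 1/1.
write_minimal_vcf <- function(cohort, path) {
  gt_codes <- c("0/0", "0/1", "1/1")
  vm <- cohort$variant_map
  samples <- rownames(cohort$genotypes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  for (i in seq_len(nrow(vm))) {
    gts <- gt_codes[cohort$genotypes[, vm$variant[i]] + 1L]
    writeLines(paste(c(vm$chrom[i], vm$pos[i], vm$variant[i], "A", "G", ".",
                       "PASS", ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

#' @export
print.gld_cohort <- function(x, ...) {
  cat("Synthetic multiomic cohort\n")
  cat(sprintf("  samples: %d  genes: %d  variants: %d  metabolites: %d\n",
              nrow(x$genotypes), nrow(x$counts), ncol(x$genotypes),
              nrow(x$metabolites)))
  cat(sprintf("  planted GLD-like module: %d genes, master regulator %s\n",
              sum(x$truth$module_labels == x$truth$gld_module),
              x$truth$master_regulator))
  invisible(x)
}
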