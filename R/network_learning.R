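# Consensus Bayesian causal networks: k-means discretization, structure
# priors from cis-eQTLs and CIT calls, MCMC reconstructions with BDeu
# scoring, consensus thresholding, weakest-link cycle breaking, seed-list
# expansion, and the multiscale (gene + metabolite + trait) variant.

#' Discretize continuous node values into 2-3 states by k-means
#'
#' Per node: values are z-scored and clustered with k = 3 (best of
#' `n_init` restarts); when any cluster receives fewer than 2 samples or
#' two centers fall within 0.5 SD of each other (a split mode rather than
#' a distinct cluster), the node is refit with
#' k = 2. States are labeled 0..k-1 in increasing center order
#' (low / none / high).
#'
#' @param x Nodes x samples numeric matrix.
#' @param k Target number of states.
#' @param n_init k-means restarts.
#' @param seed Integer seed.
#' @param min_cluster Minimum samples per cluster before falling back.
#' @param min_separation Minimum center separation (SD units).
#' @return A `DiscreteMatrix`: list with `states` (integer matrix),
#'   `nstates`, `centers`.
#' @export
discretize <- function(x, k = 3, n_init = 10, seed = 1L, min_cluster = 2,
                       min_separation = 0.5) {
  check_that(is.matrix(x), "x must be a matrix")
  sds <- apply(x, 1, sd)
  check_that(all(sds > 0),
             paste("constant node(s):", paste(head(rownames(x)[sds == 0]),
                                              collapse = ", ")))
  set.seed(seed)
  states <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  nstates <- integer(nrow(x))
  centers <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    z <- as.numeric(scale(x[i, ]))
    fit <- kmeans_states(z, k, n_init, min_cluster, min_separation)
    states[i, ] <- fit$states
    nstates[i] <- fit$k
    centers[[i]] <- fit$centers
  }
  names(nstates) <- rownames(x)
  names(centers) <- rownames(x)
  out <- list(states = states, nstates = nstates, centers = centers)
  class(out) <- "DiscreteMatrix"
  out
}

kmeans_states <- function(z, k, n_init, min_cluster, min_separation) {
  ku <- length(unique(z))
  for (kk in seq(min(k, ku), 2)) {
    fit <- tryCatch(kmeans(z, centers = kk, nstart = n_init),
                    error = function(e) NULL)
    if (is.null(fit)) next
    ctr <- as.numeric(fit$centers)
    ok <- min(fit$size) >= min_cluster &&
      (kk == 1 || min(diff(sort(ctr))) >= min_separation)
    if (ok || kk == 2) {
      ord <- order(ctr)
      relabel <- match(seq_len(kk), ord) - 1L
      return(list(states = relabel[fit$cluster], k = kk,
                  centers = sort(ctr)))
    }
  }
  # fewer than 2 distinct values was excluded upstream (constant node)
  med <- stats::median(z)
  list(states = as.integer(z > med), k = 2L, centers = c(-1, 1))
}

# Combine discrete matrices (e.g. genes + metabolites + traits) by sample.
combine_discrete <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, TRUE)]
  samples <- Reduce(intersect, lapply(parts, function(p) colnames(p$states)))
  out <- list(
    states = do.call(rbind, lapply(parts, function(p)
      p$states[, samples, drop = FALSE])),
    nstates = do.call(c, lapply(parts, `[[`, "nstates")),
    centers = do.call(c, lapply(parts, `[[`, "centers")))
  class(out) <- "DiscreteMatrix"
  out
}

# Discretize categorical / binary trait columns into their natural states.
discretize_categorical <- function(traits, columns) {
  samples <- rownames(traits)
  states <- t(vapply(columns, function(cl) {
    f <- factor(traits[[cl]])
    check_that(nlevels(f) %in% 2:3,
               sprintf("categorical trait '%s' must have 2-3 levels", cl))
    as.integer(f) - 1L
  }, integer(nrow(traits))))
  rownames(states) <- columns
  colnames(states) <- samples
  out <- list(states = states,
              nstates = setNames(apply(states, 1, function(s)
                length(unique(s))), columns),
              centers = setNames(vector("list", length(columns)), columns))
  class(out) <- "DiscreteMatrix"
  out
}

#' Build structure priors for network reconstruction
#'
#' Soft priors encode the DNA -> RNA direction: any edge pointing INTO an
#' eQTL-anchored node from a non-anchored node is down-weighted by
#' `eqtl_weight`, preferentially placing genetically anchored genes
#' upstream and breaking Markov-equivalent orientations. Strong priors
#' (e.g. CIT-derived gene -> metabolite edges) are forced present in every
#' reconstruction; forbidden edges are never proposed.
#'
#' @param nodes Node names.
#' @param eqtl_genes Nodes carrying a cis-eQTL anchor.
#' @param strong_edges Optional data frame (from, to) of forced edges.
#' @param forbidden_edges Optional data frame (from, to) of banned edges.
#' @param eqtl_weight Multiplicative weight (< 1) against edges into
#'   anchored nodes from non-anchored nodes.
#' @return A `StructurePriors`: list with `log_w`, `strong`, `forbidden`
#'   matrices and `nodes`.
#' @export
make_structure_priors <- function(nodes, eqtl_genes = character(),
                                  strong_edges = NULL,
                                  forbidden_edges = NULL,
                                  eqtl_weight = 0.1) {
  check_that(eqtl_weight > 0, "prior weights must be positive")
  n <- length(nodes)
  log_w <- matrix(0, n, n, dimnames = list(nodes, nodes))
  anchored <- nodes %in% eqtl_genes
  log_w[!anchored, anchored] <- log(eqtl_weight)
  strong <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  forbidden <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  if (!is.null(strong_edges) && nrow(strong_edges)) {
    check_that(all(c(strong_edges$from, strong_edges$to) %in% nodes),
               "strong-prior edge references unknown node")
    strong[cbind(strong_edges$from, strong_edges$to)] <- 1L
    g <- igraph::graph_from_data_frame(strong_edges[, c("from", "to")],
                                       directed = TRUE, vertices = nodes)
    check_that(igraph::is_dag(g), "strong-prior edges must form a DAG")
  }
  if (!is.null(forbidden_edges) && nrow(forbidden_edges))
    forbidden[cbind(forbidden_edges$from, forbidden_edges$to)] <- 1L
  check_that(!any(strong == 1 & forbidden == 1),
             "an edge cannot be both strong and forbidden")
  out <- list(log_w = log_w, strong = strong, forbidden = forbidden,
              nodes = nodes)
  class(out) <- "StructurePriors"
  out
}

#' Refine structure priors with instrument-association orientation
#'
#' A gene's cis variant acts on other genes only through that gene, so any
#' node associated with gene A's top eSNP must lie downstream of A. For
#' every significant eQTL gene A among the nodes, every other node B whose
#' values associate with A's top eSNP (p below `p_threshold`) has the edge
#' B -> A down-weighted by `weight`. This orients edges between two
#' anchored genes, which the coarse anchored/non-anchored rule cannot.
#'
#' @param priors A `StructurePriors`.
#' @param values Nodes x samples numeric matrix (expression, metabolites,
#'   discretizable traits) covering the prior nodes present in it.
#' @param genotypes Samples x variants dosage matrix.
#' @param eqtl An `EqtlResult`.
#' @param p_threshold Association threshold for the orientation call.
#' @param weight Multiplicative penalty on the disfavored direction.
#' @return The updated `StructurePriors`.
#' @export
add_instrument_orientation <- function(priors, values, genotypes, eqtl,
                                       p_threshold = 1e-3, weight = 0.01) {
  check_that(weight > 0, "prior weights must be positive")
  sig <- eqtl$genes[eqtl$genes$significant, , drop = FALSE]
  sig <- sig[sig$gene %in% priors$nodes, , drop = FALSE]
  if (!nrow(sig)) return(priors)
  samples <- intersect(colnames(values), rownames(genotypes))
  V <- values[intersect(priors$nodes, rownames(values)), samples,
              drop = FALSE]
  n <- length(samples)
  for (i in seq_len(nrow(sig))) {
    a <- sig$gene[i]
    d <- genotypes[samples, sig$top_esnp[i]]
    if (sd(d) == 0) next
    r <- suppressWarnings(cor(d, t(V)))[1, ]
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
    p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
    dn <- setdiff(names(p)[!is.na(p) & p < p_threshold], a)
    if (length(dn))
      priors$log_w[dn, a] <- pmin(priors$log_w[dn, a], log(weight))
  }
  priors
}

#' BDeu log marginal-likelihood score of a DAG
#'
#' Decomposable Bayesian Dirichlet equivalent uniform score: the sum over
#' nodes of the Dirichlet-multinomial family score with equivalent sample
#' size `ess`.
#'
#' @param dag Adjacency matrix (from x to) or data frame of edges
#'   (from, to) over the discrete nodes.
#' @param discrete A `DiscreteMatrix`.
#' @param ess Equivalent sample size.
#' @param max_parents Maximum in-degree.
#' @return Log score (numeric scalar).
#' @export
score_network <- function(dag, discrete, ess = 0.25, max_parents = 3) {
  nodes <- rownames(discrete$states)
  adj <- as_adjacency(dag, nodes)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  check_that(igraph::is_dag(g), "dag must be acyclic")
  check_that(max(colSums(adj)) <= max_parents,
             sprintf("parent sets capped at %d", max_parents))
  D <- discrete$states
  storage.mode(D) <- "integer"
  total <- 0
  for (j in seq_along(nodes)) {
    parents <- which(adj[, j] == 1) - 1L
    total <- total + .bdeu_family_score(D, as.integer(discrete$nstates),
                                        j - 1L, as.integer(parents), ess)
  }
  total
}

as_adjacency <- function(dag, nodes) {
  if (is.matrix(dag)) {
    check_that(identical(dim(dag), c(length(nodes), length(nodes))),
               "adjacency dimensions must match the node set")
    adj <- dag
    dimnames(adj) <- list(nodes, nodes)
  } else {
    adj <- matrix(0L, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    if (nrow(dag)) adj[cbind(dag$from, dag$to)] <- 1L
  }
  storage.mode(adj) <- "integer"
  adj
}

#' One MCMC reconstruction of a Bayesian network structure
#'
#' Metropolis-Hastings over DAGs (add / delete / reverse moves) on the BDeu
#' posterior, with the structure-prior ratio in the acceptance probability.
#' Strong-prior edges seed the chain and are never deleted or reversed. The
#' final sampled DAG is returned.
#'
#' @param discrete A `DiscreteMatrix`.
#' @param priors A `StructurePriors` over the same nodes.
#' @param n_iter Post-burn-in steps (default `300 * n_nodes`).
#' @param burn_in Burn-in steps (default `150 * n_nodes`).
#' @param seed Integer seed.
#' @param max_parents Maximum in-degree.
#' @param ess BDeu equivalent sample size.
#' @return Adjacency matrix of the sampled DAG.
#' @export
mcmc_reconstruction <- function(discrete, priors, n_iter = NULL,
                                burn_in = NULL, seed = 1L, max_parents = 3,
                                ess = 0.25) {
  nodes <- rownames(discrete$states)
  check_that(identical(nodes, priors$nodes),
             "discrete matrix and priors must share the node set")
  n <- length(nodes)
  if (is.null(n_iter)) n_iter <- 300L * n
  if (is.null(burn_in)) burn_in <- 150L * n
  check_that(n_iter > 0 && burn_in >= 0, "n_iter > burn_in >= 0 required")
  D <- discrete$states
  storage.mode(D) <- "integer"
  set.seed(seed)
  adj <- .bn_mcmc_chain(D, as.integer(discrete$nstates), priors$log_w,
                        priors$strong, priors$forbidden,
                        as.integer(burn_in + n_iter),
                        as.integer(max_parents), ess)
  dimnames(adj) <- list(nodes, nodes)
  adj
}

#' Consensus network from repeated reconstructions
#'
#' The consensus frequency of a directed edge is the fraction of sampled
#' DAGs containing it; edges at or above `threshold` are retained.
#'
#' @param samples List of adjacency matrices (same dimnames).
#' @param threshold Consensus frequency cutoff.
#' @param node_types Optional named node-type vector (gene / metabolite /
#'   trait).
#' @param strong Optional strong-prior adjacency used to flag forced edges.
#' @return A `ConsensusCausalNetwork`: list with `edges` (from, to,
#'   frequency, prior), `nodes`, `node_types`, `threshold`, `removed`
#'   (cycle-break log, empty here).
#' @export
build_consensus <- function(samples, threshold = 0.3, node_types = NULL,
                            strong = NULL) {
  check_that(length(samples) >= 1, "need >= 1 reconstruction")
  freq <- Reduce(`+`, samples) / length(samples)
  nodes <- rownames(freq)
  keep <- which(freq >= threshold & row(freq) != col(freq), arr.ind = TRUE)
  edges <- data.frame(from = nodes[keep[, 1]], to = nodes[keep[, 2]],
                      frequency = freq[keep], stringsAsFactors = FALSE)
  edges$prior <- if (!is.null(strong) && nrow(edges))
    strong[cbind(edges$from, edges$to)] == 1 else
      rep(FALSE, nrow(edges))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  if (is.null(node_types))
    node_types <- setNames(rep("gene", length(nodes)), nodes)
  out <- list(edges = edges, nodes = nodes, node_types = node_types,
              threshold = threshold, removed = edges[0, ])
  class(out) <- "ConsensusCausalNetwork"
  out
}

#' Break cycles in a consensus network by removing weakest links
#'
#' While a directed cycle exists, the cycle's minimum-frequency edge is
#' removed (ties broken lexicographically by source then target); forced
#' strong-prior edges are never removed. All removals are recorded.
#'
#' @param network A `ConsensusCausalNetwork`.
#' @return The network with an acyclic edge set and a populated `removed`
#'   log.
#' @export
break_cycles <- function(network) {
  edges <- network$edges
  removed <- edges[0, ]
  repeat {
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                       directed = TRUE,
                                       vertices = network$nodes)
    if (igraph::is_dag(g)) break
    cyc <- find_cycle(edges)
    cand <- cyc[!cyc$prior, , drop = FALSE]
    if (!nrow(cand))
      stop("cycle consists entirely of strong-prior edges", call. = FALSE)
    cand <- cand[order(cand$frequency, cand$from, cand$to), , drop = FALSE]
    drop <- cand[1, ]
    removed <- rbind(removed, drop)
    edges <- edges[!(edges$from == drop$from & edges$to == drop$to), ,
                   drop = FALSE]
  }
  network$edges <- edges
  network$removed <- removed
  network
}

# Locate one directed cycle via DFS back-edge tracking; returns its edges.
find_cycle <- function(edges) {
  nodes <- unique(c(edges$from, edges$to))
  succ <- split(edges$to, factor(edges$from, levels = nodes))
  color <- setNames(rep(0L, length(nodes)), nodes)  # 0 white 1 grey 2 black
  parent <- setNames(rep(NA_character_, length(nodes)), nodes)
  cycle_nodes <- NULL
  dfs <- function(u) {
    color[u] <<- 1L
    for (v in succ[[u]]) {
      if (color[v] == 0L) {
        parent[v] <<- u
        dfs(v)
        if (!is.null(cycle_nodes)) return()
      } else if (color[v] == 1L) {
        path <- u
        while (path[1] != v) path <- c(parent[path[1]], path)
        cycle_nodes <<- c(path, v)
        return()
      }
    }
    color[u] <<- 2L
  }
  for (u in nodes) {
    if (color[u] == 0L) dfs(u)
    if (!is.null(cycle_nodes)) break
  }
  check_that(!is.null(cycle_nodes), "no cycle found")
  idx <- vapply(seq_len(length(cycle_nodes) - 1), function(i)
    which(edges$from == cycle_nodes[i] & edges$to == cycle_nodes[i + 1])[1],
    1L)
  edges[idx, , drop = FALSE]
}

#' Learn a consensus causal network end to end
#'
#' Runs `n_reconstructions` independent MCMC chains (seeds derived from
#' `seed`), thresholds the edge frequencies, and breaks any residual
#' cycles by the weakest link.
#'
#' @param discrete A `DiscreteMatrix`.
#' @param priors A `StructurePriors`.
#' @param n_reconstructions Number of chains.
#' @param threshold Consensus cutoff.
#' @param seed Run seed.
#' @param node_types Optional node-type labels.
#' @param ... Passed to [mcmc_reconstruction()].
#' @return A DAG `ConsensusCausalNetwork`.
#' @export
learn_consensus_network <- function(discrete, priors,
                                    n_reconstructions = 50,
                                    threshold = 0.3, seed = 1L,
                                    node_types = NULL, ...) {
  samples <- lapply(seq_len(n_reconstructions), function(r)
    mcmc_reconstruction(discrete, priors,
                        seed = stage_seed(seed, paste0("chain", r)), ...))
  net <- build_consensus(samples, threshold, node_types,
                         strong = priors$strong)
  break_cycles(net)
}

#' @export
print.ConsensusCausalNetwork <- function(x, ...) {
  cat(sprintf("ConsensusCausalNetwork: %d nodes, %d edges (threshold %.2f, %d forced, %d removed in cycle breaking)\n",
              length(x$nodes), nrow(x$edges), x$threshold,
              sum(x$edges$prior), nrow(x$removed)))
  invisible(x)
}

# igraph view of a consensus network.
network_graph <- function(network) {
  igraph::graph_from_data_frame(network$edges[, c("from", "to")],
                                directed = TRUE, vertices = network$nodes)
}

#' Expand a seed gene list via pathways and protein interactions
#'
#' Simplified pathway-expansion rule: the expanded set is the union of the
#' seed list, the correlated genes, every gene in any pathway containing at
#' least one seed/correlated gene, and any protein-interaction node lying
#' on a shortest path of length <= 2 between two members that are not
#' directly connected.
#'
#' @param seed_genes Seed list (non-empty).
#' @param correlated_genes Genes correlated with the module eigengene.
#' @param pathways Named list of pathway gene sets (GMT-style).
#' @param ppi Data frame (from, to) of undirected interactions.
#' @return Character vector of expanded genes.
#' @export
expand_seed_pexa <- function(seed_genes, correlated_genes = character(),
                             pathways = list(), ppi = NULL) {
  check_that(length(seed_genes) > 0, "empty seed list")
  members <- union(seed_genes, correlated_genes)
  expanded <- members
  for (pw in pathways)
    if (length(intersect(pw, members))) expanded <- union(expanded, pw)
  if (!is.null(ppi) && nrow(ppi)) {
    g <- igraph::graph_from_data_frame(ppi, directed = FALSE)
    present <- intersect(members, igraph::V(g)$name)
    if (length(present) >= 2) {
      bridge <- setdiff(igraph::V(g)$name, members)
      adj_mem <- lapply(bridge, function(x)
        intersect(igraph::neighbors(g, x)$name, present))
      direct <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
      for (i in seq_along(bridge)) {
        nb <- adj_mem[[i]]
        if (length(nb) < 2) next
        pairs <- utils::combn(nb, 2)
        on_path <- any(!direct[cbind(pairs[1, ], pairs[2, ])])
        if (on_path) expanded <- union(expanded, bridge[i])
      }
    }
  }
  expanded
}

#' Learn the multiscale (gene + metabolite + trait) consensus network
#'
#' Metabolites and continuous traits are discretized with the same k-means
#' scheme as genes; categorical traits take their natural 2-3 states.
#' CIT-derived edges enter as strong priors (forced into every
#' reconstruction); by default trait nodes may not parent eQTL-anchored
#' genes.
#'
#' @param expr Genes x samples normalized matrix (module genes).
#' @param metabolites Metabolites x samples matrix.
#' @param traits Samples x traits data.frame.
#' @param continuous_traits,categorical_traits Column names per kind.
#' @param eqtl_genes Genes with cis-eQTL anchors (soft priors).
#' @param cit_edges Data frame (from, to) of CIT strong-prior edges.
#' @param forbid_trait_to_anchored Forbid trait -> eQTL-gene edges.
#' @param genotypes,eqtl Optional dosage matrix and `EqtlResult` enabling
#'   instrument-association orientation priors
#'   (see [add_instrument_orientation()]).
#' @param n_reconstructions,threshold,seed,... Passed to
#'   [learn_consensus_network()].
#' @return A `ConsensusCausalNetwork` with node types.
#' @export
build_multiscale <- function(expr, metabolites, traits,
                             continuous_traits, categorical_traits,
                             eqtl_genes = character(), cit_edges = NULL,
                             forbid_trait_to_anchored = TRUE,
                             genotypes = NULL, eqtl = NULL,
                             n_reconstructions = 50, threshold = 0.3,
                             seed = 1L, ...) {
  samples <- Reduce(intersect, list(colnames(expr), colnames(metabolites),
                                    rownames(traits)))
  dg <- discretize(expr[, samples, drop = FALSE],
                   seed = stage_seed(seed, "disc_genes"))
  dm <- discretize(metabolites[, samples, drop = FALSE],
                   seed = stage_seed(seed, "disc_metab"))
  ct <- t(as.matrix(traits[samples, continuous_traits, drop = FALSE]))
  dct <- discretize(ct, seed = stage_seed(seed, "disc_traits"))
  dcat <- if (length(categorical_traits))
    discretize_categorical(traits[samples, , drop = FALSE],
                           categorical_traits) else NULL
  disc <- combine_discrete(dg, dm, dct, dcat)
  nodes <- rownames(disc$states)
  node_types <- setNames(rep("gene", length(nodes)), nodes)
  node_types[rownames(metabolites)] <- "metabolite"
  node_types[c(continuous_traits, categorical_traits)] <- "trait"
  forbidden <- NULL
  if (forbid_trait_to_anchored && length(eqtl_genes)) {
    tn <- nodes[node_types[nodes] == "trait"]
    anch <- intersect(eqtl_genes, nodes)
    if (length(tn) && length(anch))
      forbidden <- expand.grid(from = tn, to = anch,
                               stringsAsFactors = FALSE)
  }
  priors <- make_structure_priors(nodes, eqtl_genes = eqtl_genes,
                                  strong_edges = cit_edges,
                                  forbidden_edges = forbidden)
  if (!is.null(genotypes) && !is.null(eqtl)) {
    num <- vapply(traits[samples, c(continuous_traits, categorical_traits),
                         drop = FALSE], is.numeric, TRUE)
    tv <- t(as.matrix(traits[samples, names(num)[num], drop = FALSE]))
    values <- rbind(expr[, samples, drop = FALSE],
                    metabolites[, samples, drop = FALSE], tv)
    priors <- add_instrument_orientation(priors, values, genotypes, eqtl)
  }
  learn_consensus_network(disc, priors, n_reconstructions, threshold, seed,
                          node_types = node_types, ...)
}
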