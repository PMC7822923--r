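# Key driver analysis on directed networks and the cross-network weighted
# composite ranking.

#' Bounded downstream neighborhood of a node
#'
#' All nodes reachable from `node` by directed paths of length at most
#' `max_path`, excluding the node itself.
#'
#' @param network A `ConsensusCausalNetwork`, igraph, or edge data frame
#'   (from, to).
#' @param node Node name.
#' @param max_path Maximum path length (use `Inf` for all descendants).
#' @return Character vector of downstream nodes.
#' @export
downstream_neighborhood <- function(network, node, max_path = 7) {
  g <- to_igraph(network)
  check_that(node %in% igraph::V(g)$name, paste("unknown node:", node))
  order <- if (is.infinite(max_path)) igraph::vcount(g) else max_path
  nb <- igraph::ego(g, order = order, nodes = node, mode = "out")[[1]]
  setdiff(nb$name, node)
}

to_igraph <- function(network) {
  if (inherits(network, "igraph")) return(network)
  if (inherits(network, "ConsensusCausalNetwork")) return(network_graph(network))
  igraph::graph_from_data_frame(network[, c("from", "to")], directed = TRUE)
}

#' Key driver analysis
#'
#' Every node with a non-empty bounded downstream neighborhood is a
#' candidate; its neighborhood is tested for enrichment of the target set
#' against the network node universe by a one-tailed Fisher
#' (hypergeometric) test, with BH correction across candidates. Key driver
#' genes (KDGs) are candidates at `q <= fdr`.
#'
#' @param network Directed network (see [downstream_neighborhood()]).
#' @param targets Target gene set (e.g. GLD module genes); members outside
#'   the network are intersected away with a message.
#' @param max_path Maximum downstream path length.
#' @param fdr KDG threshold.
#' @return A `KdaResult` data frame: node, n_downstream, overlap, p, q,
#'   kdg; attribute `targets` holds the intersected target set.
#' @export
kda <- function(network, targets, max_path = 7, fdr = 0.05) {
  g <- to_igraph(network)
  universe <- igraph::V(g)$name
  missing <- setdiff(targets, universe)
  if (length(missing))
    message(sprintf("%d target(s) absent from the network were dropped",
                    length(missing)))
  targets <- intersect(targets, universe)
  check_that(length(targets) > 0, "empty target set")
  order <- if (is.infinite(max_path)) length(universe) else max_path
  nbs <- igraph::ego(g, order = order, nodes = universe, mode = "out")
  rows <- list()
  for (i in seq_along(universe)) {
    nb <- setdiff(nbs[[i]]$name, universe[i])
    if (!length(nb)) next
    k <- length(intersect(nb, targets))
    rows[[length(rows) + 1]] <- data.frame(
      node = universe[i], n_downstream = length(nb), overlap = k,
      p = hyper_p(k, length(nb), length(targets), length(universe)),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(node = character(), n_downstream = integer(),
                      overlap = integer(), p = numeric())
  tab$q <- p.adjust(tab$p, method = "BH")
  tab$kdg <- tab$q <= fdr
  tab <- tab[order(tab$p, -tab$n_downstream, tab$node), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "targets") <- targets
  class(tab) <- c("KdaResult", class(tab))
  tab
}

#' Weighted key-driver ranks within one network
#'
#' KDGs are ordered with the least significant first (larger p first; ties
#' on p broken by smaller downstream-target overlap first, then
#' lexicographically) and each receives `position / N_KDG`, so the most
#' significant key driver gets weight exactly 1.
#'
#' @param kda_result A `KdaResult` (or data frame with node, p, overlap,
#'   n_downstream, kdg).
#' @return Named weight vector over KDGs (values in `(0, 1]`).
#' @export
weighted_rank <- function(kda_result) {
  kdgs <- kda_result[kda_result$kdg, , drop = FALSE]
  check_that(nrow(kdgs) >= 1, "no key driver gene to rank")
  # least significant first; p ties resolved by downstream-target count
  # (fewer targets = less significant), then lexicographically
  ord <- kdgs[order(-kdgs$p, kdgs$overlap, kdgs$n_downstream, kdgs$node), ,
              drop = FALSE]
  n <- nrow(ord)
  setNames(seq_len(n) / n, ord$node)
}

#' Composite key-driver score across networks
#'
#' Sums each node's weighted rank over the networks in which it is a key
#' driver (0 elsewhere); the maximum possible score equals the number of
#' networks (most significant KDG in every one).
#'
#' @param weighted_ranks Named list of weight vectors (one per network,
#'   from [weighted_rank()]).
#' @return Data frame (node, score, n_networks) sorted by descending
#'   score.
#' @export
composite_score <- function(weighted_ranks) {
  check_that(length(weighted_ranks) >= 1, "need >= 1 network")
  nodes <- unique(unlist(lapply(weighted_ranks, names)))
  score <- setNames(rep(0, length(nodes)), nodes)
  hits <- setNames(rep(0L, length(nodes)), nodes)
  for (w in weighted_ranks) {
    score[names(w)] <- score[names(w)] + w
    hits[names(w)] <- hits[names(w)] + 1L
  }
  out <- data.frame(node = nodes, score = unname(score),
                    n_networks = unname(hits), stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}
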