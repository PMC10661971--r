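# Pathway co-expression network: build a simplified correlation network
# from a reference activity matrix (or import a precomputed edge list via
# read_network_edges), mask it to the differentially regulated pathways,
# and cluster the masked subnetwork into coordinate pathway groups.

#' Build a pathway co-expression network from reference activity profiles
#'
#' Correlates every pair of pathway activity profiles across reference
#' samples and keeps edges with |correlation| at or above `min_abs_weight`
#' and correlation-test p at or below `max_edge_p`. Edge weights are the
#' signed correlations. This is a simplified co-expression network builder;
#' users with a precomputed reference network can import it with
#' [read_network_edges()] instead.
#'
#' @param reference_act Pathways-by-samples activity matrix from reference
#'   (compendium) data.
#' @param corr_method `"pearson"` or `"spearman"`.
#' @param min_abs_weight Minimum absolute correlation for an edge
#'   (default 0.3).
#' @param max_edge_p Maximum correlation-test p-value for an edge
#'   (default 0.05).
#' @return Undirected igraph with all non-constant pathways as nodes and
#'   `weight`/`p_value` edge attributes.
#' @export
build_reference_network <- function(reference_act,
                                    corr_method = c("pearson", "spearman"),
                                    min_abs_weight = 0.3,
                                    max_edge_p = 0.05) {
  corr_method <- match.arg(corr_method)
  act <- unclass(reference_act)
  stopifnot(is.matrix(act), nrow(act) >= 2L, ncol(act) >= 3L)
  n <- ncol(act)
  if (n < 10L) warning("fewer than 10 reference samples; correlations noisy")
  sdv <- apply(act, 1L, stats::sd)
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " constant activity row(s) excluded from edges")
  }
  keep <- sdv > 0
  act <- act[keep, , drop = FALSE]
  r <- stats::cor(t(act), method = corr_method)
  # two-sided t-approximation p for the correlation test
  rr <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tstat <- rr * sqrt((n - 2) / (1 - rr^2))
  pmat <- 2 * stats::pt(-abs(tstat), n - 2)
  ut <- upper.tri(r)
  sel <- ut & abs(r) >= min_abs_weight & pmat <= max_edge_p
  idx <- which(sel, arr.ind = TRUE)
  edges <- data.frame(
    pathway_a = rownames(r)[idx[, 1]],
    pathway_b = rownames(r)[idx[, 2]],
    weight = r[sel],
    p_value = pmat[sel],
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = rownames(act))
  )
}

#' Mask a network to a set of pathways
#'
#' Induced subgraph on the intersection of `keep` with the network's nodes;
#' isolated nodes are retained.
#'
#' @param net An igraph pathway network.
#' @param keep Character vector of pathway names to retain.
#' @return The induced subgraph.
#' @export
mask_network <- function(net, keep) {
  stopifnot(length(keep) > 0L)
  nodes <- igraph::V(net)$name
  found <- intersect(keep, nodes)
  missing <- setdiff(keep, nodes)
  if (length(found) == 0L) {
    stop("no requested pathway found in the network; first unmatched: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  if (length(missing) > 0L) {
    warning(length(missing), " requested pathway(s) absent from the network")
  }
  igraph::induced_subgraph(net, found)
}

cluster_fun <- function(algorithm) {
  switch(algorithm,
         louvain = igraph::cluster_louvain,
         fast_greedy = igraph::cluster_fast_greedy,
         label_propagation = igraph::cluster_label_prop,
         edge_betweenness = igraph::cluster_edge_betweenness)
}

#' Cluster a pathway network into coordinate groups
#'
#' Runs a community-detection algorithm on the weighted graph. Weights are
#' transformed per `edge_weight_mode` before clustering: `"absolute"` uses
#' |correlation| (the default, so anti-correlated pathways can share a
#' cluster), `"positive_only"` removes negative-weight edges first. For
#' `edge_betweenness`, which treats weights as distances, 1/weight is
#' passed. Clusters smaller than `min_cluster_size` are dropped; surviving
#' clusters are labeled A, B, C, ... by decreasing size (ties broken by the
#' lexicographically smallest member).
#'
#' @param net Undirected igraph with a `weight` edge attribute.
#' @param algorithm One of `"louvain"`, `"fast_greedy"`,
#'   `"label_propagation"`, `"edge_betweenness"`.
#' @param seed Integer RNG seed (louvain and label propagation are
#'   stochastic).
#' @param min_cluster_size Minimum retained cluster size (default 5).
#' @param edge_weight_mode `"absolute"` or `"positive_only"`.
#' @return Named list of pathway-name vectors (one per cluster), with
#'   attributes `algorithm`, `seed`, `min_cluster_size`.
#' @export
cluster_pathways <- function(net,
                             algorithm = c("louvain", "fast_greedy",
                                           "label_propagation",
                                           "edge_betweenness"),
                             seed = 1L, min_cluster_size = 5,
                             edge_weight_mode = c("absolute",
                                                  "positive_only")) {
  algorithm <- match.arg(algorithm)
  edge_weight_mode <- match.arg(edge_weight_mode)
  if (igraph::vcount(net) == 0L) stop("empty graph")
  w <- igraph::E(net)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(net))
  if (edge_weight_mode == "positive_only") {
    drop <- which(w <= 0)
    if (length(drop) > 0L) {
      net <- igraph::delete_edges(net, drop)
      w <- w[-drop]
    }
  } else {
    w <- abs(w)
  }
  g <- net
  if (igraph::ecount(g) > 0L) {
    igraph::E(g)$weight <- if (algorithm == "edge_betweenness") 1 / w else w
  }
  set.seed(seed)
  comm <- if (igraph::ecount(g) > 0L) {
    cluster_fun(algorithm)(g)
  } else {
    NULL
  }
  memb <- if (is.null(comm)) {
    stats::setNames(seq_len(igraph::vcount(g)), igraph::V(g)$name)
  } else {
    stats::setNames(igraph::membership(comm), igraph::V(g)$name)
  }
  groups <- split(names(memb), memb)
  small <- lengths(groups) < min_cluster_size
  if (any(small)) {
    if (all(small)) warning("all clusters below min_cluster_size; empty result")
    else message("dropped ", sum(small), " cluster(s) below min size")
  }
  groups <- groups[!small]
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups),
               vapply(groups, function(g) g[1] %||% "", ""))
  groups <- groups[ord]
  names(groups) <- make_cluster_labels(length(groups))
  structure(groups, algorithm = algorithm, seed = seed,
            min_cluster_size = min_cluster_size,
            edge_weight_mode = edge_weight_mode)
}

make_cluster_labels <- function(n) {
  if (n == 0L) return(character(0))
  labs <- LETTERS
  while (length(labs) < n) {
    labs <- c(labs, paste0(labs[1:26], rep(LETTERS, each = 26))[
      seq_len(min(n - length(labs), 676))])
  }
  labs[seq_len(n)]
}

#' Jaccard similarity between two cluster sets
#'
#' @param a,b Cluster sets (named lists of pathway-name vectors).
#' @return Matrix with entry (i, j) = |A_i intersect B_j| / |A_i union B_j|.
#' @export
jaccard_cluster_similarity <- function(a, b) {
  m <- matrix(0, length(a), length(b),
              dimnames = list(names(a), names(b)))
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      m[i, j] <- length(intersect(a[[i]], b[[j]])) /
        length(union(a[[i]], b[[j]]))
    }
  }
  m
}
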