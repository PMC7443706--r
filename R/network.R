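#' Build a compartment-filtered synapse graph
#'
#' Edge weight from neuron i to neuron j is the number of connector links
#' whose presynaptic node carries the requested source-compartment label on
#' i and whose postsynaptic node carries the target-compartment label on j
#' (e.g. axo-axonic: both `"axon"`). Self-loops are dropped.
#'
#' @param conn a `connectors` table.
#' @param profiles named list of [flow_centrality()] profiles (or any named
#'   list of per-node label vectors named by node id), keyed by neuron id.
#' @param source_compartment,target_compartment compartment labels; `NULL`
#'   disables that side of the filter.
#' @param nodes optional vector of neuron ids to include as graph vertices
#'   (defaults to the neurons appearing in `profiles`, or in `conn` when no
#'   profiles are given).
#' @return directed weighted [igraph::igraph] graph.
#' @export
build_graph <- function(conn, profiles = NULL, source_compartment = NULL,
                        target_compartment = NULL, nodes = NULL) {
  valid <- c("axon", "dendrite", "linker", "soma-fiber")
  for (cc in c(source_compartment, target_compartment))
    if (!cc %in% valid) stop("unknown compartment tag: ", cc)
  lab_of <- function(p) if (inherits(p, "compartment_profile")) p$labels else p
  keep <- rep(TRUE, nrow(conn))
  if (!is.null(source_compartment)) {
    if (is.null(profiles)) stop("compartment filter needs profiles")
    keep <- keep & mapply(function(nrn, nd) {
      labs <- lab_of(profiles[[nrn]])
      !is.null(labs) && identical(unname(labs[as.character(nd)]),
                                  source_compartment)
    }, conn$pre_neuron, conn$pre_node)
  }
  if (!is.null(target_compartment)) {
    if (is.null(profiles)) stop("compartment filter needs profiles")
    keep <- keep & mapply(function(nrn, nd) {
      labs <- lab_of(profiles[[nrn]])
      !is.null(labs) && identical(unname(labs[as.character(nd)]),
                                  target_compartment)
    }, conn$post_neuron, conn$post_node)
  }
  links <- as.data.frame(conn)[keep, , drop = FALSE]
  links <- links[links$pre_neuron != links$post_neuron, , drop = FALSE]
  if (is.null(nodes)) {
    nodes <- if (!is.null(profiles)) names(profiles) else
      unique(c(conn$pre_neuron, conn$post_neuron))
  }
  if (nrow(links)) {
    agg <- stats::aggregate(list(weight = rep(1L, nrow(links))),
                            by = list(from = links$pre_neuron,
                                      to = links$post_neuron),
                            FUN = sum)
  } else {
    agg <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0))
  }
  nodes <- union(nodes, c(agg$from, agg$to))
  igraph::graph_from_data_frame(agg, directed = TRUE,
                                vertices = data.frame(name = nodes))
}

# dense weighted adjacency of a directed igraph
.adjacency <- function(graph) {
  w <- if ("weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL
  as.matrix(igraph::as_adjacency_matrix(graph, attr = w, sparse = FALSE))
}

#' Weighted reciprocity of a directed graph
#'
#' The fraction of reciprocated edge weight: for every unordered node pair
#' the reciprocal portion is `min(w_ij, w_ji)` and the total `w_ij + w_ji`;
#' `r` is the ratio of the two sums over all pairs. A pair with weights 5
#' and 2 contributes 2 reciprocal out of 7 total, so a two-node graph with
#' those weights has r = 2/7 = 0.2857. Under this convention a perfectly
#' symmetric graph has r = 1/2 and a DAG r = 0; low reciprocity indicates a
#' hierarchical (one-way) network.
#'
#' @param graph directed weighted igraph graph (or adjacency matrix).
#' @return r in \[0, 1/2\] for graphs without self-loops.
#' @export
weighted_reciprocity <- function(graph) {
  W <- if (is.matrix(graph)) graph else .adjacency(graph)
  if (sum(W) == 0) stop("graph has no edges")
  diag(W) <- 0
  up <- upper.tri(W)
  recip <- sum(pmin(W[up], t(W)[up]))
  total <- sum(W[up] + t(W)[up])
  recip / total
}

#' Weighted out-degree per node
#' @param graph directed weighted igraph graph.
#' @return named vector: sum of outgoing edge weights per node.
#' @export
weighted_out_degree <- function(graph) {
  igraph::strength(graph, mode = "out", loops = FALSE)
}

#' Local reaching centrality
#'
#' The weighted fraction of the network a node can reach via outgoing
#' edges. Edge weights are first normalized by the global mean edge weight;
#' for each reachable node j the contribution is the mean normalized weight
#' along the path from i to j, and LRC(i) is the sum over reachable j
#' divided by N - 1. Paths are minimum-hop directed paths; among equal-hop
#' alternatives the one maximizing summed weight is used. On a uniform-
#' weight graph this reduces to the plain fraction of reachable nodes, so a
#' complete digraph scores 1 everywhere and any sink scores 0.
#'
#' @param graph directed weighted igraph graph.
#' @return named numeric vector of LRC values, >= 0.
#' @export
local_reaching_centrality <- function(graph) {
  N <- igraph::vcount(graph)
  if (N < 2) stop("need at least two nodes")
  W <- .adjacency(graph)
  mw <- mean(W[W > 0])
  if (!is.finite(mw) || mw == 0) {
    return(stats::setNames(rep(0, N), igraph::V(graph)$name))
  }
  Wn <- W / mw
  vals <- numeric(N)
  for (i in seq_len(N)) {
    # BFS layers with max-weight DP over minimum-hop paths
    hops <- rep.int(NA_integer_, N)
    best <- rep.int(-Inf, N)
    hops[i] <- 0L; best[i] <- 0
    frontier <- i
    d <- 0L
    total <- 0
    while (length(frontier)) {
      d <- d + 1L
      nxt <- integer(0)
      for (v in frontier) {
        out <- which(Wn[v, ] > 0)
        for (u in out) {
          if (is.na(hops[u])) {
            hops[u] <- d
            best[u] <- best[v] + Wn[v, u]
            nxt <- c(nxt, u)
          } else if (hops[u] == d && best[v] + Wn[v, u] > best[u]) {
            best[u] <- best[v] + Wn[v, u]
          }
        }
      }
      nxt <- unique(nxt)
      total <- total + sum(best[nxt] / d)
      frontier <- nxt
    }
    vals[i] <- total / (N - 1)
  }
  stats::setNames(vals, igraph::V(graph)$name)
}

#' Detect communities by weighted modularity optimization
#'
#' Leiden modularity optimization on the weight-collapsed undirected graph
#' (reciprocal edge weights are summed). Isolated nodes are left unassigned
#' (`NA`), mirroring disconnected neurons being excluded from communities.
#'
#' @param graph directed weighted igraph graph.
#' @param seed RNG seed controlling the partition refinement.
#' @param n_iterations Leiden iterations (default 5).
#' @return list with `membership` (named vector, `NA` for isolated nodes),
#'   `modularity` and `n_communities`.
#' @export
detect_communities <- function(graph, seed = 1, n_iterations = 5) {
  if (igraph::vcount(graph) < 2) stop("need at least two nodes")
  und <- igraph::as_undirected(graph, mode = "collapse",
                               edge.attr.comb = list(weight = "sum"))
  set.seed(seed)
  cl <- igraph::cluster_leiden(und, objective_function = "modularity",
                               weights = igraph::E(und)$weight,
                               n_iterations = n_iterations)
  memb <- igraph::membership(cl)
  isolated <- igraph::degree(und) == 0
  mod <- igraph::modularity(und, memb, weights = igraph::E(und)$weight)
  memb <- stats::setNames(as.integer(memb), igraph::V(graph)$name)
  memb[isolated] <- NA_integer_
  list(membership = memb, modularity = mod,
       n_communities = length(unique(memb[!is.na(memb)])))
}

#' Reciprocity of the proximity-based null model
#'
#' Builds the connectivity predicted by presynapse proximity alone: the
#' null edge weight i -> j is the number of i's presynapses within `delta`
#' of j's skeleton ([near_synapses()]), and the null reciprocity is the
#' weighted reciprocity of that graph. Observed reciprocity far below the
#' null indicates directed (hierarchical) wiring not explained by geometry.
#'
#' @param skeletons named list of [skeleton]s.
#' @param conn `connectors` table holding each neuron's presynapses
#'   (positions of connectors with `pre_neuron` = that neuron).
#' @param params a [prediction_params()].
#' @param restrict_nodes optional named list of node-id vectors per neuron
#'   (e.g. axonal nodes only) used both to select presynapses and as the
#'   target point sets.
#' @return list with `reciprocity` and the null `matrix`.
#' @export
proximity_null_reciprocity <- function(skeletons, conn,
                                       params = prediction_params(),
                                       restrict_nodes = NULL) {
  ids <- names(skeletons)
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  upos <- conn[!duplicated(conn$connector_id), , drop = FALSE]
  for (i in ids) {
    rows <- upos$pre_neuron == i
    if (!is.null(restrict_nodes))
      rows <- rows & upos$pre_node %in% restrict_nodes[[i]]
    if (!any(rows)) next
    P <- cbind(upos$x[rows], upos$y[rows], upos$z[rows])
    for (j in ids) {
      if (i == j) next
      K <- skeleton_points(skeletons[[j]],
                           node_ids = if (is.null(restrict_nodes)) NULL
                           else restrict_nodes[[j]])
      if (nrow(K) == 0L) next
      d2 <- .cross_dist2(P, K)
      M[i, j] <- sum(apply(d2, 1, min) <= params$delta^2)
    }
  }
  list(reciprocity = weighted_reciprocity(M), matrix = M)
}

#' Community composition by annotation
#'
#' @param membership community membership (named by neuron id, `NA` =
#'   unassigned; unassigned nodes are skipped).
#' @param annotations named vector of annotations (e.g. odor scene) per
#'   neuron; missing/NA annotations become `"unknown"`.
#' @return list of named fraction vectors, one per community, each summing
#'   to 1.
#' @export
community_fingerprint <- function(membership, annotations) {
  keep <- !is.na(membership)
  memb <- membership[keep]
  ann <- annotations[names(memb)]
  ann[is.na(ann)] <- "unknown"
  lapply(split(ann, memb), function(a) {
    tab <- table(a)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  })
}

#' Weak/strong upstream partner statistics for one target
#'
#' Upstream partners are split at a fraction-of-total-input threshold
#' (weak < threshold, strong >= threshold); the input budget composition is
#' tallied by partner class.
#'
#' @param graph directed weighted igraph graph.
#' @param target neuron id of the target node.
#' @param threshold fraction-of-input cut-off (default 0.01; a 0.015 cut is
#'   conventional when counting uniglomerular PN partners).
#' @param classes optional named vector mapping neuron ids to classes.
#' @return list with `n_weak`, `n_strong`, `fractions` (per partner) and
#'   `composition` (input-budget fraction per class, sums to 1).
#' @export
input_budget_stats <- function(graph, target, threshold = 0.01,
                               classes = NULL) {
  if (!target %in% igraph::V(graph)$name) stop("target not in graph")
  W <- .adjacency(graph)
  w_in <- W[, target]
  w_in <- w_in[w_in > 0]
  if (!length(w_in)) stop("target has zero inputs")
  frac <- w_in / sum(w_in)
  comp <- NULL
  if (!is.null(classes)) {
    cls <- classes[names(w_in)]
    cls[is.na(cls)] <- "unknown"
    comp <- tapply(w_in, cls, sum) / sum(w_in)
    comp <- stats::setNames(as.numeric(comp), names(comp))
  }
  list(n_weak = sum(frac < threshold),
       n_strong = sum(frac >= threshold),
       fractions = frac,
       composition = comp)
}
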