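#' Centrifugal synapse flow centrality and axon/dendrite split
#'
#' For every node the flow centrality is the number of (input, output)
#' synapse pairs whose tree path enters the node's distal subtree through it:
#' `score(v) = (# inputs outside subtree(v)) * (# outputs inside subtree(v))`,
#' with polyadic presynapses (outputs) counted once each. The split node is
#' the argmax (ties resolved towards the root); its distal subtree is the
#' axon and the remaining arbor the dendrite. Synapse-free segments on the
#' direct path from the root to the split node are labelled `linker`, and the
#' initial run of them starting at the root `soma-fiber`.
#'
#' @param skel a [skeleton].
#' @param presyn_nodes node ids carrying presynapses (outputs), one entry per
#'   connector (presynapses counted once regardless of polyadicity).
#' @param postsyn_nodes node ids carrying postsynaptic links (inputs), one
#'   entry per link.
#' @return list of class `compartment_profile`: `scores` (per node),
#'   `split_node`, `labels` (per node: axon/dendrite/linker/soma-fiber),
#'   `splittable`, plus per-compartment synapse/cable summaries from
#'   [synapse_densities()] lazily computable.
#' @export
flow_centrality <- function(skel, presyn_nodes, postsyn_nodes) {
  nd <- skel$nodes
  n <- nrow(nd)
  if (!all(presyn_nodes %in% nd$node_id) ||
      !all(postsyn_nodes %in% nd$node_id))
    stop("synapse node ids not on skeleton")
  n_out_total <- length(presyn_nodes)
  n_in_total <- length(postsyn_nodes)
  out_at <- tabulate(match(presyn_nodes, nd$node_id), nbins = n)
  in_at <- tabulate(match(postsyn_nodes, nd$node_id), nbins = n)
  kids <- .children_index(skel)
  root <- .root_index(skel)
  # post-order accumulation of subtree synapse counts
  order_dfs <- integer(n); stack <- root; k <- 0L
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    k <- k + 1L; order_dfs[k] <- v
    stack <- c(stack, kids[[v]])
  }
  out_sub <- out_at; in_sub <- in_at
  pidx <- .parent_index(skel)
  for (v in rev(order_dfs)) {
    p <- pidx[v]
    if (!is.na(p)) {
      out_sub[p] <- out_sub[p] + out_sub[v]
      in_sub[p] <- in_sub[p] + in_sub[v]
    }
  }
  scores <- (n_in_total - in_sub) * out_sub
  splittable <- n_out_total > 0 && n_in_total > 0 && max(scores) > 0
  labels <- rep("dendrite", n)
  split_node <- NA
  if (splittable) {
    # depth for root-ward tie-breaking
    depth <- integer(n)
    for (v in order_dfs) if (!is.na(pidx[v])) depth[v] <- depth[pidx[v]] + 1L
    best <- which(scores == max(scores))
    split_idx <- best[which.min(depth[best])]
    split_node <- nd$node_id[split_idx]
    axon_ids <- .subtree_ids(skel, split_node)
    labels[match(axon_ids, nd$node_id)] <- "axon"
    # path root -> split node
    path <- split_idx
    while (!is.na(pidx[path[1]])) path <- c(pidx[path[1]], path)
    path <- setdiff(path, split_idx)
    # a path node is linker when its residual subtree (excluding the axon
    # branch) carries no synapses
    syn_sub <- out_sub + in_sub
    on_path <- rep(FALSE, n); on_path[path] <- TRUE
    axon_syn <- syn_sub[split_idx]
    resid <- syn_sub - ifelse(on_path, axon_syn, 0)
    is_linker <- on_path & resid == 0
    labels[is_linker] <- "linker"
    # initial run from the root = soma fiber
    v <- root
    while (!is.na(v) && is_linker[v]) {
      labels[v] <- "soma-fiber"
      nxt <- intersect(kids[[v]], path)
      v <- if (length(nxt)) nxt[1] else NA
    }
  }
  structure(list(neuron_id = skel$neuron_id,
                 node_id = nd$node_id,
                 scores = stats::setNames(scores, nd$node_id),
                 split_node = split_node,
                 labels = stats::setNames(labels, nd$node_id),
                 splittable = splittable,
                 presyn_nodes = presyn_nodes,
                 postsyn_nodes = postsyn_nodes,
                 skeleton = skel),
            class = "compartment_profile")
}

#' @export
print.compartment_profile <- function(x, ...) {
  cat("<compartment_profile> ", x$neuron_id,
      if (!x$splittable) ": un-splittable" else
        paste0(": split at node ", x$split_node), "\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

# inputs/outputs per compartment (axon, dendrite); linker/soma-fiber synapses
# are counted with the compartment they sit in only if labelled so -- by
# construction linker segments carry none
.compartment_counts <- function(profile) {
  labs <- profile$labels
  comp <- c("axon", "dendrite")
  out <- sapply(comp, function(cc) {
    ids <- names(labs)[labs == cc]
    c(n_presyn = sum(as.character(profile$presyn_nodes) %in% ids),
      n_postsyn = sum(as.character(profile$postsyn_nodes) %in% ids))
  })
  t(out)
}

#' Axon/dendrite segregation index
#'
#' Entropy-based polarization score in \[0, 1\]: with `n_i` synapses in
#' compartment `i` and `H_i` the binary entropy of its input:output mix,
#' `SI = 1 - (sum_i (n_i/N) H_i) / H_total`, where `H_total` is the entropy
#' of the whole-cell input:output ratio. 1 = completely polarized (all
#' inputs on the dendrite, all outputs on the axon), 0 = totally
#' unsegregated (same mix in both compartments).
#'
#' @param profile a [flow_centrality()] profile.
#' @return value in \[0, 1\].
#' @export
segregation_index <- function(profile) {
  cts <- .compartment_counts(profile)
  ent <- function(n_in, n_out) {
    n <- n_in + n_out
    if (n == 0) return(0)
    p <- n_in / n
    h <- 0
    if (p > 0) h <- h - p * log(p)
    if (p < 1) h <- h - (1 - p) * log(1 - p)
    h
  }
  N <- sum(cts)
  if (N == 0) stop("no synapses on neuron")
  tot_in <- sum(cts[, "n_postsyn"]); tot_out <- sum(cts[, "n_presyn"])
  h_max <- ent(tot_in, tot_out)
  if (h_max == 0) return(0)  # only one synapse polarity on the whole cell
  s <- sum(apply(cts, 1, function(r) {
    (r["n_presyn"] + r["n_postsyn"]) / N * ent(r["n_postsyn"], r["n_presyn"])
  }))
  1 - s / h_max
}

#' Per-compartment synapse counts, cable and densities
#'
#' Densities are synapses per micrometre of compartment cable. Linker and
#' soma-fiber cable is excluded from the denominators: densities describe
#' the arbors.
#'
#' @param profile a [flow_centrality()] profile.
#' @return data.frame, one row per compartment (axon, dendrite) with
#'   `n_presyn`, `n_postsyn`, `cable_um`, `presyn_density`, `postsyn_density`.
#' @export
synapse_densities <- function(profile) {
  cts <- .compartment_counts(profile)
  labs <- profile$labels
  skel <- profile$skeleton
  cable <- vapply(rownames(cts), function(cc)
    cable_length(skel, names(labs)[labs == cc]), numeric(1))
  data.frame(compartment = rownames(cts),
             n_presyn = cts[, "n_presyn"],
             n_postsyn = cts[, "n_postsyn"],
             cable_um = cable,
             presyn_density = ifelse(cable > 0, cts[, "n_presyn"] / cable, NA),
             postsyn_density = ifelse(cable > 0, cts[, "n_postsyn"] / cable, NA),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Polyadicity statistics of a connector set
#'
#' @param conn a `connectors` table (one row per postsynaptic link).
#' @return list with `mean`, `sem` (NA for a single connector), `n` and
#'   `quantiles` (letter-value style: eighths and quartiles plus extremes).
#' @export
polyadicity_stats <- function(conn) {
  k <- polyadicity(conn)
  if (!length(k)) stop("no connectors")
  sem <- if (length(k) > 1) stats::sd(k) / sqrt(length(k)) else NA_real_
  qs <- stats::quantile(k, c(0, 0.125, 0.25, 0.5, 0.75, 0.875, 1))
  list(mean = mean(k), sem = sem, n = length(k), quantiles = qs)
}

#' Lifetime sparseness of an input-weight vector
#'
#' Selectivity of a neuron's weighted input connectivity across channels
#' (e.g. uniglomerular PN types), in the Rolls-Tovee / Willmore-Tolhurst
#' form: `S = (1 - (sum r / n)^2 / (sum r^2 / n)) / (1 - 1/n)`. 1 for a
#' one-hot vector (maximally selective), 0 for a uniform one. Scale
#' invariant.
#'
#' @param r non-negative weight vector, not all zero, length >= 2.
#' @return value in \[0, 1\].
#' @export
lifetime_sparseness <- function(r) {
  if (any(r < 0)) stop("weights must be non-negative")
  if (all(r == 0)) stop("all-zero weight vector")
  n <- length(r)
  if (n < 2) stop("need at least two channels")
  (1 - (sum(r) / n)^2 / (sum(r^2) / n)) / (1 - 1 / n)
}
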