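#' Configuration for the synthetic toy brain
#'
#' Defines a parameterized antennal-lobe-like brain: Gaussian glomerulus
#' blobs, uni- and multiglomerular projection neurons with soma-rooted
#' backbones splitting into a dendritic arbor (sampling glomeruli with
#' chosen fractional weights) and an axonal arbor in a displaced target
#' region, polyadic presynapses placed along cable, and a planted
#' axo-axonic community/hierarchy structure.
#'
#' Default per-class presynapse densities (1.14/um cholinergic uPN axons,
#' 0.47/um GABAergic PN axons), the axonal postsynapse density (0.19/um)
#' and the mean polyadicity (~12 links per presynapse) follow whole-brain
#' EM measurements of the fly olfactory system.
#'
#' @param n_glomeruli number of glomeruli.
#' @param glomerulus_spacing grid spacing between glomerulus centers (nm).
#' @param glomerulus_sd isotropic sd of each glomerulus blob (nm).
#' @param glomerulus_centers optional matrix of centers (nm); auto-grid
#'   when `NULL`.
#' @param n_upn_per_glom uniglomerular PNs per glomerulus.
#' @param n_mpn multiglomerular PNs.
#' @param mpn_weight_profile optional list of named weight vectors (one per
#'   mPN, non-negative, summing to <= 1); random sparse profiles when `NULL`.
#' @param n_dendrite_points dendritic sample points per PN.
#' @param n_axon_points axonal sample points per PN.
#' @param presyn_density named per-um axonal presynapse rates by class.
#' @param postsyn_density per-um axonal postsynapse rate.
#' @param mean_polyadicity mean postsynaptic links per presynapse.
#' @param link_delta reach (nm) within which generated links attach to
#'   target nodes.
#' @param n_communities planted axo-axonic communities.
#' @param lambda_within,lambda_between mean planted edge weight for ordered
#'   pairs within / between communities.
#' @param reciprocity_target planted weighted reciprocity in \[0, 0.5\]
#'   (0.5 = fully symmetric under the min/total convention).
#' @param n_lhn third-order neurons with dendrites in the target region.
#' @param seed integer seed; identical configs give identical brains.
#' @return list of class `brain_config`.
#' @export
brain_config <- function(n_glomeruli = 4,
                         glomerulus_spacing = 20000,
                         glomerulus_sd = 3000,
                         glomerulus_centers = NULL,
                         n_upn_per_glom = 2,
                         n_mpn = 4,
                         mpn_weight_profile = NULL,
                         n_dendrite_points = 300,
                         n_axon_points = 150,
                         presyn_density = c(uPN_ACh = 1.14, PN_GABA = 0.47),
                         postsyn_density = 0.19,
                         mean_polyadicity = 12,
                         link_delta = 5000,
                         n_communities = 3,
                         lambda_within = 8,
                         lambda_between = 0.5,
                         reciprocity_target = 0.074,
                         n_lhn = 0,
                         seed = 1) {
  stopifnot(n_glomeruli >= 1, glomerulus_sd > 0,
            all(presyn_density >= 0), postsyn_density >= 0,
            mean_polyadicity >= 1, link_delta > 0,
            reciprocity_target >= 0, reciprocity_target <= 0.5)
  if (!is.null(mpn_weight_profile)) {
    ok <- vapply(mpn_weight_profile,
                 function(w) all(w >= 0) && sum(w) <= 1 + 1e-9, logical(1))
    if (!all(ok)) stop("mPN weight vectors must be non-negative, sum <= 1")
  }
  structure(as.list(environment()), class = "brain_config")
}

#' Generate ground-truth glomeruli
#'
#' Glomeruli are isotropic Gaussian blobs; centers come from the config or
#' an automatic 3D grid with the configured spacing.
#'
#' @param config a [brain_config()].
#' @return list with `centers` (matrix, nm), `sd` (nm) and `labels`.
#' @export
generate_glomeruli <- function(config) {
  n <- config$n_glomeruli
  if (!is.null(config$glomerulus_centers)) {
    centers <- as.matrix(config$glomerulus_centers)
  } else {
    side <- ceiling(n^(1 / 3))
    grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                  z = seq_len(side)))[seq_len(n), , drop = FALSE]
    centers <- (grid - 1) * config$glomerulus_spacing
  }
  colnames(centers) <- c("x", "y", "z")
  if (anyDuplicated(round(centers, 6)))
    stop("glomerulus centers must be pairwise distinct")
  labels <- sprintf("G%02d", seq_len(n))
  rownames(centers) <- labels
  list(centers = centers, sd = config$glomerulus_sd, labels = labels)
}

# greedy nearest-neighbour tree: parent index per point (0 = arbor root)
.grow_arbor <- function(root_xyz, pts) {
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  coords <- rbind(root_xyz, matrix(NA_real_, n, 3))
  parent <- integer(n)
  for (i in seq_len(n)) {
    have <- coords[seq_len(i), , drop = FALSE]
    d2 <- (have[, 1] - pts[i, 1])^2 + (have[, 2] - pts[i, 2])^2 +
      (have[, 3] - pts[i, 3])^2
    parent[i] <- which.min(d2) - 1L
    coords[i + 1L, ] <- pts[i, ]
  }
  parent
}

#' Generate one projection neuron
#'
#' The skeleton is a piecewise-linear tree: a soma-rooted fiber runs to a
#' branch point, where it splits into a dendritic arbor (points drawn from
#' the glomerular Gaussians in proportion to `weights`; any remaining mass
#' `1 - sum(weights)` is drawn from a broad background cloud) and, via a
#' linker, an axonal arbor around `axon_center`. Ground-truth compartment
#' labels and the sampling weights are stored on the result.
#'
#' @param glomeruli from [generate_glomeruli()].
#' @param weights named non-negative glomerulus weights summing to <= 1.
#' @param n_dendrite_points dendritic points (> 0).
#' @param axon_center nm triple for the axonal arbor center.
#' @param axon_sd spread of the axonal arbor (nm).
#' @param n_axon_points axonal points.
#' @param neuron_id identifier.
#' @return a [skeleton] with extra fields `truth_labels` (per-node
#'   ground-truth compartment) and `truth_innervation` (the sampling
#'   weights, including an `unassigned` entry).
#' @export
generate_pn <- function(glomeruli, weights, n_dendrite_points = 300,
                        axon_center = c(150000, 0, 0), axon_sd = 8000,
                        n_axon_points = 150, neuron_id = "pn") {
  if (!length(weights)) stop("empty weight vector")
  if (any(weights < 0) || sum(weights) > 1 + 1e-9)
    stop("weights must be non-negative and sum to <= 1")
  if (n_dendrite_points < 1) stop("a PN needs a dendrite: n_dendrite_points >= 1")
  bad <- setdiff(names(weights), glomeruli$labels)
  if (length(bad)) stop("unknown glomeruli in weights: ",
                        paste(bad, collapse = ", "))
  p_un <- max(0, 1 - sum(weights))
  draw <- sample(c(names(weights), "unassigned"), n_dendrite_points,
                 replace = TRUE, prob = c(weights, p_un))
  centers <- glomeruli$centers
  span <- apply(centers, 2, function(v) diff(range(v)))
  dend <- t(vapply(draw, function(g) {
    if (g == "unassigned") {
      # broad background cloud over the whole antennal lobe
      colMeans(centers) + stats::rnorm(3, sd = pmax(span, glomeruli$sd) )
    } else {
      centers[g, ] + stats::rnorm(3, sd = glomeruli$sd)
    }
  }, numeric(3)))
  axon <- cbind(stats::rnorm(n_axon_points, axon_center[1], axon_sd),
                stats::rnorm(n_axon_points, axon_center[2], axon_sd),
                stats::rnorm(n_axon_points, axon_center[3], axon_sd))
  dend_root <- colMeans(dend)
  soma <- dend_root + c(0, 0, -6 * glomeruli$sd)
  n_fiber <- 4L
  fiber <- t(vapply(seq_len(n_fiber), function(i)
    soma + (i / n_fiber) * (dend_root - soma), numeric(3)))
  axon_entry <- axon[1, ]
  n_link <- 4L
  linker <- t(vapply(seq_len(n_link) - 1L, function(i)
    dend_root + (i / n_link) * (axon_entry - dend_root), numeric(3)))[-1, , drop = FALSE]
  dend_parent <- .grow_arbor(dend_root, dend)
  axon_parent <- .grow_arbor(axon_entry, axon[-1, , drop = FALSE])
  # assemble node table; ids are assigned in block order
  # 1 = soma, fiber chain, branch point (= dendrite root), dendrite points,
  # linker chain, axon entry, axon points
  coords <- rbind(soma, fiber, dend, linker, axon, deparse.level = 0)
  n_all <- nrow(coords)
  id_soma <- 1L
  id_fiber <- id_soma + seq_len(n_fiber)           # last fiber node = branch pt
  id_branch <- id_fiber[n_fiber]
  id_dend <- id_branch + seq_len(nrow(dend))
  id_linker <- if (nrow(linker)) max(id_dend) + seq_len(nrow(linker)) else integer(0)
  id_axon_entry <- n_all - nrow(axon) + 1L
  id_axon_rest <- if (nrow(axon) > 1) id_axon_entry + seq_len(nrow(axon) - 1L) else integer(0)
  parent <- integer(n_all)
  parent[id_soma] <- NA
  parent[id_fiber] <- c(id_soma, id_fiber[-n_fiber])
  parent[id_dend] <- ifelse(dend_parent == 0L, id_branch, id_branch + dend_parent)
  if (length(id_linker))
    parent[id_linker] <- c(id_branch, id_linker[-length(id_linker)])
  parent[id_axon_entry] <- if (length(id_linker)) id_linker[length(id_linker)] else id_branch
  if (length(id_axon_rest))
    parent[id_axon_rest] <- ifelse(axon_parent == 0L, id_axon_entry,
                                   id_axon_entry + axon_parent)
  nodes <- data.frame(node_id = seq_len(n_all), parent_id = parent,
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      radius = 100)
  skel <- skeleton(nodes, neuron_id = neuron_id, tags = list(soma = id_soma))
  truth <- rep("dendrite", n_all)
  truth[c(id_soma, id_fiber)] <- "soma-fiber"
  truth[id_branch] <- "linker"
  truth[id_linker] <- "linker"
  truth[c(id_axon_entry, id_axon_rest)] <- "axon"
  skel$truth_labels <- stats::setNames(truth, seq_len(n_all))
  ti <- stats::setNames(rep(0, length(glomeruli$labels)), glomeruli$labels)
  ti[names(weights)] <- weights
  skel$truth_innervation <- c(ti, unassigned = p_un)
  skel
}

#' Generate polyadic synapses from a source neuron onto targets
#'
#' Presynapses are placed by a homogeneous Poisson process along the source
#' neuron's (optionally restricted) cable at `rate` per um; each connector
#' receives `1 + Poisson(mean_polyadicity - 1)` postsynaptic links assigned
#' uniformly among target skeleton nodes within `link_delta` of the
#' presynapse. Presynapses with no target in reach keep zero links and are
#' counted in the `unreached` attribute rather than silently dropped.
#'
#' @param source source [skeleton].
#' @param targets named list of target [skeleton]s.
#' @param rate presynapses per um of cable.
#' @param mean_polyadicity mean links per presynapse (>= 1).
#' @param link_delta link reach in nm.
#' @param source_nodes optional node-id subset of the source (e.g. axon);
#'   presynapses are placed only on edges whose child is in the subset.
#' @param target_nodes optional named list of node-id subsets per target.
#' @param id_prefix connector-id prefix.
#' @return list with `connectors` (a `connectors` table; attribute
#'   `unreached` = number of flagged presynapses) and `counts` (ground-truth
#'   source x target link-count matrix).
#' @export
generate_synapses <- function(source, targets, rate, mean_polyadicity = 12,
                              link_delta = 5000, source_nodes = NULL,
                              target_nodes = NULL, id_prefix = "c") {
  stopifnot(rate >= 0, mean_polyadicity >= 1)
  nd <- source$nodes
  pidx <- .parent_index(source)
  child <- which(!is.na(pidx))
  if (!is.null(source_nodes))
    child <- child[nd$node_id[child] %in% source_nodes]
  counts <- matrix(0, 1, length(targets),
                   dimnames = list(source$neuron_id, names(targets)))
  empty <- as_connectors(data.frame(connector_id = character(0),
                                    pre_neuron = character(0),
                                    pre_node = integer(0),
                                    post_neuron = character(0),
                                    post_node = integer(0),
                                    x = numeric(0), y = numeric(0),
                                    z = numeric(0)))
  if (!length(child) || rate == 0)
    return(list(connectors = empty, counts = counts))
  elen <- sqrt((nd$x[child] - nd$x[pidx[child]])^2 +
                 (nd$y[child] - nd$y[pidx[child]])^2 +
                 (nd$z[child] - nd$z[pidx[child]])^2)
  total_um <- sum(elen) / 1000
  n_pre <- stats::rpois(1, rate * total_um)
  if (n_pre == 0) return(list(connectors = empty, counts = counts))
  eidx <- sample(seq_along(child), n_pre, replace = TRUE, prob = elen)
  frac <- stats::runif(n_pre)
  px <- nd$x[pidx[child][eidx]] + frac * (nd$x[child][eidx] - nd$x[pidx[child][eidx]])
  py <- nd$y[pidx[child][eidx]] + frac * (nd$y[child][eidx] - nd$y[pidx[child][eidx]])
  pz <- nd$z[pidx[child][eidx]] + frac * (nd$z[child][eidx] - nd$z[pidx[child][eidx]])
  pre_node <- nd$node_id[child][eidx]
  # candidate pool: all target nodes with identity
  pool <- do.call(rbind, lapply(names(targets), function(tn) {
    tnd <- targets[[tn]]$nodes
    if (!is.null(target_nodes) && !is.null(target_nodes[[tn]]))
      tnd <- tnd[tnd$node_id %in% target_nodes[[tn]], , drop = FALSE]
    if (!nrow(tnd)) return(NULL)
    data.frame(neuron = tn, node = tnd$node_id,
               x = tnd$x, y = tnd$y, z = tnd$z)
  }))
  rows <- list()
  unreached <- 0L
  for (s in seq_len(n_pre)) {
    k <- 1L + stats::rpois(1, mean_polyadicity - 1)
    cand <- integer(0)
    if (!is.null(pool)) {
      d2 <- (pool$x - px[s])^2 + (pool$y - py[s])^2 + (pool$z - pz[s])^2
      cand <- which(d2 <= link_delta^2)
    }
    if (!length(cand)) {
      unreached <- unreached + 1L
      next
    }
    # each postsynaptic density is a distinct site: links sample candidate
    # nodes without replacement (truncated if the pool is smaller than k)
    picked <- if (length(cand) == 1L) cand else
      sample(cand, min(k, length(cand)))
    rows[[length(rows) + 1L]] <- data.frame(
      connector_id = sprintf("%s%06d", id_prefix, s),
      pre_neuron = source$neuron_id, pre_node = pre_node[s],
      post_neuron = pool$neuron[picked], post_node = pool$node[picked],
      x = px[s], y = py[s], z = pz[s], n_links = 1L)
  }
  if (!length(rows)) {
    conn <- empty
  } else {
    tab <- do.call(rbind, rows)
    for (tn in names(targets)) {
      i <- tab$post_neuron == tn
      counts[1, tn] <- sum(tab$n_links[i])
    }
    conn <- as_connectors(tab[setdiff(names(tab), "n_links")])
  }
  attr(conn, "unreached") <- unreached
  list(connectors = conn, counts = counts)
}

#' Generate a full synthetic brain bundle
#'
#' Builds glomeruli, uniglomerular and multiglomerular PNs, an axo-axonic
#' synapse network realizing a planted community partition with a planted
#' weighted-reciprocity level, optional third-order neurons receiving
#' feedforward synapses, and all ground truth needed to validate the
#' downstream analyses.
#'
#' The planted axo-axonic graph draws ordered-pair weights from Poisson
#' rates (`lambda_within` within communities, `lambda_between` between) and
#' enforces the reciprocity target `t` by setting the back-edge of every
#' pair to `round(rho * w_forward)` with `rho = t / (1 - t)`, which under
#' the min/total reciprocity convention yields r = t in expectation.
#' Community members share an axonal target sub-region so the planted
#' structure is also spatial.
#'
#' @param config a [brain_config()].
#' @return list of class `brain_bundle`: `glomeruli`, `skeletons`,
#'   `connectors` (all links), `conn_axo`, `conn_ff`, `metadata`,
#'   `truth_graph` (axo-axonic count matrix), `truth_partition`,
#'   `truth_innervation`, `truth_labels` (per-neuron node compartments),
#'   `ff_counts`, `config`.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "brain_config"))
  set.seed(config$seed)
  glom <- generate_glomeruli(config)
  n_upn <- config$n_upn_per_glom * config$n_glomeruli
  n_pn <- n_upn + config$n_mpn
  ids <- character(0)
  meta <- list()
  weights_list <- list()
  for (g in glom$labels) {
    for (k in seq_len(config$n_upn_per_glom)) {
      id <- sprintf("uPN_%s_%d", g, k)
      ids <- c(ids, id)
      w <- stats::setNames(1, g)
      weights_list[[id]] <- w
      meta[[id]] <- data.frame(neuron_id = id, class_label = "uPN",
                               transmitter = "ACh", type_name = g,
                               hemisphere = "R", stringsAsFactors = FALSE)
    }
  }
  if (config$n_mpn > 0) {
    profiles <- config$mpn_weight_profile
    for (k in seq_len(config$n_mpn)) {
      id <- sprintf("mPN_%02d", k)
      ids <- c(ids, id)
      if (!is.null(profiles)) {
        w <- profiles[[((k - 1L) %% length(profiles)) + 1L]]
      } else {
        n_g <- min(config$n_glomeruli, 3L)
        gs <- sample(glom$labels, n_g)
        raw <- stats::runif(n_g, 0.5, 1)
        w <- stats::setNames(raw / sum(raw), gs)
      }
      weights_list[[id]] <- w
      meta[[id]] <- data.frame(neuron_id = id, class_label = "mPN",
                               transmitter = "GABA",
                               type_name = sprintf("mPN_type_%02d", k),
                               hemisphere = "R", stringsAsFactors = FALSE)
    }
  }
  # odor scenes annotated per glomerulus; a PN inherits its top glomerulus'
  scenes <- c("pheromonal", "food", "aversive")
  glom_scene <- stats::setNames(scenes[(seq_along(glom$labels) - 1L) %%
                                         length(scenes) + 1L], glom$labels)
  # planted communities share an axonal sub-region in the target neuropil
  part <- stats::setNames(rep(seq_len(config$n_communities), length.out = n_pn),
                          ids)
  part <- stats::setNames(sample(part), ids)  # shuffle assignment
  lh_origin <- c(150000, 0, 0)
  comm_off <- cbind(0, (seq_len(config$n_communities) - 1) * 30000, 0)
  skels <- list()
  for (id in ids) {
    ctr <- lh_origin + comm_off[part[id], ] + stats::rnorm(3, sd = 3000)
    skels[[id]] <- generate_pn(glom, weights_list[[id]],
                               n_dendrite_points = config$n_dendrite_points,
                               axon_center = ctr, axon_sd = 8000,
                               n_axon_points = config$n_axon_points,
                               neuron_id = id)
  }
  metadata <- do.call(rbind, meta)
  metadata$odor_scene <- vapply(ids, function(id) {
    w <- weights_list[[id]]
    glom_scene[[names(w)[which.max(w)]]]
  }, character(1))
  rownames(metadata) <- NULL
  # planted axo-axonic graph with reciprocity target
  t <- config$reciprocity_target
  rho <- if (t >= 0.5) 1 else t / (1 - t)
  Wt <- matrix(0, n_pn, n_pn, dimnames = list(ids, ids))
  for (a in seq_len(n_pn - 1)) {
    for (b in (a + 1):n_pn) {
      lam <- if (part[a] == part[b]) config$lambda_within else config$lambda_between
      wf <- stats::rpois(1, lam)
      if (wf == 0) next
      wb <- round(rho * wf)
      if (stats::runif(1) < 0.5) {
        Wt[a, b] <- wf; Wt[b, a] <- wb
      } else {
        Wt[b, a] <- wf; Wt[a, b] <- wb
      }
    }
  }
  # realize the planted graph as polyadic connectors on axonal cable
  axo_rows <- list()
  cid <- 0L
  for (i in ids) {
    out_w <- Wt[i, ]
    L <- sum(out_w)
    if (L == 0) next
    skel <- skels[[i]]
    axon_ids <- as.integer(names(skel$truth_labels)[skel$truth_labels == "axon"])
    nd <- skel$nodes
    pidx <- .parent_index(skel)
    child <- which(!is.na(pidx) & nd$node_id %in% axon_ids)
    elen <- sqrt((nd$x[child] - nd$x[pidx[child]])^2 +
                   (nd$y[child] - nd$y[pidx[child]])^2 +
                   (nd$z[child] - nd$z[pidx[child]])^2)
    n_conn <- max(1L, round(L / config$mean_polyadicity))
    eidx <- sample(seq_along(child), n_conn, replace = TRUE, prob = elen)
    frac <- stats::runif(n_conn)
    cx <- nd$x[pidx[child][eidx]] + frac * (nd$x[child][eidx] - nd$x[pidx[child][eidx]])
    cy <- nd$y[pidx[child][eidx]] + frac * (nd$y[child][eidx] - nd$y[pidx[child][eidx]])
    cz <- nd$z[pidx[child][eidx]] + frac * (nd$z[child][eidx] - nd$z[pidx[child][eidx]])
    pre_node <- nd$node_id[child][eidx]
    # each outgoing link goes to a uniformly chosen connector of i and lands
    # on the target's axon node nearest to that connector
    link_tgt <- rep(ids, out_w)
    link_conn <- sample.int(n_conn, length(link_tgt), replace = TRUE)
    for (j in unique(link_tgt)) {
      tskel <- skels[[j]]
      t_axon <- as.integer(names(tskel$truth_labels)[tskel$truth_labels == "axon"])
      K <- skeleton_points(tskel, t_axon)
      kid <- t_axon[order(match(t_axon, tskel$nodes$node_id))]
      tnd <- tskel$nodes[tskel$nodes$node_id %in% t_axon, ]
      cs <- link_conn[link_tgt == j]
      tab <- table(cs)
      for (ci in as.integer(names(tab))) {
        n_links <- tab[[as.character(ci)]]
        d2 <- (tnd$x - cx[ci])^2 + (tnd$y - cy[ci])^2 + (tnd$z - cz[ci])^2
        ord <- order(d2)[seq_len(min(n_links, nrow(tnd)))]
        axo_rows[[length(axo_rows) + 1L]] <- data.frame(
          connector_id = sprintf("a%s_%04d", i, ci),
          pre_neuron = i, pre_node = pre_node[ci],
          post_neuron = j, post_node = tnd$node_id[ord],
          x = cx[ci], y = cy[ci], z = cz[ci],
          stringsAsFactors = FALSE)
      }
    }
  }
  conn_axo <- if (length(axo_rows)) as_connectors(do.call(rbind, axo_rows)) else
    as_connectors(data.frame(connector_id = character(0),
                             pre_neuron = character(0), pre_node = integer(0),
                             post_neuron = character(0), post_node = integer(0),
                             x = numeric(0), y = numeric(0), z = numeric(0)))
  realized <- matrix(0, n_pn, n_pn, dimnames = list(ids, ids))
  if (nrow(conn_axo)) {
    agg <- stats::aggregate(list(w = rep(1L, nrow(conn_axo))),
                            by = list(i = conn_axo$pre_neuron,
                                      j = conn_axo$post_neuron), FUN = sum)
    realized[cbind(agg$i, agg$j)] <- agg$w
  }
  # optional third-order neurons receiving feedforward synapses
  lhn_ids <- character(0)
  conn_ff <- NULL
  ff_counts <- NULL
  if (config$n_lhn > 0) {
    for (k in seq_len(config$n_lhn)) {
      id <- sprintf("LHN_%02d", k)
      lhn_ids <- c(lhn_ids, id)
      # dendrite spread across the whole target region: model as a PN-style
      # tree whose "glomerulus" is a single broad blob at the LH
      fake <- list(centers = matrix(lh_origin + c(0, 15000, 0), 1, 3,
                                    dimnames = list("LH", c("x", "y", "z"))),
                   sd = 20000, labels = "LH")
      skels[[id]] <- generate_pn(fake, stats::setNames(1, "LH"),
                                 n_dendrite_points = config$n_dendrite_points,
                                 axon_center = lh_origin + c(0, 0, 80000),
                                 axon_sd = 8000,
                                 n_axon_points = max(20L, config$n_axon_points %/% 3L),
                                 neuron_id = id)
      metadata <- rbind(metadata,
                        data.frame(neuron_id = id, class_label = "LHON",
                                   transmitter = "unknown",
                                   type_name = "LHN", hemisphere = "R",
                                   odor_scene = NA_character_))
    }
    ff_counts <- matrix(0, n_pn, config$n_lhn, dimnames = list(ids, lhn_ids))
    lhn_dend <- lapply(skels[lhn_ids], function(s)
      as.integer(names(s$truth_labels)[s$truth_labels == "dendrite"]))
    ff_list <- list()
    for (i in ids) {
      cls <- metadata$transmitter[metadata$neuron_id == i]
      rate <- if (cls == "ACh") config$presyn_density[["uPN_ACh"]] else
        config$presyn_density[["PN_GABA"]]
      skel <- skels[[i]]
      axon_ids <- as.integer(names(skel$truth_labels)[skel$truth_labels == "axon"])
      gs <- generate_synapses(skel, skels[lhn_ids], rate = rate,
                              mean_polyadicity = config$mean_polyadicity,
                              link_delta = config$link_delta,
                              source_nodes = axon_ids,
                              target_nodes = lhn_dend,
                              id_prefix = sprintf("f%s_", i))
      ff_list[[i]] <- gs$connectors
      ff_counts[i, ] <- gs$counts
    }
    conn_ff <- as_connectors(do.call(rbind, lapply(ff_list, as.data.frame)))
  }
  all_conn <- if (is.null(conn_ff)) conn_axo else
    as_connectors(rbind(as.data.frame(conn_axo), as.data.frame(conn_ff)))
  structure(list(glomeruli = glom,
                 skeletons = skels,
                 connectors = all_conn,
                 conn_axo = conn_axo,
                 conn_ff = conn_ff,
                 metadata = metadata,
                 truth_graph = realized,
                 truth_planted = Wt,
                 truth_partition = part,
                 truth_innervation = do.call(rbind, lapply(skels[ids], function(s)
                   s$truth_innervation)),
                 truth_labels = lapply(skels, function(s) s$truth_labels),
                 ff_counts = ff_counts,
                 config = config),
            class = "brain_bundle")
}

#' @export
print.brain_bundle <- function(x, ...) {
  cat("<brain_bundle> ", length(x$skeletons), " neurons, ",
      x$config$n_glomeruli, " glomeruli, ",
      nrow(x$connectors), " synaptic links\n", sep = "")
  invisible(x)
}
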