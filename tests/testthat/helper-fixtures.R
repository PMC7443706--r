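# fixture builders and independent oracles used across the suite

# random skeleton: n nodes, each attached to a uniformly chosen earlier node
random_tree_skeleton <- function(n, scale = 5000, id = "rnd") {
  parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  skeleton(data.frame(node_id = seq_len(n), parent_id = parent,
                      x = runif(n, 0, scale), y = runif(n, 0, scale),
                      z = runif(n, 0, scale), radius = 50),
           neuron_id = id)
}

# straight chain skeleton along x with given node spacing (nm)
chain_skeleton <- function(n, spacing = 1000, id = "chain", y = 0, z = 0) {
  skeleton(data.frame(node_id = seq_len(n),
                      parent_id = c(NA, seq_len(n - 1L)),
                      x = (seq_len(n) - 1) * spacing, y = y, z = z,
                      radius = 50),
           neuron_id = id)
}

# brute-force edge-sum cable length in um
oracle_cable_length <- function(skel) {
  nd <- skel$nodes
  total <- 0
  for (i in seq_len(nrow(nd))) {
    p <- nd$parent_id[i]
    if (is.na(p)) next
    j <- which(nd$node_id == p)
    total <- total + sqrt(sum((nd[i, c("x", "y", "z")] -
                                 nd[j, c("x", "y", "z")])^2))
  }
  total / 1000
}

# node-id sequence of the tree path between two nodes (via root splice)
.tree_path <- function(skel, from, to) {
  nd <- skel$nodes
  up <- function(v) {
    path <- v
    repeat {
      p <- nd$parent_id[nd$node_id == path[length(path)]]
      if (is.na(p)) break
      path <- c(path, p)
    }
    path
  }
  a <- up(from); b <- up(to)
  lca <- intersect(a, b)[1]
  c(a[seq_len(match(lca, a))], rev(b[seq_len(match(lca, b) - 1L)]))
}

# exhaustive flow-centrality oracle: for each node count (input, output)
# pairs whose tree path arrives at the node from its parent
oracle_flow_centrality <- function(skel, presyn_nodes, postsyn_nodes) {
  nd <- skel$nodes
  scores <- setNames(numeric(nrow(nd)), nd$node_id)
  for (i in postsyn_nodes) {
    for (o in presyn_nodes) {
      path <- .tree_path(skel, i, o)
      if (length(path) < 2L) next  # input and output on the same node
      for (k in 2:length(path)) {
        v <- path[k]
        par <- nd$parent_id[nd$node_id == v]
        if (!is.na(par) && path[k - 1L] == par)
          scores[as.character(v)] <- scores[as.character(v)] + 1
      }
    }
  }
  scores
}

# exhaustive LRC oracle over all simple directed paths (graphs <= 7 nodes):
# minimum-hop path, ties broken by maximum summed weight; edge weights
# normalized by the global mean weight
oracle_lrc <- function(W) {
  N <- nrow(W)
  mw <- mean(W[W > 0])
  Wn <- W / mw
  all_paths <- function(i, j) {
    out <- list()
    rec <- function(path) {
      v <- path[length(path)]
      if (v == j) {
        out[[length(out) + 1L]] <<- path
        return()
      }
      for (u in which(W[v, ] > 0)) if (!u %in% path) rec(c(path, u))
    }
    rec(i)
    out
  }
  vals <- numeric(N)
  for (i in seq_len(N)) {
    tot <- 0
    for (j in seq_len(N)) {
      if (i == j) next
      ps <- all_paths(i, j)
      if (!length(ps)) next
      hops <- vapply(ps, length, integer(1)) - 1L
      ps <- ps[hops == min(hops)]
      wsum <- vapply(ps, function(p) {
        sum(Wn[cbind(p[-length(p)], p[-1])])
      }, numeric(1))
      tot <- tot + max(wsum) / min(hops)
    }
    vals[i] <- tot / (N - 1)
  }
  vals
}

# pairwise min/total weighted reciprocity oracle
oracle_reciprocity <- function(W) {
  diag(W) <- 0
  num <- 0; den <- 0
  n <- nrow(W)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      num <- num + min(W[a, b], W[b, a])
      den <- den + W[a, b] + W[b, a]
    }
  }
  num / den
}

# double-loop overlap score oracle
oracle_overlap <- function(S, K, delta) {
  tot <- 0
  for (s in seq_len(nrow(S)))
    for (k in seq_len(nrow(K)))
      tot <- tot + exp(-sum((S[s, ] - K[k, ])^2) / (2 * delta^2))
  tot
}

# brute-force potential-contact sites with the same single-linkage merge rule
oracle_contacts <- function(S, K, delta, step) {
  q <- which(vapply(seq_len(nrow(S)), function(s)
    any(colSums((t(K) - S[s, ])^2) <= delta^2), logical(1)))
  if (!length(q)) return(0L)
  Q <- S[q, , drop = FALSE]
  groups <- as.list(seq_len(nrow(Q)))
  merged <- TRUE
  while (merged) {
    merged <- FALSE
    for (a in seq_along(groups)) {
      if (is.null(groups[[a]])) next
      for (b in seq_along(groups)) {
        if (a == b || is.null(groups[[b]])) next
        close <- any(vapply(groups[[a]], function(i)
          any(colSums((t(Q[groups[[b]], , drop = FALSE]) - Q[i, ])^2) <=
                (step * (1 + 1e-9))^2), logical(1)))
        if (close) {
          groups[[a]] <- c(groups[[a]], groups[[b]])
          groups[b] <- list(NULL)
          merged <- TRUE
        }
      }
    }
  }
  sum(!vapply(groups, is.null, logical(1)))
}

# two well-separated glomeruli plus an atlas fitted on fresh clouds
two_blob_atlas <- function(n_fit = 400, sd = 3000, spacing = 20000) {
  glom <- generate_glomeruli(brain_config(n_glomeruli = 2,
                                          glomerulus_spacing = spacing,
                                          glomerulus_sd = sd))
  clouds <- lapply(seq_len(2), function(i)
    sweep(matrix(rnorm(n_fit * 3, sd = sd), ncol = 3), 2,
          glom$centers[i, ], "+"))
  names(clouds) <- glom$labels
  list(glomeruli = glom, atlas = fit_atlas(clouds))
}
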