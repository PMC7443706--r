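#' Sorted innervation trace of one neuron
#'
#' The glomerular entries of an innervation-matrix row (the `unassigned`
#' column is dropped) sorted in descending order: top glomerulus first. Ties
#' are broken by glomerulus name so traces are deterministic.
#'
#' @param row named numeric vector over glomeruli (+ optional `unassigned`).
#' @return numeric vector of the same glomerular length, non-increasing.
#' @export
innervation_trace <- function(row) {
  row <- row[setdiff(names(row), "unassigned")]
  ord <- order(-row, names(row))
  unname(row[ord])
}

#' Classify projection neurons from innervation traces
#'
#' Traces are averaged within morphology types, pairwise Euclidean distances
#' between type-average traces are clustered with average linkage, and the
#' tree is cut at k = 2 (superclasses: uniglomerular `uPN` vs multiglomerular
#' `mPN`) and at `k_sub` (subclasses `uni`, `uni+`, `oligo`, `multi`, `pan`).
#' Subclass names are assigned in order of decreasing trace sharpness (mean
#' top-glomerulus score); because hierarchical cuts are nested, subclasses
#' `uni`/`uni+` always sit inside the uPN supercluster.
#'
#' @param traces matrix, one row per neuron, columns = sorted trace entries
#'   (see [innervation_trace()]).
#' @param types morphology-type label per neuron (row). Types are an input:
#'   they may come from synthetic ground truth or any external morphological
#'   clustering tool. Defaults to one type per neuron.
#' @param k_sub number of subclasses to cut (default 5).
#' @return list of class `pn_classification` with `neurons` (data.frame
#'   `neuron_id`, `type`, `subclass`, `superclass`), `type_classes`,
#'   `dendrogram` (the hclust tree over types) and `degenerate` flag.
#' @export
classify_pns <- function(traces, types = NULL, k_sub = 5) {
  traces <- as.matrix(traces)
  if (is.null(rownames(traces)))
    rownames(traces) <- paste0("n", seq_len(nrow(traces)))
  if (is.null(types)) types <- rownames(traces)
  stopifnot(length(types) == nrow(traces))
  if (any(table(types) == 0)) stop("morphology type with no members")
  avg <- t(vapply(split(seq_len(nrow(traces)), types),
                  function(i) colMeans(traces[i, , drop = FALSE]),
                  numeric(ncol(traces))))
  n_types <- nrow(avg)
  if (n_types < 2) stop("need at least two morphology types to classify")
  d <- stats::dist(avg, method = "euclidean")
  degenerate <- max(d) == 0
  hc <- stats::hclust(d, method = "average")
  k_sub <- min(k_sub, n_types)
  sup_cut <- stats::cutree(hc, k = if (degenerate) 1 else 2)
  sub_cut <- stats::cutree(hc, k = if (degenerate) 1 else k_sub)
  sharp <- avg[, 1]  # mean top-glomerulus score per type
  if (degenerate) {
    sup_lab <- stats::setNames("uPN", "1")
    sub_lab <- stats::setNames("uni", "1")
  } else {
    # supercluster with the sharper mean trace = uniglomerular
    sup_mean <- tapply(sharp, sup_cut, mean)
    upn_sup <- names(sup_mean)[which.max(sup_mean)]
    sup_lab <- stats::setNames(ifelse(names(sup_mean) == upn_sup,
                                      "uPN", "mPN"), names(sup_mean))
    # name subclusters by sharpness, respecting nesting in the superclasses
    sub_mean <- tapply(sharp, sub_cut, mean)
    sub_sup <- tapply(sup_cut, sub_cut, function(v) v[1])  # nested cut
    sub_lab <- character(length(sub_mean))
    names(sub_lab) <- names(sub_mean)
    for (side in unique(sup_lab)) {
      ids <- names(sub_mean)[sup_lab[as.character(sub_sup)] == side]
      ids <- ids[order(-sub_mean[ids])]
      pool <- if (side == "uPN") c("uni", "uni+") else c("oligo", "multi", "pan")
      labs <- pool[pmin(seq_along(ids), length(pool))]
      sub_lab[ids] <- labs
    }
  }
  type_classes <- data.frame(
    type = rownames(avg),
    superclass = unname(sup_lab[as.character(sup_cut)]),
    subclass = unname(sub_lab[as.character(sub_cut)]),
    stringsAsFactors = FALSE)
  ti <- match(types, type_classes$type)
  neurons <- data.frame(neuron_id = rownames(traces),
                        type = types,
                        subclass = type_classes$subclass[ti],
                        superclass = type_classes$superclass[ti],
                        stringsAsFactors = FALSE)
  structure(list(neurons = neurons, type_classes = type_classes,
                 dendrogram = hc, degenerate = degenerate),
            class = "pn_classification")
}

#' @export
print.pn_classification <- function(x, ...) {
  cat("<pn_classification> ", nrow(x$neurons), " neurons, ",
      nrow(x$type_classes), " types",
      if (x$degenerate) " (degenerate: all traces identical)", "\n", sep = "")
  print(table(x$neurons$superclass, x$neurons$subclass))
  invisible(x)
}

#' Anatomical transfer function
#'
#' Attributes each neuron's axonal presynapse count fractionally back to
#' glomeruli via its innervation-matrix row: a uniglomerular PN's synapses
#' count 100% towards its glomerulus, a multiglomerular PN's are split in
#' proportion to its dendritic innervation. Mass falling in the `unassigned`
#' column is not attributed to any glomerulus.
#'
#' @param inn_matrix innervation matrix (neurons x glomeruli + unassigned),
#'   rows summing to 1.
#' @param counts axonal presynapse count per neuron, aligned with rows.
#' @param categories optional factor per neuron (e.g. transmitter x uPN/mPN);
#'   the budget is then split into one column per category.
#' @return matrix glomeruli x categories of attributed presynapse counts
#'   (class `transfer_budget`); a single `all` column when no categories.
#' @export
transfer_function <- function(inn_matrix, counts, categories = NULL) {
  inn_matrix <- as.matrix(inn_matrix)
  stopifnot(length(counts) == nrow(inn_matrix))
  if (any(counts < 0)) stop("negative synapse counts")
  glom <- setdiff(colnames(inn_matrix), "unassigned")
  W <- inn_matrix[, glom, drop = FALSE]
  if (is.null(categories)) categories <- rep("all", length(counts))
  categories <- as.character(categories)
  cats <- sort(unique(categories))
  budget <- vapply(cats, function(cc) {
    i <- categories == cc
    drop(crossprod(W[i, , drop = FALSE], counts[i]))
  }, numeric(length(glom)))
  budget <- matrix(budget, nrow = length(glom),
                   dimnames = list(glom, cats))
  class(budget) <- c("transfer_budget", class(budget))
  budget
}

#' Summarise a per-glomerulus synapse budget
#'
#' @param budget matrix from [transfer_function()].
#' @param volumes optional named vector of glomerulus volumes; Pearson
#'   correlation between per-glomerulus totals and volume is reported.
#' @return list with `totals` (per glomerulus), `composition` (fractions per
#'   glomerulus across categories, rows summing to 1 where total > 0),
#'   `pearson_r` and `p_value` (NA when undefined, e.g. constant volumes).
#' @export
budget_summary <- function(budget, volumes = NULL) {
  totals <- rowSums(budget)
  comp <- budget / ifelse(totals > 0, totals, 1)
  r <- NA_real_; p <- NA_real_
  if (!is.null(volumes)) {
    bad <- setdiff(names(volumes), rownames(budget))
    if (length(bad)) stop("volumes for unknown glomeruli: ",
                          paste(bad, collapse = ", "))
    v <- volumes[rownames(budget)]
    if (stats::sd(v) > 0 && stats::sd(totals) > 0) {
      r <- stats::cor(totals, v)
      if (length(v) >= 3)
        p <- stats::cor.test(totals, v, method = "pearson")$p.value
    }
  }
  list(totals = totals, composition = comp, pearson_r = r, p_value = p)
}

# for each leaf pair, the maximum number of clusters k at which the pair is
# still in the same cluster of the cutree(hc, k) partition (0 if never
# together below k = n, i.e. only at the trivial k = n... k runs 2..n-1)
.pair_merge_depth <- function(hc) {
  n <- length(hc$order)
  labs <- hc$labels
  if (is.null(labs)) labs <- as.character(seq_len(n))
  cuts <- stats::cutree(hc, k = seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  depth <- vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    same <- cuts[i, ] == cuts[j, ]
    max(which(same))
  }, numeric(1))
  names(depth) <- paste(labs[pairs[, 1]], labs[pairs[, 2]], sep = "\r")
  depth
}

#' Baker's gamma index between two hierarchical clusterings
#'
#' For every pair of leaves, the maximum number of clusters at which the pair
#' still shares a cluster is recorded for each tree; gamma is the Spearman
#' correlation between the two sets of pair values. The one-sided p value
#' comes from permuting the leaf labels of the second tree.
#'
#' @param hc_a,hc_b `hclust` trees over the same leaf set (>= 3 leaves).
#' @param n_permutations permutations for the null (default 1000).
#' @param seed RNG seed for the permutation null.
#' @return list with `gamma`, `p_value` and the vector of permuted gammas.
#' @export
bakers_gamma <- function(hc_a, hc_b, n_permutations = 1000, seed = 1) {
  la <- hc_a$labels; lb <- hc_b$labels
  if (is.null(la) || is.null(lb) || !setequal(la, lb) ||
      length(la) != length(lb))
    stop("dendrograms must share an identical leaf set")
  if (length(la) < 3) stop("need at least 3 leaves")
  da <- .pair_merge_depth(hc_a)
  db <- .pair_merge_depth(hc_b)
  # align pair keys (order within a pair may differ between trees)
  canon <- function(d) {
    parts <- strsplit(names(d), "\r", fixed = TRUE)
    key <- vapply(parts, function(p) paste(sort(p), collapse = "\r"),
                  character(1))
    stats::setNames(d, key)
  }
  da <- canon(da); db <- canon(db)
  db <- db[names(da)]
  gamma <- stats::cor(da, db, method = "spearman")
  perm <- numeric(n_permutations)
  if (n_permutations > 0) {
    set.seed(seed)
    leaves <- sort(la)
    for (b in seq_len(n_permutations)) {
      relab <- stats::setNames(sample(leaves), leaves)
      parts <- strsplit(names(db), "\r", fixed = TRUE)
      key <- vapply(parts, function(p)
        paste(sort(relab[p]), collapse = "\r"), character(1))
      dbp <- stats::setNames(db, key)[names(da)]
      perm[b] <- stats::cor(da, dbp, method = "spearman")
    }
  }
  p <- if (n_permutations > 0) mean(perm >= gamma) else NA_real_
  list(gamma = gamma, p_value = p, permuted = perm)
}
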