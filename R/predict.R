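#' Prediction parameters for morphology-based connectivity models
#'
#' @param delta distance (nm) at which a synapse might occur between two
#'   points; the field default 1210 nm is the 90% quantile of observed
#'   presynapse-to-target distances in a whole-brain EM dataset (see
#'   [calibrate_delta()]).
#' @param resample_step skeleton resampling interval in nm (default 1 um).
#' @param quantile quantile used by [calibrate_delta()] (default 0.90).
#' @return list of class `prediction_params`.
#' @export
prediction_params <- function(delta = 1210, resample_step = 1000,
                              quantile = 0.90) {
  stopifnot(delta > 0, resample_step > 0, quantile > 0, quantile < 1)
  structure(list(delta = delta, resample_step = resample_step,
                 quantile = quantile), class = "prediction_params")
}

.as_points <- function(x, step) {
  if (inherits(x, "skeleton")) resample_points(x, step) else as.matrix(x)
}

#' Overlap score between an axon and a dendrite
#'
#' Both arbors are resampled to evenly spaced points and the score is
#' `sum_s sum_k exp(-d(s,k)^2 / (2 delta^2))` over all source points `s` and
#' target points `k`, `d` the Euclidean distance. Symmetric in the point
#' clouds, but by convention the source is the axonal arbor of the upstream
#' candidate and the target the dendritic arbor of the downstream one.
#'
#' @param source axonal [skeleton] (or point matrix, used as is).
#' @param target dendritic [skeleton] (or point matrix).
#' @param params a [prediction_params()].
#' @return numeric score >= 0.
#' @export
overlap_score <- function(source, target, params = prediction_params()) {
  S <- .as_points(source, params$resample_step)
  K <- .as_points(target, params$resample_step)
  if (nrow(S) == 0L || nrow(K) == 0L) {
    warning("empty point cloud; overlap score 0")
    return(0)
  }
  total <- 0
  chunk <- 2000L
  for (start in seq(1L, nrow(S), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(S))
    d2 <- .cross_dist2(S[idx, , drop = FALSE], K)
    total <- total + sum(exp(-d2 / (2 * params$delta^2)))
  }
  total
}

#' Calibrate delta from observed connections
#'
#' For every observed postsynaptic link, the distance from the presynapse
#' position to the nearest skeleton node of the downstream neuron is
#' measured; delta is the given quantile of those distances.
#'
#' @param conn a `connectors` table of observed links.
#' @param skeletons named list of [skeleton]s covering the postsynaptic
#'   neurons.
#' @param quantile quantile (default 0.90).
#' @return delta in nm.
#' @export
calibrate_delta <- function(conn, skeletons, quantile = 0.90) {
  if (nrow(conn) < 10) stop("need >= 10 observed connections to calibrate")
  targets <- unique(conn$post_neuron)
  missing_t <- setdiff(targets, names(skeletons))
  if (length(missing_t)) stop("missing skeletons for: ",
                              paste(missing_t, collapse = ", "))
  d <- numeric(nrow(conn))
  for (tn in targets) {
    i <- which(conn$post_neuron == tn)
    P <- cbind(conn$x[i], conn$y[i], conn$z[i])
    K <- skeleton_points(skeletons[[tn]])
    d[i] <- sqrt(apply(.cross_dist2(P, K), 1, min))
  }
  stats::quantile(d, quantile, names = FALSE)
}

#' Potential synaptic contact sites between an axon and a dendrite
#'
#' Counts resampled source points that lie within `delta` of at least one
#' target point. Qualifying points closer than `resample_step` to each other
#' are merged (single linkage) into one contact site; both the merged site
#' count and the raw qualifying-point count are returned.
#'
#' @inheritParams overlap_score
#' @return list with `sites` (merged count) and `points` (raw count).
#' @export
potential_contacts <- function(source, target, params = prediction_params()) {
  S <- .as_points(source, params$resample_step)
  K <- .as_points(target, params$resample_step)
  if (nrow(S) == 0L || nrow(K) == 0L) return(list(sites = 0L, points = 0L))
  near <- rep(FALSE, nrow(S))
  chunk <- 2000L
  for (start in seq(1L, nrow(S), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(S))
    d2 <- .cross_dist2(S[idx, , drop = FALSE], K)
    near[idx] <- apply(d2, 1, min) <= params$delta^2
  }
  q <- which(near)
  if (!length(q)) return(list(sites = 0L, points = 0L))
  Q <- S[q, , drop = FALSE]
  # single-linkage components among qualifying points within resample_step
  # (consecutive resampled points sit at exactly the step, so the bound is
  # inclusive with a small numerical tolerance)
  adj <- .cross_dist2(Q, Q) <= (params$resample_step * (1 + 1e-9))^2
  comp <- seq_len(nrow(Q))
  repeat {
    new <- vapply(seq_len(nrow(Q)),
                  function(i) min(comp[adj[i, ]]), numeric(1))
    if (all(new == comp)) break
    comp <- new
  }
  list(sites = length(unique(comp)), points = length(q))
}

#' Presynapses within range of a target neuron
#'
#' Counts source presynapses whose distance to the nearest target skeleton
#' node is at most `delta`; each such presynapse is predicted to connect.
#'
#' @param presyn_positions matrix of presynapse positions (nm), or a
#'   `connectors` table (unique connector positions are used).
#' @param target target [skeleton].
#' @param params a [prediction_params()].
#' @return predicted count (number of presynapses in range).
#' @export
near_synapses <- function(presyn_positions, target,
                          params = prediction_params()) {
  if (inherits(presyn_positions, "connectors") ||
      (is.data.frame(presyn_positions) &&
       "connector_id" %in% names(presyn_positions))) {
    u <- !duplicated(presyn_positions$connector_id)
    presyn_positions <- cbind(presyn_positions$x[u], presyn_positions$y[u],
                              presyn_positions$z[u])
  }
  P <- as.matrix(presyn_positions)
  if (nrow(P) == 0L) return(0L)
  K <- skeleton_points(target)
  d2 <- .cross_dist2(P, K)
  sum(apply(d2, 1, min) <= params$delta^2)
}

#' Cosine similarity between predicted and observed connectivity
#'
#' @param predicted,observed non-negative matrices with identical source and
#'   target axes.
#' @param groups optional grouping factor over targets (columns), e.g.
#'   downstream neuron class; similarity is reported per group.
#' @return named vector of cosine similarities in \[0, 1\]; NA (with a
#'   warning) where either vector is all-zero.
#' @export
prediction_similarity <- function(predicted, observed, groups = NULL) {
  predicted <- as.matrix(predicted); observed <- as.matrix(observed)
  stopifnot(all(dim(predicted) == dim(observed)))
  if (is.null(groups)) groups <- rep("all", ncol(predicted))
  stopifnot(length(groups) == ncol(predicted))
  vapply(split(seq_len(ncol(predicted)), groups), function(j) {
    p <- as.vector(predicted[, j]); o <- as.vector(observed[, j])
    np <- sqrt(sum(p^2)); no <- sqrt(sum(o^2))
    if (np == 0 || no == 0) {
      warning("zero connectivity vector in group; similarity undefined")
      return(NA_real_)
    }
    sum(p * o) / (np * no)
  }, numeric(1))
}

#' Filling fraction of predicted near synapses
#'
#' For each neuron pair the filling fraction is the observed synapse count
#' divided by the near-synapse (potential) count, a proportion in \[0, 1\]
#' since the prediction is a superset of the observation. Group statistics
#' are near-synapse-weighted means and SDs; pairs with zero predicted
#' synapses are excluded (and counted in `n_excluded`).
#'
#' @param near_counts,observed_counts aligned per-pair vectors.
#' @param groups grouping factor per pair (e.g. target class).
#' @return data.frame per group: `group`, `mean`, `sd`, `n`, `n_excluded`.
#' @export
filling_fraction <- function(near_counts, observed_counts, groups = NULL) {
  stopifnot(length(near_counts) == length(observed_counts))
  if (is.null(groups)) groups <- rep("all", length(near_counts))
  keep <- near_counts > 0
  res <- lapply(split(seq_along(near_counts), groups), function(i) {
    use <- i[keep[i]]
    if (!length(use))
      return(data.frame(mean = NA_real_, sd = NA_real_, n = 0L,
                        n_excluded = length(i)))
    f <- observed_counts[use] / near_counts[use]
    w <- near_counts[use]
    m <- sum(w * f) / sum(w)
    v <- sum(w * (f - m)^2) / sum(w)
    data.frame(mean = m, sd = sqrt(v), n = length(use),
               n_excluded = length(i) - length(use))
  })
  out <- do.call(rbind, res)
  out <- cbind(group = names(res), out)
  rownames(out) <- NULL
  out
}

#' Weighted two-sample t test for filling fractions
#'
#' Welch-style t test on weighted group means, with effective sample sizes
#' `n_eff = (sum w)^2 / sum w^2`.
#'
#' @param x,y per-pair fractions in the two groups.
#' @param wx,wy weights (near-synapse counts).
#' @return list with `statistic`, `df`, `p_value` (two-sided).
#' @export
weighted_t_test <- function(x, wx, y, wy) {
  wm <- function(v, w) sum(w * v) / sum(w)
  wv <- function(v, w) {
    m <- wm(v, w)
    sum(w * (v - m)^2) / sum(w)
  }
  neff <- function(w) sum(w)^2 / sum(w^2)
  mx <- wm(x, wx); my <- wm(y, wy)
  vx <- wv(x, wx); vy <- wv(y, wy)
  nx <- neff(wx); ny <- neff(wy)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df))
}
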