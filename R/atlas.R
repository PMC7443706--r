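#' Fit a probabilistic glomerulus atlas
#'
#' Each glomerulus is modelled as a 3D Gaussian kernel density estimate over
#' a labelled point cloud (typically dendritic points of known uniglomerular
#' projection neurons). Points are later assigned to the glomerulus whose
#' density is highest, or left unassigned when every density falls below a
#' probability threshold.
#'
#' The kernel is isotropic in nm space. The default bandwidth follows a
#' Scott-style rule on the pooled per-glomerulus clouds:
#' `h = mean within-glomerulus per-axis sd * n^(-1/7)` (d = 3). The default
#' threshold is the density below which 5% of the fitting points fall under
#' their own glomerulus KDE, so 95% of training points stay assigned.
#'
#' @param clouds named list of point matrices (columns x, y, z, nm), one per
#'   glomerulus; every cloud needs >= 10 points.
#' @param bandwidth kernel sd in nm; `NULL` for the Scott-style default.
#' @param threshold density cut-off; `NULL` for the 5%-quantile default.
#' @return object of class `glomerulus_atlas`.
#' @export
fit_atlas <- function(clouds, bandwidth = NULL, threshold = NULL) {
  if (!length(clouds)) stop("need at least one glomerulus cloud")
  if (is.null(names(clouds)) || anyDuplicated(names(clouds)))
    stop("clouds must be uniquely named by glomerulus")
  clouds <- lapply(clouds, function(p) {
    p <- as.matrix(p)[, 1:3, drop = FALSE]
    colnames(p) <- c("x", "y", "z")
    p
  })
  sizes <- vapply(clouds, nrow, integer(1))
  if (any(sizes < 10))
    stop("every glomerulus needs >= 10 points; too few for: ",
         paste(names(clouds)[sizes < 10], collapse = ", "))
  if (is.null(bandwidth)) {
    sds <- vapply(clouds, function(p) mean(apply(p, 2, stats::sd)), numeric(1))
    n <- sum(sizes)
    bandwidth <- mean(sds) * n^(-1 / 7)
  }
  if (bandwidth <= 0) stop("bandwidth must be positive")
  atlas <- structure(list(glomeruli = clouds, bandwidth = bandwidth,
                          threshold = 0),
                     class = "glomerulus_atlas")
  if (is.null(threshold)) {
    # leave-one-out self-densities: subtracting each point's own kernel
    # calibrates the quantile for fresh points rather than fitting points
    self <- unlist(lapply(names(clouds), function(g) {
      n_g <- nrow(clouds[[g]])
      own <- 1 / (n_g * (2 * pi)^(3 / 2) * bandwidth^3)
      d <- .kde_density(clouds[[g]], clouds[[g]], bandwidth) - own
      pmax(d, 0) * n_g / max(1, n_g - 1)
    }))
    threshold <- stats::quantile(self, 0.05, names = FALSE)
  }
  atlas$threshold <- threshold
  atlas
}

#' @export
print.glomerulus_atlas <- function(x, ...) {
  cat("<glomerulus_atlas> ", length(x$glomeruli), " glomeruli, bandwidth ",
      format(x$bandwidth, digits = 4), " nm, threshold ",
      format(x$threshold, digits = 4), "\n", sep = "")
  invisible(x)
}

# Gaussian KDE density of `centers` evaluated at `pts`; isotropic sd = h.
# Chunked over evaluation points to bound memory.
.kde_density <- function(pts, centers, h, chunk = 2000L) {
  pts <- as.matrix(pts)
  if (nrow(pts) == 0L) return(numeric(0))
  const <- 1 / (nrow(centers) * (2 * pi)^(3 / 2) * h^3)
  out <- numeric(nrow(pts))
  for (start in seq(1L, nrow(pts), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(pts))
    d2 <- .cross_dist2(pts[idx, , drop = FALSE], centers)
    out[idx] <- const * rowSums(exp(-d2 / (2 * h^2)))
  }
  out
}

#' Evaluate per-glomerulus KDE densities at points
#' @param atlas fitted [fit_atlas()] object.
#' @param points matrix with columns x, y, z (nm).
#' @return matrix points x glomeruli of densities.
#' @export
atlas_density <- function(atlas, points) {
  stopifnot(inherits(atlas, "glomerulus_atlas"))
  points <- as.matrix(points)
  dens <- vapply(atlas$glomeruli,
                 function(cl) .kde_density(points, cl, atlas$bandwidth),
                 numeric(nrow(points)))
  if (nrow(points) == 1L) dens <- matrix(dens, nrow = 1,
                                         dimnames = list(NULL, names(atlas$glomeruli)))
  dens
}

#' Assign points to glomeruli
#'
#' Each point gets the label of the glomerulus with the highest kernel
#' density, or `"unassigned"` when the maximum density is below the atlas
#' threshold.
#'
#' @inheritParams atlas_density
#' @return character vector of labels, one per point.
#' @export
assign_points <- function(atlas, points) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) return(character(0))
  dens <- atlas_density(atlas, points)
  best <- max.col(dens, ties.method = "first")
  lab <- names(atlas$glomeruli)[best]
  lab[dens[cbind(seq_len(nrow(dens)), best)] < atlas$threshold] <- "unassigned"
  lab
}

#' Score fractional dendritic innervation of one neuron
#'
#' For every dendritic point, the per-glomerulus densities are normalized to
#' probabilities (points below threshold carry all their mass in the
#' `unassigned` column); probabilities are summed per glomerulus and divided
#' by the number of points, so the row sums to 1.
#'
#' @inheritParams atlas_density
#' @param points dendritic point cloud of one neuron (nm).
#' @return named numeric vector over glomeruli plus `"unassigned"`; sums to 1.
#' @export
innervation_scores <- function(atlas, points) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("empty dendritic point cloud")
  dens <- atlas_density(atlas, points)
  below <- apply(dens, 1, max) < atlas$threshold
  prob <- dens / pmax(rowSums(dens), .Machine$double.xmin)
  prob[below, ] <- 0
  row <- c(colSums(prob), unassigned = sum(below)) / nrow(points)
  row
}

#' Innervation matrix for a set of neurons
#'
#' @inheritParams atlas_density
#' @param clouds named list of dendritic point clouds, one per neuron.
#' @return matrix neurons x (glomeruli + unassigned); rows sum to 1.
#' @export
innervation_matrix <- function(atlas, clouds) {
  rows <- t(vapply(clouds, function(p) innervation_scores(atlas, p),
                   numeric(length(atlas$glomeruli) + 1L)))
  rownames(rows) <- names(clouds)
  rows
}

#' Validate an atlas against labelled points
#'
#' @inheritParams atlas_density
#' @param points labelled point matrix.
#' @param labels true glomerulus per point; must be atlas glomeruli.
#' @return named vector of percentages `correct`, `incorrect`, `unassigned`
#'   summing to 100.
#' @export
validate_atlas <- function(atlas, points, labels) {
  points <- as.matrix(points)
  stopifnot(nrow(points) == length(labels))
  bad <- setdiff(unique(labels), names(atlas$glomeruli))
  if (length(bad)) stop("labels not in atlas: ", paste(bad, collapse = ", "))
  pred <- assign_points(atlas, points)
  n <- length(labels)
  c(correct = 100 * sum(pred == labels) / n,
    incorrect = 100 * sum(pred != labels & pred != "unassigned") / n,
    unassigned = 100 * sum(pred == "unassigned") / n)
}
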