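#' Construct a neuron skeleton
#'
#' A skeleton is a rooted tree of 3D nodes representing one neuron's cable.
#' Coordinates are stored in nanometres throughout; cable lengths and synapse
#' densities are reported in micrometres where that is the field convention.
#'
#' @param nodes data.frame with columns `node_id`, `parent_id` (`NA` or -1 for
#'   the root), `x`, `y`, `z` (nm) and optionally `radius` (nm) and `type`
#'   (SWC structure code, preserved but unused).
#' @param neuron_id identifier for the neuron.
#' @param tags named list mapping labels (e.g. `"soma"`) to node ids.
#' @return An object of class `skeleton`.
#' @export
skeleton <- function(nodes, neuron_id = "neuron", tags = list()) {
  stopifnot(is.data.frame(nodes))
  req <- c("node_id", "parent_id", "x", "y", "z")
  missing_cols <- setdiff(req, names(nodes))
  if (length(missing_cols))
    stop("missing skeleton columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(nodes) == 0L) stop("a skeleton needs at least one node")
  if (!"radius" %in% names(nodes)) nodes$radius <- -1
  if (!"type" %in% names(nodes)) nodes$type <- 0L
  nodes$parent_id[!is.na(nodes$parent_id) & nodes$parent_id == -1] <- NA
  if (anyDuplicated(nodes$node_id)) stop("duplicate node ids")
  root <- which(is.na(nodes$parent_id))
  if (length(root) != 1L)
    stop("skeleton must have exactly one root, found ", length(root))
  known <- nodes$parent_id %in% nodes$node_id | is.na(nodes$parent_id)
  if (!all(known))
    stop("parent_id refers to absent node(s): ",
         paste(unique(nodes$parent_id[!known]), collapse = ", "))
  # acyclicity + connectivity: walking parent pointers from every node must
  # reach the root in < n steps
  idx <- match(nodes$parent_id, nodes$node_id)
  n <- nrow(nodes)
  depth <- rep.int(NA_integer_, n)
  depth[root] <- 0L
  for (pass in seq_len(n)) {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    ready <- todo[!is.na(depth[idx[todo]])]
    if (!length(ready)) stop("skeleton contains a cycle or disconnected nodes")
    depth[ready] <- depth[idx[ready]] + 1L
  }
  for (tag in names(tags)) {
    if (!all(unlist(tags[[tag]]) %in% nodes$node_id))
      stop("tag '", tag, "' refers to a node that does not exist")
  }
  rownames(nodes) <- NULL
  structure(list(neuron_id = neuron_id,
                 nodes = nodes[c("node_id", "parent_id", "type",
                                 "x", "y", "z", "radius")],
                 tags = tags),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat("<skeleton> ", x$neuron_id, ": ", nrow(x$nodes), " nodes, ",
      format(cable_length(x), digits = 4), " um cable\n", sep = "")
  invisible(x)
}

# index of each node's parent row (NA at root)
.parent_index <- function(skel) match(skel$nodes$parent_id, skel$nodes$node_id)

# list of child row indices per node row
.children_index <- function(skel) {
  pidx <- .parent_index(skel)
  n <- nrow(skel$nodes)
  kids <- vector("list", n)
  ok <- which(!is.na(pidx))
  sp <- split(ok, pidx[ok])
  kids[as.integer(names(sp))] <- sp
  kids
}

# row index of the root node
.root_index <- function(skel) which(is.na(skel$nodes$parent_id))

# node ids of the subtree rooted at `node_id` (inclusive), iterative DFS
.subtree_ids <- function(skel, node_id) {
  kids <- .children_index(skel)
  start <- match(node_id, skel$nodes$node_id)
  if (is.na(start)) stop("unknown node id: ", node_id)
  stack <- start
  seen <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    seen <- c(seen, v)
    stack <- c(stack, kids[[v]])
  }
  skel$nodes$node_id[seen]
}

#' Read a skeleton from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`, `#` comments,
#' parent -1 marks the root). Coordinates are interpreted as nanometres.
#'
#' @param path file path.
#' @param neuron_id identifier to attach; defaults to the file base name.
#' @return A [skeleton].
#' @export
read_swc <- function(path, neuron_id = NULL) {
  if (is.null(neuron_id))
    neuron_id <- sub("\\.swc$", "", basename(path), ignore.case = TRUE)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("node_id", "type", "x", "y", "z",
                                         "radius", "parent_id"),
                           colClasses = c("integer", "integer", "numeric",
                                          "numeric", "numeric", "numeric",
                                          "integer"))
  skeleton(tab, neuron_id = neuron_id)
}

#' Write a skeleton to an SWC file
#'
#' Inverse of [read_swc()]: node ids, parents, coordinates and radii are
#' preserved field for field.
#'
#' @param skel a [skeleton].
#' @param path output file path.
#' @export
write_swc <- function(skel, path) {
  stopifnot(inherits(skel, "skeleton"))
  nd <- skel$nodes
  parent <- ifelse(is.na(nd$parent_id), -1L, nd$parent_id)
  lines <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                   nd$node_id, nd$type, nd$x, nd$y, nd$z, nd$radius, parent)
  writeLines(c("# id type x y z radius parent", lines), con = path)
  invisible(path)
}

#' Read a polyadic connector table
#'
#' One row per postsynaptic link; rows sharing a `connector_id` belong to the
#' same polyadic presynapse. The presynapse position (`x`, `y`, `z`, nm) is
#' the position of the presynaptic site.
#'
#' @param path CSV with columns `connector_id`, `pre_neuron`, `pre_node`,
#'   `post_neuron`, `post_node`, `x`, `y`, `z`.
#' @return data.frame of class `connectors` (one row per link).
#' @export
read_connectors <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_connectors(tab)
}

#' Validate a connector link table
#'
#' @param tab data.frame with the connector columns (see [read_connectors()]).
#' @return the validated table with class `connectors`.
#' @export
as_connectors <- function(tab) {
  req <- c("connector_id", "pre_neuron", "pre_node",
           "post_neuron", "post_node", "x", "y", "z")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("missing connector columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(tab)) {
    key <- paste(tab$connector_id, tab$post_neuron, tab$post_node, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (connector_id, post_neuron, post_node) rows")
    # a connector has a single presynaptic site
    pre <- unique(tab[c("connector_id", "pre_neuron", "pre_node")])
    if (anyDuplicated(pre$connector_id))
      stop("connector_id with inconsistent presynaptic site")
  }
  class(tab) <- c("connectors", "data.frame")
  tab
}

#' Write a connector table to CSV
#' @param conn a `connectors` table.
#' @param path output path.
#' @export
write_connectors <- function(conn, path) {
  utils::write.csv(as.data.frame(conn), path, row.names = FALSE)
  invisible(path)
}

#' Number of postsynaptic links per connector
#' @param conn a `connectors` table.
#' @return named integer vector, one entry per connector_id.
#' @export
polyadicity <- function(conn) {
  if (nrow(conn) == 0L) return(integer(0))
  tab <- table(conn$connector_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Cable length of a skeleton
#'
#' Sum of parent-child Euclidean distances, reported in micrometres.
#'
#' @param skel a [skeleton].
#' @param node_ids optional node ids; only edges whose *child* is in the
#'   subset are counted, so the length is additive over disjoint subsets.
#' @return length in um.
#' @export
cable_length <- function(skel, node_ids = NULL) {
  nd <- skel$nodes
  pidx <- .parent_index(skel)
  child <- which(!is.na(pidx))
  if (!is.null(node_ids)) child <- child[nd$node_id[child] %in% node_ids]
  if (!length(child)) return(0)
  dx <- nd$x[child] - nd$x[pidx[child]]
  dy <- nd$y[child] - nd$y[pidx[child]]
  dz <- nd$z[child] - nd$z[pidx[child]]
  sum(sqrt(dx^2 + dy^2 + dz^2)) / 1000
}

#' Resample a skeleton into an evenly spaced point cloud
#'
#' Every parent-child edge is subdivided so consecutive points are at most
#' `step` apart along any root-to-leaf path. All original nodes (branch
#' points, end points) are kept, so the gaps sum exactly to the cable length.
#'
#' @param skel a [skeleton].
#' @param step spacing in nm (default 1000 = 1 um).
#' @return matrix with columns x, y, z (nm) and attribute `node_id` giving,
#'   for each point, the id of the child node of the edge it lies on (the
#'   node itself for original nodes).
#' @export
resample_points <- function(skel, step = 1000) {
  if (step <= 0) stop("step must be positive")
  nd <- skel$nodes
  pidx <- .parent_index(skel)
  child <- which(!is.na(pidx))
  pts <- list(cbind(x = nd$x, y = nd$y, z = nd$z))
  ids <- list(nd$node_id)
  for (i in child) {
    p <- pidx[i]
    d <- sqrt((nd$x[i] - nd$x[p])^2 + (nd$y[i] - nd$y[p])^2 +
                (nd$z[i] - nd$z[p])^2)
    nseg <- ceiling(d / step)
    if (nseg > 1) {
      f <- seq_len(nseg - 1) / nseg
      pts[[length(pts) + 1L]] <-
        cbind(x = nd$x[p] + f * (nd$x[i] - nd$x[p]),
              y = nd$y[p] + f * (nd$y[i] - nd$y[p]),
              z = nd$z[p] + f * (nd$z[i] - nd$z[p]))
      ids[[length(ids) + 1L]] <- rep.int(nd$node_id[i], nseg - 1L)
    }
  }
  out <- do.call(rbind, pts)
  attr(out, "node_id") <- unlist(ids, use.names = FALSE)
  out
}

#' Node coordinates of a skeleton as a matrix
#' @param skel a [skeleton].
#' @param node_ids optional subset of node ids.
#' @return matrix with columns x, y, z (nm).
#' @export
skeleton_points <- function(skel, node_ids = NULL) {
  nd <- skel$nodes
  if (!is.null(node_ids)) nd <- nd[nd$node_id %in% node_ids, ]
  cbind(x = nd$x, y = nd$y, z = nd$z)
}

# squared Euclidean cross-distances between rows of A (n x 3) and B (m x 3)
.cross_dist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Read a neuron metadata table
#'
#' @param path CSV with columns `neuron_id`, `class_label`, `transmitter`,
#'   `type_name`, `hemisphere` and optionally `odor_scene`.
#' @return validated data.frame.
#' @export
read_metadata <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(tab)
}

#' @rdname read_metadata
#' @param tab metadata data.frame to validate in place.
#' @export
validate_metadata <- function(tab) {
  req <- c("neuron_id", "class_label", "transmitter")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("missing metadata columns: ", paste(missing_cols, collapse = ", "))
  classes <- c("uPN", "mPN", "LHON", "LHLN", "KC", "other")
  transmitters <- c("ACh", "GABA", "Glu", "OA", "unknown")
  bad <- setdiff(unique(tab$class_label), classes)
  if (length(bad)) stop("unknown class_label: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(tab$transmitter), transmitters)
  if (length(bad)) stop("unknown transmitter: ", paste(bad, collapse = ", "))
  tab
}
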