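# Skeleton graphs: joints, bone edges, self-loop-augmented adjacency, degrees.
# Joint indices are 0-based throughout, matching the exchange-format
# documentation; adjacency matrices are 1-based R matrices over the same
# joints.

#' Build a skeleton graph
#'
#' Constructs the undirected joint graph used by the spatial graph
#' convolution. A self-loop is added to every joint so that a node's own
#' feature always contributes to its aggregate (and no node has degree zero);
#' degrees therefore count the self-loop.
#'
#' @param edges Bone list: a two-column matrix or a list of length-2 integer
#'   vectors of 0-based joint indices. Self-loops are implicit and must not
#'   be listed.
#' @param n_joints Number of joints `V`.
#' @param joint_names Optional character vector of length `n_joints`.
#' @return A `skeleton_graph`: list with `n_joints`, `joint_names`, `edges`
#'   (k x 2 integer matrix, 0-based, each row sorted), `adjacency`
#'   (V x V 0/1 matrix with unit diagonal) and `degrees` (row sums).
#' @examples
#' g <- skeleton_graph(list(c(0, 1), c(1, 2)), n_joints = 3)
#' g$degrees  # 2 3 2 with self-loops
#' @export
skeleton_graph <- function(edges, n_joints, joint_names = NULL) {
  if (!is_count(n_joints)) {
    abort_validation("n_joints must be a positive integer")
  }
  n_joints <- as.integer(n_joints)
  if (is.list(edges)) {
    if (length(edges) == 0L) {
      edges <- matrix(integer(0), ncol = 2)
    } else {
      if (any(lengths(edges) != 2L)) {
        abort_validation("every edge must have exactly two joint indices")
      }
      edges <- do.call(rbind, lapply(edges, as.integer))
    }
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) == 0L && n_joints > 1L) {
    abort_validation("edge list is empty but the graph has %d joints", n_joints)
  }
  if (nrow(edges) > 0L) {
    if (any(edges < 0L) || any(edges >= n_joints)) {
      abort_validation("edge index out of range [0, %d)", n_joints)
    }
    if (any(edges[, 1] == edges[, 2])) {
      abort_validation("explicit self-loops are not allowed; they are implicit")
    }
    edges <- t(apply(edges, 1, sort))
    key <- paste(edges[, 1], edges[, 2])
    if (anyDuplicated(key)) {
      abort_validation("duplicate edge: %s", key[duplicated(key)][1])
    }
  }
  if (!is.null(joint_names)) {
    if (length(joint_names) != n_joints) {
      abort_validation("joint_names must have length n_joints")
    }
  } else {
    joint_names <- paste0("joint_", seq_len(n_joints) - 1L)
  }
  adjacency <- diag(1, n_joints)
  if (nrow(edges) > 0L) {
    adjacency[edges + 1L] <- 1
    adjacency[edges[, 2:1, drop = FALSE] + 1L] <- 1
  }
  dimnames(adjacency) <- list(joint_names, joint_names)
  structure(
    list(
      n_joints = n_joints,
      joint_names = joint_names,
      edges = edges,
      adjacency = adjacency,
      degrees = as.integer(rowSums(adjacency))
    ),
    class = "skeleton_graph"
  )
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "<skeleton_graph> %d joints, %d bone edges (self-loops implicit)\n",
    x$n_joints, nrow(x$edges)
  ))
  invisible(x)
}

#' Induced subgraph of a skeleton graph
#'
#' Keeps the given joints and the bone edges with both endpoints among them,
#' remapping indices to `0..k-1` in the order given. Self-loops are
#' preserved by construction.
#'
#' @param graph A [skeleton_graph()].
#' @param joints Non-empty vector of 0-based joint indices (no duplicates).
#' @return A `skeleton_graph` on `length(joints)` joints.
#' @export
subgraph <- function(graph, joints) {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (length(joints) == 0L) {
    abort_validation("joint list for subgraph must be non-empty")
  }
  joints <- as.integer(joints)
  if (any(joints < 0L) || any(joints >= graph$n_joints)) {
    abort_validation("subgraph joint index out of range")
  }
  if (anyDuplicated(joints)) {
    abort_validation("duplicate joints in subgraph selection")
  }
  remap <- rep(NA_integer_, graph$n_joints)
  remap[joints + 1L] <- seq_along(joints) - 1L
  keep <- !is.na(remap[graph$edges[, 1] + 1L]) & !is.na(remap[graph$edges[, 2] + 1L])
  new_edges <- graph$edges[keep, , drop = FALSE]
  new_edges[] <- remap[new_edges + 1L]
  if (nrow(new_edges) == 0L && length(joints) > 1L) {
    # allow fully disconnected selections: build the adjacency directly
    adjacency <- diag(1, length(joints))
    nm <- graph$joint_names[joints + 1L]
    dimnames(adjacency) <- list(nm, nm)
    return(structure(
      list(
        n_joints = length(joints),
        joint_names = nm,
        edges = matrix(integer(0), ncol = 2),
        adjacency = adjacency,
        degrees = as.integer(rowSums(adjacency))
      ),
      class = "skeleton_graph"
    ))
  }
  g <- if (length(joints) == 1L) {
    skeleton_graph(matrix(integer(0), ncol = 2), 1L,
                   joint_names = graph$joint_names[joints + 1L])
  } else {
    skeleton_graph(new_edges, length(joints),
                   joint_names = graph$joint_names[joints + 1L])
  }
  g
}

#' Restriction of a skeleton graph to within-subset edges
#'
#' Builds the pathway-specific graph of the pyramid: all joints are kept,
#' but a bone edge survives only when both of its endpoints fall in the same
#' joint subset. The limb pathway, for example, decomposes the skeleton into
#' five disconnected components (two arms, two legs, torso).
#'
#' @param graph A [skeleton_graph()].
#' @param subsets List of 0-based joint-index vectors whose union must cover
#'   all joints.
#' @return A `skeleton_graph` on the same joints with the filtered edge set.
#' @export
pathway_graph <- function(graph, subsets) {
  stopifnot(inherits(graph, "skeleton_graph"))
  covered <- sort(unique(unlist(subsets)))
  if (!identical(as.integer(covered), seq_len(graph$n_joints) - 1L)) {
    abort_validation("pathway subsets must cover every joint exactly")
  }
  keep <- rep(FALSE, nrow(graph$edges))
  for (s in subsets) {
    keep <- keep |
      (graph$edges[, 1] %in% s & graph$edges[, 2] %in% s)
  }
  edges <- graph$edges[keep, , drop = FALSE]
  adjacency <- diag(1, graph$n_joints)
  if (nrow(edges) > 0L) {
    adjacency[edges + 1L] <- 1
    adjacency[edges[, 2:1, drop = FALSE] + 1L] <- 1
  }
  dimnames(adjacency) <- list(graph$joint_names, graph$joint_names)
  structure(
    list(
      n_joints = graph$n_joints,
      joint_names = graph$joint_names,
      edges = edges,
      adjacency = adjacency,
      degrees = as.integer(rowSums(adjacency))
    ),
    class = "skeleton_graph"
  )
}

#' Three-scale joint partition of a skeleton
#'
#' Returns the pyramid's partition scheme: pathway 0 ("global") is the whole
#' joint set; pathway 1 ("half") splits the body into upper and lower halves
#' (sharing the pelvis joints so neither half is cut off from the root);
#' pathway 2 ("limb") separates the four limbs and the torso. Every
#' pathway's subsets jointly cover all joints.
#'
#' @param graph A [skeleton_graph()] (used for coverage validation).
#' @param layout A layout object from [skeleton_layout()] or [read_layout()],
#'   or a registered layout name (`"kinect25"`, `"coco17"`).
#' @return A `partition_scheme`: list with `pathways` (named list
#'   global/half/limb of joint-subset lists) and `scale_order`.
#' @export
default_partition <- function(graph, layout) {
  if (is.character(layout)) layout <- skeleton_layout(layout)
  stopifnot(inherits(layout, "fpgait_layout"))
  pathways <- list(
    global = list(all = seq_len(graph$n_joints) - 1L),
    half = layout$partition$half,
    limb = layout$partition$limb
  )
  partition_scheme(pathways)
}

#' Construct and validate a partition scheme
#'
#' @param pathways Ordered (coarse to fine) named list; each element is a
#'   list of 0-based joint-index vectors. Every pathway's union must equal
#'   the same full joint set.
#' @return A `partition_scheme` object.
#' @export
partition_scheme <- function(pathways) {
  if (length(pathways) < 1L) abort_validation("at least one pathway required")
  full <- sort(unique(unlist(pathways[[1]])))
  for (i in seq_along(pathways)) {
    u <- sort(unique(unlist(pathways[[i]])))
    if (!identical(as.integer(u), as.integer(full))) {
      abort_validation("pathway %d does not cover the full joint set", i - 1L)
    }
  }
  structure(
    list(
      pathways = pathways,
      scale_order = seq_along(pathways) - 1L,
      n_joints = length(full)
    ),
    class = "partition_scheme"
  )
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat(sprintf(
    "<partition_scheme> %d pathways over %d joints: %s\n",
    length(x$pathways), x$n_joints,
    paste(sprintf("%s(%d)", names(x$pathways), lengths(x$pathways)),
          collapse = ", ")
  ))
  invisible(x)
}
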