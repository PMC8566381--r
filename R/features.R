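#' Soma features of every node
#'
#' The four soma features of a node capture its spatial relation to the
#' soma: `l_s`, the skeleton path length to the soma (micrometres); `nl_s`,
#' that length divided by the neuron's maximum node path length; `d_s`, the
#' straight-line (Euclidean) distance to the soma; and `nd_s`, that distance
#' divided by the neuron's maximum node Euclidean distance. The normalizers
#' are maxima over all non-root nodes of the same neuron, so
#' `nl_s, nd_s` lie in (0, 1] and `d_s <= l_s` always.
#'
#' @param tree A `level_tree`.
#' @param node Optional node id(s); default all non-root nodes.
#' @return Tibble with columns `node_id`, `l_s`, `nl_s`, `d_s`, `nd_s`.
#' @export
soma_features <- function(tree, node = NULL) {
  stopifnot(inherits(tree, "level_tree"))
  ls <- path_to_root(tree)
  ds <- sqrt((tree$x - tree$x[1L])^2 + (tree$y - tree$y[1L])^2 +
               (tree$z - tree$z[1L])^2)
  non_root <- tree$node_id != attr(tree, "root_id")
  out <- tibble::tibble(
    node_id = tree$node_id,
    l_s = ls,
    nl_s = ls / max(ls[non_root]),
    d_s = ds,
    nd_s = ds / max(ds[non_root])
  )[non_root, ]
  if (!is.null(node)) {
    if (any(node == attr(tree, "root_id"))) {
      stop("soma features are undefined for the root node", call. = FALSE)
    }
    out <- out[match(node, out$node_id), ]
  }
  out
}

#' Local features of every node
#'
#' The five local features describe the morphology around a node without
#' reference to the soma: `l_p`, the path length to the parent node
#' (micrometres); `nl_p`, that length normalized by the neuron's maximum
#' node path length to the soma; `c`, the curvature (mean tortuosity) of the
#' node's cluster; `ar`, the aspect ratio of the cluster; and `rl`, the
#' ratio (min/max) of the path lengths to the node's two children. Wherever
#' a value is undefined — `rl` at leaves, `c`/`ar` for nodes outside any
#' cluster or in degenerate clusters — the sentinel value -1 is used.
#'
#' Cluster curvature is the mean over the cluster's terminals of
#' (path length from the cluster root to the terminal) / (Euclidean distance
#' from the cluster root to the terminal); it is at least 1, and exactly 1
#' when terminals lie on straight radii. Aspect ratio is
#' `sqrt(lambda1/lambda3)` of the eigenvalues of the coordinate covariance
#' of the cluster's member nodes about their centroid (`lambda3` floored at
#' `1e-9 * lambda1`); clusters with fewer than 4 member nodes get the -1
#' sentinel.
#'
#' @param tree A `level_tree`.
#' @param clusters A `neuron_clusters` object from [assign_clusters()].
#' @param node Optional node id(s); default all non-root nodes.
#' @return Tibble with columns `node_id`, `l_p`, `nl_p`, `c`, `ar`, `rl`.
#' @export
local_features <- function(tree, clusters, node = NULL) {
  stopifnot(inherits(tree, "level_tree"))
  ls <- path_to_root(tree)
  non_root <- which(tree$node_id != attr(tree, "root_id"))
  max_ls <- max(ls[non_root])
  kids <- tree_children(tree)

  rl <- vapply(seq_len(nrow(tree)), function(i) {
    ch <- kids[[i]]
    if (length(ch) < 2L) return(-1)
    e <- tree$edge_length[ch]
    if (max(e) <= 0) return(1)
    min(e) / max(e)
  }, numeric(1))

  member <- clusters$membership$cluster_id[match(tree$node_id,
                                                 clusters$membership$node_id)]
  geom <- cluster_geometry(tree, clusters, ls)
  cc <- ifelse(is.na(member), -1, geom$curvature[member])
  ar <- ifelse(is.na(member), -1, geom$aspect_ratio[member])

  out <- tibble::tibble(
    node_id = tree$node_id,
    l_p = tree$edge_length,
    nl_p = tree$edge_length / max_ls,
    c = cc,
    ar = ar,
    rl = rl
  )[non_root, ]
  if (!is.null(node)) out <- out[match(node, out$node_id), ]
  out
}

# Per-cluster curvature (mean root-to-terminal tortuosity) and aspect ratio
# (sqrt of extreme covariance eigenvalue ratio).
cluster_geometry <- function(tree, clusters, ls = path_to_root(tree)) {
  k <- clusters$n_clusters
  curvature <- rep(-1, max(k, 1L))
  aspect <- rep(-1, max(k, 1L))
  pos <- cbind(tree$x, tree$y, tree$z)
  for (ci in seq_len(k)) {
    info <- clusters$clusters[ci, ]
    root_node <- info$root_node
    term <- info$terminal_nodes[[1L]]
    term <- setdiff(term, root_node)
    if (length(term) > 0L) {
      path <- vapply(term, function(t)
        tree_path_dist(tree, ls, root_node, t), numeric(1))
      chord <- sqrt(rowSums((pos[term, , drop = FALSE] -
                               matrix(pos[root_node, ], length(term), 3L,
                                      byrow = TRUE))^2))
      ok <- chord > 1e-9
      if (any(ok)) curvature[ci] <- mean(path[ok] / chord[ok])
    }
    mem <- clusters$membership$node_id[
      which(clusters$membership$cluster_id == ci)]
    if (length(mem) >= 4L) {
      cm <- pos[mem, , drop = FALSE]
      ev <- eigen(stats::cov(cm), symmetric = TRUE, only.values = TRUE)$values
      l1 <- ev[1L]
      l3 <- max(ev[3L], 1e-9 * l1)
      if (l1 > 0) aspect[ci] <- sqrt(l1 / l3)
    }
  }
  list(curvature = curvature, aspect_ratio = aspect)
}

#' Extract the full per-node feature table of one neuron
#'
#' Runs the standardization pipeline (level tree, reduced tree, clusters,
#' polarity propagation when labels are given) and returns one row per node
#' with the four soma features, the five local features, the nodal polarity,
#' and bookkeeping columns.
#'
#' @param skeleton A [neuron_skeleton], or the list returned by [read_swc()]
#'   or [generate_neuron()] (in which case `labels` defaults to its labels).
#' @param labels Terminal label tibble, or `NULL` for prediction-mode
#'   extraction (no polarity column is filled, propagation is skipped).
#' @param characteristic_length Passed to [build_reduced_tree()].
#' @return Tibble with columns `neuron`, `node_id`, `swc_id`, `level`,
#'   `is_leaf`, `cluster_id`, `neuron_class`, `l_s`, `nl_s`, `d_s`, `nd_s`,
#'   `l_p`, `nl_p`, `c`, `ar`, `rl`, `polarity` (`NA` in prediction mode).
#' @export
extract_features <- function(skeleton, labels = NULL,
                             characteristic_length = "auto") {
  if (is.list(skeleton) && !inherits(skeleton, "neuron_skeleton") &&
      !is.null(skeleton$skeleton)) {
    if (is.null(labels)) labels <- skeleton$labels
    skeleton <- skeleton$skeleton
  }
  tree <- build_level_tree(skeleton)
  reduced <- build_reduced_tree(tree, characteristic_length)
  clusters <- assign_clusters(tree, reduced)
  sf <- soma_features(tree)
  lf <- local_features(tree, clusters)
  pol <- if (!is.null(labels) && nrow(labels) > 0L) {
    propagate_polarity(tree, labels)
  } else {
    tibble::tibble(node_id = tree$node_id, polarity = NA_character_)
  }
  non_root <- tree$node_id[tree$node_id != attr(tree, "root_id")]
  rows <- match(non_root, tree$node_id)
  tibble::tibble(
    neuron = attr(tree, "name"),
    node_id = non_root,
    swc_id = tree$swc_id[rows],
    level = tree$level[rows],
    is_leaf = tree$is_leaf[rows],
    cluster_id = clusters$membership$cluster_id[
      match(non_root, clusters$membership$node_id)],
    neuron_class = clusters$neuron_class
  ) |>
    dplyr::left_join(sf, by = "node_id") |>
    dplyr::left_join(lf, by = "node_id") |>
    dplyr::left_join(pol[, c("node_id", "polarity")], by = "node_id")
}

#' Column names of each feature model
#'
#' Model I uses the nine soma + local features, Model II the four soma
#' features only, Model III the five local features only.
#'
#' @param model `"I"`, `"II"`, or `"III"`.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(model = c("I", "II", "III")) {
  model <- match.arg(model)
  sf <- c("l_s", "nl_s", "d_s", "nd_s")
  lf <- c("l_p", "nl_p", "c", "ar", "rl")
  switch(model, I = c(sf, lf), II = sf, III = lf)
}

#' Assemble a model-specific feature matrix
#'
#' Selects the feature columns of the requested model from a table of
#' per-node feature rows (see [extract_features()]), drops dividing nodes,
#' and orders rows deterministically by neuron then node id. In training
#' mode every retained row must carry an axon/dendrite label.
#'
#' @param rows Feature rows, typically several neurons' [extract_features()]
#'   output bound together.
#' @param model `"I"`, `"II"`, or `"III"`.
#' @param training If `TRUE`, unlabeled nodes are an error; if `FALSE`,
#'   labels may be missing (prediction mode) and are carried through as-is.
#' @return Tibble with columns `neuron`, `node_id`, `swc_id`, `is_leaf`, the
#'   model's feature columns, and `label`; attribute `feature_model` records
#'   the model tag.
#' @export
build_feature_matrix <- function(rows, model = c("I", "II", "III"),
                                 training = TRUE) {
  model <- match.arg(model)
  cols <- feature_columns(model)
  keep <- is.na(rows$polarity) | rows$polarity != "dividing"
  out <- rows[keep, , drop = FALSE]
  if (training) {
    if (any(is.na(out$polarity))) {
      stop("training mode requires a polarity label for every node",
           call. = FALSE)
    }
  }
  out <- dplyr::arrange(out, .data$neuron, .data$node_id)
  res <- dplyr::bind_cols(
    out[, c("neuron", "node_id", "swc_id", "is_leaf")],
    out[, cols],
    tibble::tibble(label = out$polarity)
  )
  attr(res, "feature_model") <- model
  res
}
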