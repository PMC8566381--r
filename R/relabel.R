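#' Configuration for spatial-correlation relabeling
#'
#' Nodes of the same cluster are overwhelmingly of the same polarity, a
#' constraint the per-node classifiers cannot express. The relabeling step
#' enforces it: nodal predictions whose winning probability falls below a
#' confidence threshold are rejected as unidentified and re-assigned from
#' their neighbors.
#'
#' @param threshold Confidence threshold tau in \[0, 1\]; a prediction is
#'   accepted outright when its winning class probability is at least tau.
#' @param max_passes Maximum number of relabeling sweeps.
#' @param neighbor_scope `"cluster_first"` (majority vote within the node's
#'   cluster, falling back to tree-adjacent nodes) or `"graph_only"`
#'   (tree-adjacent nodes only).
#' @return An object of class `relabel_config`.
#' @export
relabel_config <- function(threshold = 0.8, max_passes = 10L,
                           neighbor_scope = c("cluster_first", "graph_only")) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be a probability in [0, 1]", call. = FALSE)
  }
  if (max_passes < 1L) stop("max_passes must be positive", call. = FALSE)
  structure(
    list(threshold = threshold, max_passes = as.integer(max_passes),
         neighbor_scope = match.arg(neighbor_scope)),
    class = "relabel_config"
  )
}

#' Relabel low-confidence nodal predictions from their neighbors
#'
#' Three steps: (1) take the per-node class probabilities from the
#' classifier; (2) accept the argmax label wherever the winning probability
#' reaches the threshold, and mark the remaining nodes unidentified;
#' (3) sweep over the unidentified nodes, assigning each the majority label
#' among the already-labeled nodes of its cluster (falling back to
#' tree-adjacent nodes when the node is clusterless or the vote ties, with
#' a final tie broken toward the nearer neighbor by path length), until no
#' assignment changes or `max_passes` sweeps are done. Any node still
#' unresolved keeps its argmax label. Confident nodes are never changed,
#' and a threshold of 0 accepts everything (identity).
#'
#' @param predictions Per-node prediction tibble for one neuron (columns
#'   `node_id`, `p_axon`, `p_dendrite`), e.g. one neuron's slice of a
#'   [run_protocol()] result.
#' @param tree The neuron's `level_tree`.
#' @param clusters Its [assign_clusters()] result.
#' @param config A [relabel_config()].
#' @return Tibble `node_id`, `p_axon`, `p_dendrite`, `label`, `relabeled`.
#' @export
apply_relabel <- function(predictions, tree, clusters,
                          config = relabel_config()) {
  stopifnot(inherits(config, "relabel_config"))
  tau <- config$threshold
  n <- nrow(predictions)
  if (n == 0L) {
    return(dplyr::mutate(predictions, label = character(0),
                         relabeled = logical(0)))
  }
  argmax <- ifelse(predictions$p_axon >= predictions$p_dendrite,
                   "axon", "dendrite")
  conf <- pmax(predictions$p_axon, predictions$p_dendrite) >= tau
  label <- ifelse(conf, argmax, NA_character_)
  if (!any(conf)) {
    stop("no anchor labels: every prediction falls below the threshold",
         call. = FALSE)
  }

  member <- clusters$membership$cluster_id[
    match(predictions$node_id, clusters$membership$node_id)]
  adj <- adjacency_map(tree, predictions$node_id)
  ls <- path_to_root(tree)

  for (pass in seq_len(config$max_passes)) {
    open <- which(is.na(label))
    if (length(open) == 0L) break
    new_label <- label
    for (i in open) {
      vote <- NA_character_
      if (config$neighbor_scope == "cluster_first" && !is.na(member[i])) {
        peers <- which(member == member[i] & !is.na(label))
        vote <- majority(label[peers])
      }
      if (is.na(vote)) {
        nb <- adj[[i]]
        lab_nb <- label[nb]
        vote <- majority(lab_nb[!is.na(lab_nb)])
        if (is.na(vote) && any(!is.na(lab_nb))) {
          # tie: side with the nearer labeled neighbor by path length
          cand <- nb[!is.na(lab_nb)]
          d <- abs(ls[match(predictions$node_id[cand], tree$node_id)] -
                     ls[match(predictions$node_id[i], tree$node_id)])
          vote <- label[cand[which.min(d)]]
        }
      }
      if (!is.na(vote)) new_label[i] <- vote
    }
    if (identical(new_label, label)) break
    label <- new_label
  }
  unresolved <- is.na(label)
  label[unresolved] <- argmax[unresolved]

  dplyr::bind_cols(
    predictions[, c("node_id", "p_axon", "p_dendrite")],
    tibble::tibble(label = label, relabeled = !conf & label != argmax)
  )
}

majority <- function(x) {
  if (length(x) == 0L) return(NA_character_)
  tab <- table(x)
  if (length(tab) > 1L && tab[1L] == tab[2L]) return(NA_character_)
  names(which.max(tab))
}

# parent + children of each prediction row, as row indices
adjacency_map <- function(tree, node_ids) {
  kids <- tree_children(tree)
  rows <- match(node_ids, tree$node_id)
  lapply(rows, function(r) {
    nb <- c(tree$parent[r], kids[[tree$node_id[r]]])
    nb <- nb[!is.na(nb)]
    idx <- match(nb, node_ids)
    idx[!is.na(idx)]
  })
}

#' Recover dividing nodes from predicted terminal labels
#'
#' Dividing nodes are excluded from training and prediction, but on a test
#' neuron they can be recovered after the fact: the predicted terminal
#' labels are propagated back up the tree with the same four rules used for
#' the ground truth, and any node emerging as dividing is so marked.
#'
#' @param labels Final per-node labels for the neuron (tibble `node_id`,
#'   `label`), e.g. from [apply_relabel()]; every terminal must carry an
#'   axon/dendrite label.
#' @param tree The neuron's `level_tree`.
#' @return Nodal polarity tibble as from [propagate_polarity()].
#' @export
recover_dividing <- function(labels, tree) {
  leaf_rows <- which(tree$is_leaf)
  hit <- match(tree$node_id[leaf_rows], labels$node_id)
  if (anyNA(hit)) {
    stop("terminal node ", tree$node_id[leaf_rows][which(is.na(hit))[1L]],
         " carries no final label", call. = FALSE)
  }
  term_labels <- tibble::tibble(
    point_id = tree$swc_id[leaf_rows],
    label = labels$label[hit]
  )
  propagate_polarity(tree, term_labels)
}

#' Project nodal labels onto terminals
#'
#' Scoring is always done on terminals: each terminal inherits the final
#' label of its own node.
#'
#' @param labels Per-node label tibble (`node_id`, `label`, optionally
#'   probability columns).
#' @param tree The neuron's `level_tree`.
#' @return Tibble `terminal_id` (skeleton point id), `node_id`, `label`, and
#'   any probability columns present.
#' @export
terminal_projection <- function(labels, tree) {
  leaf_rows <- which(tree$is_leaf)
  hit <- match(tree$node_id[leaf_rows], labels$node_id)
  keep <- !is.na(hit)
  out <- tibble::tibble(
    terminal_id = tree$swc_id[leaf_rows][keep],
    node_id = tree$node_id[leaf_rows][keep]
  )
  dplyr::bind_cols(out, labels[hit[keep],
                               setdiff(names(labels), "node_id"),
                               drop = FALSE])
}
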