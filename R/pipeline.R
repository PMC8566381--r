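#' Prepare one neuron for classification
#'
#' Runs the full standardization pipeline on a skeleton: level tree, reduced
#' tree, terminal clusters, nodal polarity propagation (when labels exist)
#' and the per-node feature table.
#'
#' @param neuron A list with `skeleton` and `labels` (as from [read_swc()]
#'   or [generate_neuron()]), or a bare [neuron_skeleton].
#' @param labels Optional terminal labels overriding `neuron$labels`.
#' @param characteristic_length Passed to [build_reduced_tree()].
#' @return A list of class `prepared_neuron` with elements `name`,
#'   `skeleton`, `labels`, `tree`, `reduced`, `clusters`, `polarity`
#'   (`NULL` when unlabeled), `features`.
#' @export
prepare_neuron <- function(neuron, labels = NULL,
                           characteristic_length = "auto") {
  if (inherits(neuron, "neuron_skeleton")) {
    skeleton <- neuron
  } else {
    skeleton <- neuron$skeleton
    if (is.null(labels)) labels <- neuron$labels
  }
  tree <- build_level_tree(skeleton)
  reduced <- build_reduced_tree(tree, characteristic_length)
  clusters <- assign_clusters(tree, reduced)
  labeled <- !is.null(labels) && nrow(labels) > 0L
  polarity <- if (labeled) propagate_polarity(tree, labels) else NULL
  sf <- soma_features(tree)
  lf <- local_features(tree, clusters)
  non_root <- tree$node_id[-1L]
  rows <- match(non_root, tree$node_id)
  features <- tibble::tibble(
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
    dplyr::left_join(lf, by = "node_id")
  features$polarity <- if (labeled) {
    polarity$polarity[match(non_root, polarity$node_id)]
  } else {
    NA_character_
  }
  structure(
    list(name = attr(tree, "name"), skeleton = skeleton, labels = labels,
         tree = tree, reduced = reduced, clusters = clusters,
         polarity = polarity, features = features),
    class = "prepared_neuron"
  )
}

#' Prepare a dataset of neurons
#'
#' @param neurons A [generate_dataset()] tibble, or a list of neuron lists
#'   (each with `skeleton` and `labels`).
#' @param characteristic_length Passed to [build_reduced_tree()].
#' @return An object of class `npin_dataset`: list with `neurons` (named
#'   list of `prepared_neuron`s), `features` (all per-node feature rows),
#'   `truth_terminals` (tibble `neuron`, `terminal_id`, `label`), and
#'   `index` (per-neuron class and size summary).
#' @export
prepare_neurons <- function(neurons, characteristic_length = "auto") {
  if (tibble::is_tibble(neurons)) {
    lst <- purrr::map(seq_len(nrow(neurons)), function(i) {
      list(skeleton = neurons$skeleton[[i]], labels = neurons$labels[[i]])
    })
  } else {
    lst <- neurons
  }
  prepared <- purrr::map(lst, prepare_neuron,
                         characteristic_length = characteristic_length)
  names(prepared) <- purrr::map_chr(prepared, "name")
  features <- dplyr::bind_rows(purrr::map(prepared, "features"))
  truth <- dplyr::bind_rows(purrr::map(prepared, function(p) {
    if (is.null(p$labels) || nrow(p$labels) == 0L) return(NULL)
    tibble::tibble(neuron = p$name, terminal_id = p$labels$point_id,
                   label = p$labels$label)
  }))
  index <- dplyr::bind_rows(purrr::map(prepared, function(p) {
    tibble::tibble(
      neuron = p$name,
      neuron_class = p$clusters$neuron_class,
      n_clusters = p$clusters$n_clusters,
      n_nodes = nrow(p$tree),
      n_terminals = sum(p$tree$is_leaf),
      n_dividing = if (is.null(p$polarity)) NA_integer_ else
        count_dividing(p$polarity)
    )
  }))
  structure(
    list(neurons = prepared, features = features, truth_terminals = truth,
         index = index),
    class = "npin_dataset"
  )
}

#' @export
print.npin_dataset <- function(x, ...) {
  cat("<npin_dataset> ", length(x$neurons), " neurons (",
      sum(x$index$neuron_class == "simple"), " simple, ",
      sum(x$index$neuron_class == "complex"), " complex), ",
      nrow(x$features), " feature rows\n", sep = "")
  invisible(x)
}

#' Relabel a protocol result neuron by neuron
#'
#' Applies the spatial-correlation relabeling ([apply_relabel()]) to the
#' averaged nodal predictions of every tested neuron, using each neuron's
#' own tree and clusters.
#'
#' @param result A `protocol_result` from [run_protocol()].
#' @param dataset The [prepare_neurons()] dataset the protocol ran on.
#' @param config A [relabel_config()].
#' @return Tibble of final nodal labels: `neuron`, `node_id`, `swc_id`,
#'   `is_leaf`, `p_axon`, `p_dendrite`, `label`, `relabeled`.
#' @export
relabel_protocol <- function(result, dataset, config = relabel_config()) {
  pred <- result$predictions
  purrr::map_dfr(unique(pred$neuron), function(nm) {
    p <- dataset$neurons[[nm]]
    slice <- pred[pred$neuron == nm, ]
    out <- apply_relabel(slice, p$tree, p$clusters, config)
    dplyr::bind_cols(
      tibble::tibble(neuron = nm),
      out,
      slice[match(out$node_id, slice$node_id), c("swc_id", "is_leaf")]
    )
  })
}

#' Project final nodal labels onto terminals for scoring
#'
#' @param labels Output of [relabel_protocol()] (or any tibble with
#'   `neuron`, `swc_id`, `is_leaf`, `label`).
#' @return Tibble `neuron`, `terminal_id`, `label` plus probability columns
#'   when present.
#' @export
terminal_labels <- function(labels) {
  keep <- labels[labels$is_leaf, ]
  cols <- intersect(c("p_axon", "p_dendrite", "relabeled"), names(keep))
  dplyr::bind_cols(
    tibble::tibble(neuron = keep$neuron, terminal_id = keep$swc_id,
                   label = keep$label),
    keep[, cols]
  )
}
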