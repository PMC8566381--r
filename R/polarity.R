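#' Propagate terminal polarity labels to every node
#'
#' Extends the axon/dendrite labels of the terminals to all internal nodes of
#' the level tree by a bottom-up (postorder) application of four rules:
#' two children of the same class give a parent of that class; an axon child
#' plus a dendrite child make the parent a *dividing node* (the point
#' separating an axon cluster from a dendrite cluster); a class child plus a
#' dividing child give the class; two dividing children give a dividing
#' parent. Dividing nodes are typically rare (none to two per projection
#' neuron) and are excluded from classifier training and scoring.
#'
#' A root with a single child (a soma emitting one trunk) inherits its
#' child's label; since it has the same descendants as that child it is not
#' itself a split point, and [count_dividing()] does not count it.
#'
#' @param tree A `level_tree`.
#' @param labels Tibble of terminal labels (`point_id`, `label`), keyed by
#'   skeleton point id as produced by [read_swc()] or [generate_neuron()].
#' @return A tibble (`node_id`, `level`, `swc_id`, `n_children`,
#'   `polarity`) with one row per node; `polarity` is one of `"axon"`,
#'   `"dendrite"`, `"dividing"`.
#' @export
propagate_polarity <- function(tree, labels) {
  stopifnot(inherits(tree, "level_tree"))
  kids <- tree_children(tree)
  pol <- rep(NA_character_, nrow(tree))
  leaf <- which(tree$is_leaf)
  hit <- match(tree$swc_id[leaf], labels$point_id)
  if (anyNA(hit)) {
    miss <- tree$swc_id[leaf][which(is.na(hit))[1L]]
    stop("terminal ", miss, " has no polarity label", call. = FALSE)
  }
  pol[leaf] <- labels$label[hit]
  ord <- order(-tree$level)
  for (i in ord) {
    ch <- kids[[i]]
    if (length(ch) == 0L) next
    pol[i] <- combine_polarity(pol[ch])
  }
  tibble::tibble(
    node_id = tree$node_id,
    level = tree$level,
    swc_id = tree$swc_id,
    n_children = tree$n_children,
    polarity = pol
  )
}

combine_polarity <- function(p) {
  if (length(p) == 1L) return(p)  # unary root chain inherits its child
  a <- p[1L]; b <- p[2L]
  if (a == b) return(a)
  if (a == "dividing") return(b)
  if (b == "dividing") return(a)
  "dividing"  # one axon, one dendrite
}

#' Count dividing nodes in a nodal polarity map
#'
#' Counts the bifurcations labeled `"dividing"` — the points where an
#' axonal and a dendritic subtree meet. A unary root that merely inherits
#' the label from the bifurcation below it is not a meeting point and is
#' not counted.
#'
#' @param polarity_map Tibble from [propagate_polarity()].
#' @return Number of dividing bifurcations.
#' @export
count_dividing <- function(polarity_map) {
  div <- polarity_map$polarity == "dividing"
  if ("n_children" %in% names(polarity_map)) {
    div <- div & polarity_map$n_children >= 2L
  }
  sum(div)
}
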