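# Independent oracles and hand-built fixtures used across the suite.

# ---- skeleton fixtures ------------------------------------------------

swc_points <- function(...) {
  m <- matrix(c(...), ncol = 7L, byrow = TRUE)
  tibble::tibble(
    point_id = as.integer(m[, 1]), type_code = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent_id = as.integer(m[, 7])
  )
}

# soma -> branch point -> two terminals (one dendrite, one axon)
y_skeleton <- function() {
  as_neuron_skeleton(swc_points(
    1, 1, 0, 0, 0, 1, -1,
    2, 0, 10, 0, 0, 0.5, 1,
    3, 3, 10, 10, 0, 0.5, 2,
    4, 2, 20, 0, 0, 0.5, 2
  ), name = "y")
}

# the worked toy for soma features: soma, branch B, chain D, terminals
toy_feature_skeleton <- function() {
  as_neuron_skeleton(swc_points(
    1, 1, 0, 0, 0, 1, -1,
    2, 0, 10, 0, 0, 0.5, 1,
    3, 0, 10, 10, 0, 0.5, 2,
    4, 2, 10, 10, 5, 0.5, 3,
    5, 3, 30, 0, 0, 0.5, 2
  ), name = "toy")
}

# arbitrary binary level-tree tibble from a parent vector (root first),
# explicit edge lengths and optional positions/leaf labels
toy_level_tree <- function(parent, edge_length, pos = NULL,
                           name = "toy_tree") {
  n <- length(parent)
  if (is.null(pos)) pos <- cbind(seq_len(n), 0, 0)
  kids <- rep(list(integer(0)), n)
  for (i in seq_len(n)) {
    if (!is.na(parent[i])) kids[[parent[i]]] <- c(kids[[parent[i]]], i)
  }
  lvl <- integer(n)
  for (i in seq_len(n)[-1L]) lvl[i] <- lvl[parent[i]] + 1L
  nodes <- tibble::tibble(
    node_id = seq_len(n), parent = parent,
    child_rank = vapply(seq_len(n), function(i) {
      if (is.na(parent[i])) 0L else match(i, kids[[parent[i]]])
    }, integer(1)),
    level = lvl, edge_length = edge_length,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    swc_id = seq_len(n), synthetic = FALSE,
    n_children = lengths(kids)
  )
  nodes$is_leaf <- nodes$n_children == 0L
  structure(nodes, root_id = 1L, max_level = max(lvl), name = name,
            class = c("level_tree", class(tibble::tibble())))
}

# random labeled binary tree for polarity tests, as a level_tree +
# terminal labels keyed by swc_id
random_labeled_tree <- function(n_terminals, p_axon = 0.4) {
  parent <- c(NA_integer_, 1L)
  leaves <- 2L  # node 2 is the single current leaf
  n_leaves <- 1L
  while (n_leaves < n_terminals) {
    grow <- leaves[sample.int(length(leaves), 1L)]
    parent <- c(parent, grow, grow)
    leaves <- c(setdiff(leaves, grow), length(parent) - 1L, length(parent))
    n_leaves <- n_leaves + 1L
  }
  tree <- toy_level_tree(parent, c(0, stats::runif(length(parent) - 1L)))
  term <- tree$node_id[tree$is_leaf]
  labels <- tibble::tibble(
    point_id = tree$swc_id[match(term, tree$node_id)],
    label = ifelse(stats::runif(length(term)) < p_axon, "axon", "dendrite")
  )
  list(tree = tree, labels = labels)
}

# ---- brute-force oracles ----------------------------------------------

# literal recursive transcription of the four propagation rules
oracle_polarity <- function(tree, labels) {
  kids <- rep(list(integer(0)), nrow(tree))
  for (i in seq_len(nrow(tree))) {
    p <- tree$parent[i]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
  }
  rule <- function(a, b) {
    if (a == "axon" && b == "axon") return("axon")
    if (a == "dendrite" && b == "dendrite") return("dendrite")
    if ((a == "axon" && b == "dendrite") ||
        (a == "dendrite" && b == "axon")) return("dividing")
    if (a == "dividing" && b == "dividing") return("dividing")
    if (a == "dividing") return(b)
    if (b == "dividing") return(a)
    stop("unreachable")
  }
  visit <- function(v) {
    ch <- kids[[v]]
    if (length(ch) == 0L) {
      return(labels$label[match(tree$swc_id[v], labels$point_id)])
    }
    sub <- vapply(ch, visit, character(1))
    if (length(sub) == 1L) return(sub)
    rule(sub[1L], sub[2L])
  }
  vapply(tree$node_id, visit, character(1))
}

# arc length from the root to every skeleton point, straight off the SWC
# polyline (independent of the level-tree machinery)
oracle_arc_lengths <- function(skeleton) {
  ids <- skeleton$point_id
  pidx <- match(skeleton$parent_id, ids)
  seg <- sqrt((skeleton$x - skeleton$x[pidx])^2 +
                (skeleton$y - skeleton$y[pidx])^2 +
                (skeleton$z - skeleton$z[pidx])^2)
  root <- attr(skeleton, "soma_id")
  seg[match(root, ids)] <- 0
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  walk <- function(i, acc) {
    out[as.character(ids[i])] <<- acc
    for (j in which(pidx == i)) walk(j, acc + seg[j])
  }
  old <- options(expressions = 500000L)
  on.exit(options(old))
  walk(match(root, ids), 0)
  out
}

# per-terminal confusion counting loop, no vectorized shortcuts
oracle_counts <- function(truth_labels, pred_labels) {
  counts <- c(aa = 0L, ad = 0L, da = 0L, dd = 0L)
  for (i in seq_along(truth_labels)) {
    key <- paste0(substr(truth_labels[i], 1, 1), substr(pred_labels[i], 1, 1))
    counts[key] <- counts[key] + 1L
  }
  counts
}

# small helper: run one train/test split on a prepared dataset
single_split_accuracy <- function(prep, spec, n_train, n_val, seed,
                                  relabel_tau = NULL) {
  ids <- prep$index$neuron
  set.seed(seed)
  ids <- sample(ids)
  train_ids <- ids[seq_len(n_train)]
  val_ids <- ids[n_train + seq_len(n_val)]
  test_ids <- setdiff(ids, c(train_ids, val_ids))
  tr <- build_feature_matrix(
    prep$features[prep$features$neuron %in% train_ids, ], spec$feature_model)
  va <- build_feature_matrix(
    prep$features[prep$features$neuron %in% val_ids, ], spec$feature_model)
  te <- build_feature_matrix(
    prep$features[prep$features$neuron %in% test_ids, ], spec$feature_model,
    training = FALSE)
  fit <- train_polarity(tr, spec, va)
  pred <- predict(fit, te)
  truth <- prep$truth_terminals[prep$truth_terminals$neuron %in% test_ids, ]
  pre <- score_terminals(
    tibble::tibble(neuron = pred$neuron[pred$is_leaf],
                   terminal_id = pred$swc_id[pred$is_leaf],
                   label = pred$label[pred$is_leaf]),
    truth)$accuracy
  if (is.null(relabel_tau)) return(pre)
  rel <- purrr::map_dfr(test_ids, function(nm) {
    p <- prep$neurons[[nm]]
    slice <- pred[pred$neuron == nm, ]
    out <- apply_relabel(slice, p$tree, p$clusters,
                         relabel_config(relabel_tau))
    out$neuron <- nm
    out$swc_id <- slice$swc_id[match(out$node_id, slice$node_id)]
    out$is_leaf <- slice$is_leaf[match(out$node_id, slice$node_id)]
    out
  })
  post <- score_terminals(
    tibble::tibble(neuron = rel$neuron[rel$is_leaf],
                   terminal_id = rel$swc_id[rel$is_leaf],
                   label = rel$label[rel$is_leaf]),
    truth)$accuracy
  c(pre = pre, post = post)
}
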