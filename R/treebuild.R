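#' Build the standardized level tree of a neuron skeleton
#'
#' The level tree is a 2D binary-tree encoding of the 3D skeleton that keeps
#' the position of every node (soma, bifurcations, terminals) and the arc
#' length of the skeleton path between them, while dropping branch shape.
#' The soma sits at level 0 and each child is one level deeper. Degree-2
#' chain points of the skeleton are collapsed into edges whose
#' `edge_length` accumulates the polyline arc length; multifurcations are
#' expanded into cascades of binary nodes joined by zero-length edges, so
#' path lengths are conserved. At every internal node the deeper subtree is
#' placed first (left); ties go to the subtree with more terminals, then to
#' the one containing the smallest skeleton point id.
#'
#' @param skeleton A [neuron_skeleton].
#' @return A `level_tree` tibble with one row per node: `node_id` (1-based,
#'   breadth-first in left-to-right order), `parent`, `child_rank` (1 = left),
#'   `level`, `edge_length` (micrometres of skeleton path to the parent node),
#'   `x`, `y`, `z`, `swc_id` (originating skeleton point; cascade nodes share
#'   the id of the expanded branch point), `synthetic`, `is_leaf`,
#'   `n_children`. Attributes: `root_id`, `max_level`, `name`.
#' @export
build_level_tree <- function(skeleton) {
  ids <- skeleton$point_id
  n <- length(ids)
  root <- attr(skeleton, "soma_id")
  root_row <- match(root, ids)
  pidx <- match(skeleton$parent_id, ids)  # NA at root
  seg <- sqrt((skeleton$x - skeleton$x[pidx])^2 +
                (skeleton$y - skeleton$y[pidx])^2 +
                (skeleton$z - skeleton$z[pidx])^2)
  seg[root_row] <- 0
  over <- attr(skeleton, "seg_override")
  if (!is.null(over)) {
    hit <- match(as.integer(names(over)), ids)
    seg[hit] <- unname(over)
  }

  kids <- vector("list", n)
  for (i in seq_len(n)) kids[[i]] <- integer(0)
  for (i in seq_len(n)) {
    if (!is.na(pidx[i])) kids[[pidx[i]]] <- c(kids[[pidx[i]]], i)
  }
  n_kids <- lengths(kids)
  if (all(n_kids[-root_row] == 0L) && n == 1L || !any(n_kids[root_row] > 0L)) {
    stop("degenerate skeleton: no terminals", call. = FALSE)
  }

  is_key <- n_kids >= 2L | (n_kids == 0L)
  is_key[root_row] <- TRUE

  # BFS order guarantees parents precede children irrespective of SWC id order
  ord <- integer(n)
  ord[1L] <- root_row
  head_ <- 1L; tail_ <- 1L
  while (head_ <= tail_) {
    cur <- ord[head_]
    ck <- kids[[cur]]
    if (length(ck) > 0L) {
      ord[(tail_ + 1L):(tail_ + length(ck))] <- ck
      tail_ <- tail_ + length(ck)
    }
    head_ <- head_ + 1L
  }

  # nearest key ancestor and accumulated arc length to it
  key_parent <- rep(NA_integer_, n)
  key_dist <- numeric(n)
  for (i in ord[-1L]) {
    p <- pidx[i]
    if (is_key[p]) {
      key_parent[i] <- p
      key_dist[i] <- seg[i]
    } else {
      key_parent[i] <- key_parent[p]
      key_dist[i] <- key_dist[p] + seg[i]
    }
  }

  key_rows <- which(is_key)
  m <- length(key_rows)
  kidx <- match(seq_len(n), key_rows)  # skeleton row -> key node index

  # grow-able node arrays (synthetic cascade nodes are appended at the end)
  parent <- rep(NA_integer_, m)
  elen <- numeric(m)
  pos <- cbind(skeleton$x[key_rows], skeleton$y[key_rows],
               skeleton$z[key_rows])
  swc <- ids[key_rows]
  synth <- rep(FALSE, m)
  child_list <- rep(list(integer(0)), m)

  for (i in key_rows) {
    if (i == root_row) next
    me <- kidx[i]
    pa <- kidx[key_parent[i]]
    parent[me] <- pa
    elen[me] <- key_dist[i]
    child_list[[pa]] <- c(child_list[[pa]], me)
  }
  root_node <- kidx[root_row]

  # pre-expansion subtree stats for a deterministic cascade layout
  stats <- subtree_stats(parent, child_list, root_node, swc)

  expand_one <- function(v) {
    ch <- child_list[[v]]
    o <- order(-stats$depth[ch], -stats$terms[ch], stats$min_swc[ch])
    ch <- ch[o]
    while (length(ch) > 2L) {
      parent <<- c(parent, v)
      elen <<- c(elen, 0)
      pos <<- rbind(pos, pos[v, , drop = FALSE])
      swc <<- c(swc, swc[v])
      synth <<- c(synth, TRUE)
      child_list <<- c(child_list, list(ch[-1L]))
      s <- length(parent)
      for (c2 in ch[-1L]) parent[c2] <<- s
      ch <- c(ch[1L], s)
    }
    child_list[[v]] <<- ch
  }
  multi <- which(lengths(child_list) > 2L)
  for (v in multi) expand_one(v)

  # final left/right convention on the expanded binary tree
  stats <- subtree_stats(parent, child_list, root_node, swc)
  for (v in seq_along(child_list)) {
    ch <- child_list[[v]]
    if (length(ch) > 1L) {
      o <- order(-stats$depth[ch], -stats$terms[ch], stats$min_swc[ch])
      child_list[[v]] <- ch[o]
    }
  }

  finalize_level_tree(parent, child_list, elen, pos, swc, synth, root_node,
                      name = attr(skeleton, "name"))
}

# height (in levels), terminal count and min skeleton id per subtree
subtree_stats <- function(parent, child_list, root, swc) {
  n <- length(parent)
  depth <- integer(n); terms <- integer(n); min_swc <- integer(n)
  post <- postorder(child_list, root)
  for (v in post) {
    ch <- child_list[[v]]
    if (length(ch) == 0L) {
      depth[v] <- 0L; terms[v] <- 1L; min_swc[v] <- swc[v]
    } else {
      depth[v] <- 1L + max(depth[ch])
      terms[v] <- sum(terms[ch])
      min_swc[v] <- min(swc[v], min_swc[ch])
    }
  }
  list(depth = depth, terms = terms, min_swc = min_swc)
}

postorder <- function(child_list, root) {
  n <- length(child_list)
  out <- integer(n)
  stack <- integer(n); stack[1L] <- root; sp <- 1L; k <- n
  while (sp > 0L) {
    v <- stack[sp]; sp <- sp - 1L
    out[k] <- v; k <- k - 1L
    ch <- child_list[[v]]
    if (length(ch) > 0L) {
      stack[(sp + 1L):(sp + length(ch))] <- ch
      sp <- sp + length(ch)
    }
  }
  out[out != 0L]
}

# Pack internal arrays into the level_tree tibble with BFS node ids.
finalize_level_tree <- function(parent, child_list, elen, pos, swc, synth,
                                root, name = "neuron", theta = NULL) {
  alive <- which(!is.na(parent) | seq_along(parent) == root)
  lvl <- rep(NA_integer_, length(parent))
  lvl[root] <- 0L
  bfs <- integer(length(alive)); bfs[1L] <- root
  head_ <- 1L; tail_ <- 1L
  while (head_ <= tail_) {
    v <- bfs[head_]
    ch <- child_list[[v]]
    if (length(ch) > 0L) {
      lvl[ch] <- lvl[v] + 1L
      bfs[(tail_ + 1L):(tail_ + length(ch))] <- ch
      tail_ <- tail_ + length(ch)
    }
    head_ <- head_ + 1L
  }
  bfs <- bfs[seq_len(tail_)]
  new_id <- integer(length(parent))
  new_id[bfs] <- seq_along(bfs)
  rank <- integer(length(parent))
  for (v in bfs) {
    ch <- child_list[[v]]
    if (length(ch) > 0L) rank[ch] <- seq_along(ch)
  }
  nodes <- tibble::tibble(
    node_id = seq_along(bfs),
    parent = ifelse(bfs == root, NA_integer_, new_id[parent[bfs]]),
    child_rank = ifelse(bfs == root, 0L, rank[bfs]),
    level = lvl[bfs],
    edge_length = elen[bfs],
    x = pos[bfs, 1L], y = pos[bfs, 2L], z = pos[bfs, 3L],
    swc_id = swc[bfs],
    synthetic = synth[bfs],
    n_children = lengths(child_list)[bfs]
  )
  nodes$is_leaf <- nodes$n_children == 0L
  structure(
    nodes,
    root_id = 1L,
    max_level = max(nodes$level),
    name = name,
    theta = theta,
    class = c("level_tree", class(tibble::tibble()))
  )
}

# Children lists keyed by node_id, in stored left-to-right order.
tree_children <- function(tree) {
  n <- nrow(tree)
  kids <- rep(list(integer(0)), n)
  ord <- order(tree$parent, tree$child_rank, na.last = NA)
  for (i in ord) {
    p <- tree$parent[i]
    kids[[p]] <- c(kids[[p]], tree$node_id[i])
  }
  kids
}

# Cumulative skeleton path length from the root to every node.
path_to_root <- function(tree) {
  ls <- numeric(nrow(tree))
  ord <- order(tree$level)
  for (i in ord) {
    p <- tree$parent[i]
    if (!is.na(p)) ls[i] <- ls[p] + tree$edge_length[i]
  }
  ls
}

# Path distance between two nodes along the tree (via lowest common ancestor).
tree_path_dist <- function(tree, ls, u, v) {
  au <- u
  while (!is.na(tree$parent[au[length(au)]])) {
    au <- c(au, tree$parent[au[length(au)]])
  }
  w <- v
  while (!w %in% au) w <- tree$parent[w]
  ls[u] + ls[v] - 2 * ls[w]
}

#' Derive the reduced tree by iterative short-branch pruning
#'
#' The reduced tree retains the major branches of the arbor: leaves whose
#' edge to their parent is shorter than a characteristic length `theta` are
#' removed one at a time (deepest first), and a parent left with a single
#' child is collapsed into the edge (lengths summed), so surviving leaf edges
#' accumulate. Pruning stops when no leaf edge is below `theta` or when a
#' removal would leave fewer than five levels; trees that already have five
#' or fewer levels are returned unchanged. The surviving leaves mark the
#' major branches and seed the terminal clusters (see [assign_clusters()]).
#'
#' @param tree A `level_tree` from [build_level_tree()].
#' @param characteristic_length Positive number (micrometres), or `"auto"`:
#'   the edge-length distribution is split into its short (twig) and long
#'   (trunk/stem) components by a two-component 1-D clustering of log edge
#'   lengths, and `theta` is placed between them, three quarters of the way
#'   (geometrically) towards the long component.
#' @return A `level_tree`-shaped tibble of class `reduced_tree`; `node_id`s
#'   are re-assigned breadth-first and the `provenance` attribute maps them
#'   back to the node ids of the input level tree. Attribute `theta` records
#'   the characteristic length used.
#' @export
build_reduced_tree <- function(tree, characteristic_length = "auto") {
  stopifnot(inherits(tree, "level_tree"))
  if (is.character(characteristic_length)) {
    theta <- auto_theta(tree)
  } else {
    theta <- characteristic_length
    if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
        theta <= 0) {
      stop("characteristic_length must be a positive number or \"auto\"",
           call. = FALSE)
    }
  }
  orig_levels <- attr(tree, "max_level") + 1L
  if (orig_levels <= 5L) {
    return(reduced_from_state(tree, tree$node_id, theta))
  }
  floor_levels <- 5L

  n <- nrow(tree)
  parent <- tree$parent
  elen <- tree$edge_length
  kids <- tree_children(tree)
  active <- rep(TRUE, n)
  protected <- rep(FALSE, n)
  root <- 1L

  depth_levels <- function(parent, kids, active) {
    lvl <- rep(NA_integer_, n)
    lvl[root] <- 0L
    q <- root; mx <- 0L
    while (length(q) > 0L) {
      nxt <- unlist(kids[q], use.names = FALSE)
      if (length(nxt) == 0L) break
      lvl[nxt] <- lvl[q[match(parent[nxt], q)]] + 1L
      mx <- max(mx, lvl[nxt])
      q <- nxt
    }
    mx + 1L
  }

  repeat {
    leaves <- which(active & lengths(kids) == 0L & !protected &
                      seq_len(n) != root)
    cand <- leaves[elen[leaves] < theta]
    if (length(cand) == 0L) break
    lvl_now <- tree$level  # only used for ordering; exact levels not needed
    cand <- cand[order(-lvl_now[cand], cand)]
    changed <- FALSE
    for (L in cand) {
      # collapses earlier in this pass can have grown this leaf's edge
      if (!active[L] || length(kids[[L]]) > 0L || elen[L] >= theta) next
      snap <- list(parent = parent, elen = elen, kids = kids,
                   active = active)
      P <- parent[L]
      kids[[P]] <- setdiff(kids[[P]], L)
      active[L] <- FALSE
      if (P != root && length(kids[[P]]) == 1L) {
        Q <- kids[[P]][1L]
        elen[Q] <- elen[Q] + elen[P]
        gp <- parent[P]
        kids[[gp]][kids[[gp]] == P] <- Q
        parent[Q] <- gp
        active[P] <- FALSE
      } else if (length(kids[[P]]) == 0L && P != root) {
        # cannot happen with sequential removal (parent had 2 children)
      } else if (P == root && length(kids[[P]]) == 0L) {
        parent <- snap$parent; elen <- snap$elen
        kids <- snap$kids; active <- snap$active
        protected[L] <- TRUE
        next
      }
      if (depth_levels(parent, kids, active) <
            min(floor_levels, orig_levels)) {
        parent <- snap$parent; elen <- snap$elen
        kids <- snap$kids; active <- snap$active
        protected[L] <- TRUE
      } else {
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  keep <- which(active)
  reduced_from_pruned(tree, keep, parent, elen, kids, theta)
}

# Characteristic length from the branch-length distribution: split log edge
# lengths into short/long components, place theta between them, closer to
# the major-branch scale.
auto_theta <- function(tree) {
  len <- tree$edge_length[tree$edge_length > 0]
  if (length(len) < 2L) {
    return(max(c(tree$edge_length, 1)))
  }
  lx <- log(len)
  if (diff(range(lx)) < 1e-9) {
    return(mean(len))
  }
  init <- matrix(stats::quantile(lx, c(0.1, 0.9), names = FALSE), ncol = 1L)
  if (diff(init[, 1L]) < 1e-9) init[2L, 1L] <- init[2L, 1L] + 1e-6
  km <- stats::kmeans(matrix(lx, ncol = 1L), centers = init)
  cs <- sort(km$centers[, 1L])
  exp(0.25 * cs[1L] + 0.75 * cs[2L])
}

reduced_from_state <- function(tree, keep_ids, theta) {
  out <- tree[match(keep_ids, tree$node_id), ]
  res <- finalize_level_tree(
    parent = tree$parent, child_list = tree_children(tree),
    elen = tree$edge_length,
    pos = cbind(tree$x, tree$y, tree$z), swc = tree$swc_id,
    synth = tree$synthetic, root = 1L,
    name = attr(tree, "name"), theta = theta
  )
  attr(res, "provenance") <- stats::setNames(tree$node_id, res$node_id)
  class(res) <- c("reduced_tree", class(res))
  res
}

reduced_from_pruned <- function(tree, keep, parent, elen, kids, theta) {
  # re-apply the left/right convention before assigning ids
  stats_ <- subtree_stats(ifelse(seq_along(parent) %in% keep, parent,
                                 NA_integer_),
                          kids, 1L, tree$swc_id)
  for (v in keep) {
    ch <- kids[[v]]
    if (length(ch) > 1L) {
      o <- order(-stats_$depth[ch], -stats_$terms[ch], stats_$min_swc[ch])
      kids[[v]] <- ch[o]
    }
  }
  res <- finalize_level_tree(
    parent = parent, child_list = kids, elen = elen,
    pos = cbind(tree$x, tree$y, tree$z), swc = tree$swc_id,
    synth = tree$synthetic, root = 1L,
    name = attr(tree, "name"), theta = theta
  )
  prov <- tree$node_id[keep]
  bfs_order <- res$node_id  # res rows are BFS-ordered over kept nodes
  # finalize_level_tree walked the same arrays, so recover the mapping by
  # replaying its BFS over the kept structure
  attr(res, "provenance") <- stats::setNames(replay_bfs(kids, 1L, keep),
                                             res$node_id)
  class(res) <- c("reduced_tree", class(res))
  res
}

replay_bfs <- function(kids, root, keep) {
  out <- integer(length(keep))
  q <- root; k <- 0L
  while (length(q) > 0L) {
    out[(k + 1L):(k + length(q))] <- q
    k <- k + length(q)
    q <- unlist(kids[q], use.names = FALSE)
  }
  out[seq_len(k)]
}

#' Partition a neuron's nodes into terminal clusters
#'
#' The distal major branches of the reduced tree seed the clusters: a seed
#' is a reduced-tree node whose (accumulated) parent edge is at least the
#' characteristic length `theta` and below which no other such node exists —
#' the tip of a major branch. Each seed spawns the cluster made of the level
#' tree subtree rooted at its provenance node; should the reduced tree
#' contain no edge reaching `theta` (very compact arbors), its plain leaves
#' seed the clusters instead. Nodes outside every seed subtree that are not
#' trunk nodes (short twigs pruned off the trunk) are attached to the
#' cluster of the nearest seed by path distance, so the clusters jointly
#' cover every terminal. Trunk nodes — reduced-tree nodes above the seeds —
#' belong to no cluster. A neuron with two clusters is classed `"simple"`,
#' one with more than two `"complex"` (a single-cluster arbor is classed
#' `"other"`).
#'
#' @param tree A `level_tree`.
#' @param reduced The `reduced_tree` derived from `tree`.
#' @return An object of class `neuron_clusters`: a list with `membership`
#'   (tibble `node_id`, `cluster_id`, `NA` for trunk nodes), `clusters`
#'   (tibble `cluster_id`, `root_node` — the shallowest member node, used as
#'   the reference point for cluster curvature —, `seed_leaf`, `n_terminals`,
#'   `terminal_swc` list-column), `n_clusters`, and `neuron_class`.
#' @export
assign_clusters <- function(tree, reduced) {
  stopifnot(inherits(tree, "level_tree"), inherits(reduced, "reduced_tree"))
  prov <- attr(reduced, "provenance")
  if (is.null(prov) || !all(prov %in% tree$node_id)) {
    stop("provenance mismatch: reduced tree does not derive from this level tree",
         call. = FALSE)
  }
  theta <- attr(reduced, "theta")
  major <- reduced$node_id[!is.na(reduced$parent) &
                             reduced$edge_length >= theta]
  if (length(major) > 0L) {
    red_kids <- tree_children(reduced)
    has_major_below <- vapply(major, function(v) {
      any(setdiff(subtree_ids(red_kids, v), v) %in% major)
    }, logical(1))
    seed_red <- major[!has_major_below]
  } else {
    seed_red <- reduced$node_id[reduced$is_leaf]
  }
  seed <- unname(prov[as.character(seed_red)])
  in_seed_subtree <- unlist(lapply(seed, function(s)
    subtree_ids(tree_children(tree), s)))
  trunk <- setdiff(unname(prov), in_seed_subtree)
  k <- length(seed)

  kids <- tree_children(tree)
  member <- rep(NA_integer_, nrow(tree))
  for (ci in seq_len(k)) {
    sub <- subtree_ids(kids, seed[ci])
    member[sub] <- ci
  }
  member[trunk] <- NA_integer_
  ls <- path_to_root(tree)
  orphan <- which(is.na(member) & !tree$node_id %in% trunk)
  if (length(orphan) > 0L && k > 0L) {
    for (u in orphan) {
      d <- vapply(seed, function(v) tree_path_dist(tree, ls, u, v),
                  numeric(1))
      member[u] <- which.min(d)
    }
  }

  cl_rows <- purrr::map(seq_len(k), function(ci) {
    mem <- tree$node_id[which(member == ci)]
    mem_rows <- match(mem, tree$node_id)
    root_node <- mem[order(tree$level[mem_rows], mem)][1L]
    term <- mem[tree$is_leaf[mem_rows]]
    tibble::tibble(
      cluster_id = ci,
      root_node = root_node,
      seed_leaf = seed[ci],
      n_terminals = length(term),
      terminal_nodes = list(term),
      terminal_swc = list(tree$swc_id[match(term, tree$node_id)])
    )
  })
  clusters <- dplyr::bind_rows(cl_rows)
  neuron_class <- if (k == 2L) "simple" else if (k > 2L) "complex" else "other"
  structure(
    list(
      membership = tibble::tibble(node_id = tree$node_id,
                                  cluster_id = member),
      clusters = clusters,
      n_clusters = k,
      neuron_class = neuron_class
    ),
    class = "neuron_clusters"
  )
}

subtree_ids <- function(kids, root) {
  out <- integer(0)
  q <- root
  while (length(q) > 0L) {
    out <- c(out, q)
    q <- unlist(kids[q], use.names = FALSE)
  }
  out
}

#' Export a level tree as a Newick string
#'
#' Debug/inspection helper: branch lengths are the level-tree edge lengths,
#' tip labels the skeleton point ids.
#'
#' @param tree A `level_tree` or `reduced_tree`.
#' @return A single Newick string.
#' @export
tree_to_newick <- function(tree) {
  kids <- tree_children(tree)
  rec <- function(v) {
    ch <- kids[[v]]
    lab <- paste0("n", tree$swc_id[v])
    if (length(ch) == 0L) {
      paste0(lab, ":", format(tree$edge_length[v], digits = 8))
    } else {
      paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")",
             lab, ":", format(tree$edge_length[v], digits = 8))
    }
  }
  paste0(rec(1L), ";")
}

#' @export
print.level_tree <- function(x, ...) {
  cat("<level_tree", if (inherits(x, "reduced_tree")) " (reduced)" else "",
      "> ", attr(x, "name"), ": ", nrow(x), " nodes, ",
      sum(x$is_leaf), " leaves, ", attr(x, "max_level") + 1L, " levels\n",
      sep = "")
  NextMethod()
}
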