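test_that("a Y skeleton builds the smallest binary level tree", {
  tree <- build_level_tree(y_skeleton())
  expect_equal(nrow(tree), 4L)
  expect_equal(sort(tree$level), c(0L, 1L, 2L, 2L))
  expect_equal(sum(tree$is_leaf), 2L)
  # branch lengths follow the skeleton arcs
  expect_equal(sort(tree$edge_length[tree$is_leaf]), c(10, 10))
})

test_that("the deeper subtree is placed left, ties broken deterministically", {
  # left branch of the branch point runs 3 generations deep, right is a
  # single terminal
  sk <- as_neuron_skeleton(swc_points(
    1, 1, 0, 0, 0, 1, -1,
    2, 0, 10, 0, 0, 0.5, 1,
    3, 0, 20, 0, 0, 0.5, 2,   # short side terminal candidate
    4, 0, 10, 10, 0, 0.5, 2,
    5, 0, 10, 20, 0, 0.5, 4,
    6, 0, 10, 20, 5, 0.5, 5,
    7, 0, 15, 10, 0, 0.5, 4
  ), name = "asym")
  tree <- build_level_tree(sk)
  kids <- npinr:::tree_children(tree)
  branch <- tree$node_id[tree$level == 1L]
  ch <- kids[[branch]]
  depth_of <- function(v) {
    sub <- npinr:::subtree_ids(kids, v)
    max(tree$level[match(sub, tree$node_id)]) - tree$level[match(v, tree$node_id)]
  }
  expect_true(depth_of(ch[1L]) >= depth_of(ch[2L]))
  expect_equal(tree$swc_id[match(ch[1L], tree$node_id)], 4L)
})

test_that("left/right convention holds across generated neurons", {
  cfg <- synth_config(n_neurons = 15L, seed = 2L)
  ds <- generate_dataset(cfg)
  for (i in seq_len(nrow(ds))) {
    tree <- build_level_tree(ds$skeleton[[i]])
    kids <- npinr:::tree_children(tree)
    depths <- npinr:::subtree_stats(tree$parent, kids, 1L, tree$swc_id)$depth
    for (v in tree$node_id) {
      ch <- kids[[v]]
      if (length(ch) == 2L) expect_gte(depths[ch[1L]], depths[ch[2L]])
    }
  }
})

test_that("multifurcations expand to zero-length cascades conserving path length", {
  sk <- as_neuron_skeleton(swc_points(
    1, 1, 0, 0, 0, 1, -1,
    2, 0, 10, 0, 0, 0.5, 1,
    3, 0, 10, 10, 0, 0.5, 2,
    4, 0, 10, -10, 0, 0.5, 2,
    5, 0, 20, 0, 0, 0.5, 2,
    6, 0, 20, 0, 5, 0.5, 5
  ), name = "trif")
  tree <- build_level_tree(sk)
  expect_equal(sum(tree$synthetic), 1L)
  expect_equal(tree$edge_length[tree$synthetic], 0)
  # every internal node is binary after standardization
  expect_true(all(tree$n_children[!tree$is_leaf & tree$node_id != 1L] == 2L))
  ls <- npinr:::path_to_root(tree)
  arcs <- oracle_arc_lengths(sk)
  for (leaf in tree$node_id[tree$is_leaf]) {
    expect_equal(ls[leaf],
                 unname(arcs[as.character(tree$swc_id[match(leaf, tree$node_id)])]),
                 tolerance = 1e-10)
  }
})

test_that("a skeleton without terminals is rejected", {
  sk <- as_neuron_skeleton(swc_points(1, 1, 0, 0, 0, 1, -1), name = "dot")
  expect_error(build_level_tree(sk), "no terminals")
})

test_that("pruning is the identity when leaf edges are long or the tree shallow", {
  # all leaf edges >= theta: fixed point
  tr <- toy_level_tree(
    parent = c(NA, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 7L, 7L),
    edge_length = c(0, 50, 40, 45, 30, 35, 30, 28, 25, 26, 24, 22)
  )
  red <- build_reduced_tree(tr, characteristic_length = 10)
  expect_equal(nrow(red), nrow(tr))
  expect_equal(attr(red, "max_level"), attr(tr, "max_level"))

  # four levels only: untouched no matter the threshold
  tr4 <- toy_level_tree(
    parent = c(NA, 1L, 2L, 2L, 3L, 3L),
    edge_length = c(0, 5, 0.1, 0.2, 0.1, 0.3)
  )
  red4 <- build_reduced_tree(tr4, characteristic_length = 1e6)
  expect_equal(nrow(red4), nrow(tr4))
  expect_identical(red4$edge_length, tr4$edge_length)

  expect_error(build_reduced_tree(tr4, characteristic_length = -1),
               "positive")
  expect_error(build_reduced_tree(tr4, characteristic_length = 0),
               "positive")
})

test_that("a short twig is pruned and its parent collapsed as hand-simulated", {
  # seven levels so the five-level floor does not bite; node 6 is a 1 um
  # twig leaf among 20 um branches
  parent <- c(NA, 1L, 2L, 2L, 3L, 3L, 5L, 5L, 7L, 7L, 9L, 9L)
  elen <- c(0, 20, 20, 20, 20, 1, 20, 20, 20, 20, 20, 20)
  tr <- toy_level_tree(parent, elen)
  red <- build_reduced_tree(tr, characteristic_length = 5)
  # hand simulation of the loop: leaf 6 removed (edge 1 < 5); its parent 3
  # is left unary and collapses, so node 5's edge becomes 20 + 20 = 40;
  # every remaining leaf edge is 20 >= theta and pruning stops
  prov <- attr(red, "provenance")
  expect_false(6L %in% prov)
  expect_false(3L %in% prov)
  expect_equal(nrow(red), 10L)
  merged <- as.integer(names(prov)[prov == 5L])
  expect_equal(red$edge_length[red$node_id == merged], 40)
  expect_equal(attr(red, "max_level"), 5L)
})

test_that("pruning contracts: node count, depth floor, theta positivity", {
  cfg <- synth_config(n_neurons = 25L, seed = 9L)
  ds <- generate_dataset(cfg)
  for (i in seq_len(nrow(ds))) {
    tree <- build_level_tree(ds$skeleton[[i]])
    red <- build_reduced_tree(tree)
    expect_lte(nrow(red), nrow(tree))
    expect_gte(attr(red, "max_level") + 1L,
               min(5L, attr(tree, "max_level") + 1L))
    expect_gt(attr(red, "theta"), 0)
    # surviving node positions are a subset of the level tree's
    prov <- attr(red, "provenance")
    expect_true(all(prov %in% tree$node_id))
  }
})

test_that("clusters partition terminals and class simple/complex correctly", {
  # hand-built simple neuron: two arbors on a trunk
  cfg2 <- synth_config(n_neurons = 30L, cluster_count_range = 2L, seed = 21L)
  ds2 <- generate_dataset(cfg2)
  for (i in seq_len(nrow(ds2))) {
    tree <- build_level_tree(ds2$skeleton[[i]])
    red <- build_reduced_tree(tree)
    cl <- assign_clusters(tree, red)
    expect_equal(cl$n_clusters, 2L)
    expect_equal(cl$neuron_class, "simple")
    # partition: disjoint, jointly covering all terminals
    term <- tree$node_id[tree$is_leaf]
    mem <- cl$membership$cluster_id[match(term, cl$membership$node_id)]
    expect_false(anyNA(mem))
    all_members <- unlist(cl$clusters$terminal_nodes)
    expect_equal(sort(all_members), sort(term))
  }
})

test_that("cluster count recovers the generated ground truth at high separation", {
  cfg <- synth_config(n_neurons = 120L, separation = 1, seed = 31L)
  ds <- generate_dataset(cfg)
  found <- vapply(seq_len(nrow(ds)), function(i) {
    tree <- build_level_tree(ds$skeleton[[i]])
    assign_clusters(tree, build_reduced_tree(tree))$n_clusters
  }, integer(1))
  expect_gte(mean(found == ds$k), 0.95)
})

test_that("mismatched provenance is a consistency error", {
  t1 <- build_level_tree(y_skeleton())
  cfg <- synth_config(n_neurons = 1L, seed = 3L)
  sk2 <- generate_dataset(cfg)$skeleton[[1L]]
  t2 <- build_level_tree(sk2)
  r2 <- build_reduced_tree(t2)
  expect_error(assign_clusters(t1, r2), "provenance")
})

test_that("newick export parses with branch lengths intact", {
  tree <- build_level_tree(y_skeleton())
  nwk <- tree_to_newick(tree)
  ph <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(ph), 2L)
  expect_equal(sort(ph$edge.length), sort(tree$edge_length[-1L]))
})
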