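test_that("soma features match hand-computed path sums and Pythagoras", {
  tree <- build_level_tree(toy_feature_skeleton())
  # level tree: root, branch B (swc 2), leaves T_a (swc 4) and T_c (swc 5)
  ta <- tree$node_id[tree$swc_id == 4L]
  tc <- tree$node_id[tree$swc_id == 5L]
  sf <- soma_features(tree)
  expect_equal(sf$l_s[sf$node_id == ta], 25)
  expect_equal(sf$d_s[sf$node_id == ta], 15)
  expect_equal(sf$nl_s[sf$node_id == ta], 25 / 30)
  # T_c runs straight from the soma through B: d_s = l_s, and it is the
  # deepest path so both normalizers hit 1 there
  expect_equal(sf$l_s[sf$node_id == tc], 30)
  expect_equal(sf$d_s[sf$node_id == tc], 30)
  expect_equal(sf$nl_s[sf$node_id == tc], 1)
  expect_equal(sf$nd_s[sf$node_id == tc], 1)

  expect_error(soma_features(tree, node = 1L), "root")
})

test_that("child path-length ratio uses min/max with -1 at leaves", {
  tr <- toy_level_tree(c(NA, 1L, 2L, 2L), c(0, 5, 4, 8))
  cl <- assign_clusters(tr, build_reduced_tree(tr, 1))
  lf <- local_features(tr, cl)
  expect_equal(lf$rl[lf$node_id == 2L], 0.5)
  expect_equal(lf$rl[lf$node_id %in% c(3L, 4L)], c(-1, -1))

  tre <- toy_level_tree(c(NA, 1L, 2L, 2L), c(0, 5, 6, 6))
  cle <- assign_clusters(tre, build_reduced_tree(tre, 1))
  expect_equal(local_features(tre, cle)$rl[1L], 1)
})

test_that("cluster curvature is 1 for straight radii and aspect ratio guards small clusters", {
  # star cluster: terminals on straight radii from the cluster root
  pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0), c(20, 10, 0),
               c(30, 0, 0), c(20, -10, 0))
  tr <- toy_level_tree(c(NA, 1L, 2L, 3L, 3L, 2L),
                       c(0, 10, 10, sqrt(100 + 100) - 10 + 10, 10, 10),
                       pos = pos)
  # hand-built clusters: nodes 2..6 form one cluster rooted at node 2
  member <- tibble::tibble(node_id = 1:6,
                           cluster_id = c(NA, 1L, 1L, 1L, 1L, 1L))
  clusters <- structure(
    list(membership = member,
         clusters = tibble::tibble(
           cluster_id = 1L, root_node = 2L, seed_leaf = 2L,
           n_terminals = 3L,
           terminal_nodes = list(c(4L, 5L, 6L)),
           terminal_swc = list(c(4L, 5L, 6L))),
         n_clusters = 1L, neuron_class = "other"),
    class = "neuron_clusters")
  # straighten the tree: make all edges collinear path segments
  tr2 <- toy_level_tree(c(NA, 1L, 2L, 3L, 3L, 2L),
                        c(0, 10, 10, 10, 10, 10),
                        pos = rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0),
                                    c(30, 0, 0), c(30, 0, 0), c(20, 0, 0)))
  tr2$edge_length <- c(0, 10, 10, 10, 10, 10)
  geom <- npinr:::cluster_geometry(tr2, clusters)
  expect_equal(geom$curvature[1L], 1, tolerance = 1e-9)

  # fewer than 4 member nodes: aspect ratio sentinel
  small <- structure(
    list(membership = tibble::tibble(node_id = 1:6,
                                     cluster_id = c(NA, NA, NA, 1L, 1L, 1L)),
         clusters = tibble::tibble(
           cluster_id = 1L, root_node = 4L, seed_leaf = 4L,
           n_terminals = 1L, terminal_nodes = list(5L),
           terminal_swc = list(5L)),
         n_clusters = 1L, neuron_class = "other"),
    class = "neuron_clusters")
  geom2 <- npinr:::cluster_geometry(tr2, small)
  expect_equal(geom2$aspect_ratio[1L], -1)
})

test_that("soma-feature inequalities and sentinel closure hold on synthetic data", {
  cfg <- synth_config(n_neurons = 30L, seed = 13L)
  prep <- prepare_neurons(generate_dataset(cfg))
  f <- prep$features
  expect_true(all(f$d_s <= f$l_s + 1e-9))
  expect_true(all(f$nl_s > 0 & f$nl_s <= 1 + 1e-12))
  expect_true(all(f$nd_s > 0 & f$nd_s <= 1 + 1e-12))
  # every neuron attains both normalization maxima
  maxes <- dplyr::summarise(dplyr::group_by(f, neuron),
                            ml = max(nl_s), md = max(nd_s))
  expect_true(all(abs(maxes$ml - 1) < 1e-12))
  expect_true(all(abs(maxes$md - 1) < 1e-12))
  # sentinels: rl = -1 exactly at leaves; c/ar = -1 only off-cluster or in
  # degenerate clusters
  expect_true(all((f$rl == -1) == f$is_leaf))
  expect_true(all(f$c[is.na(f$cluster_id)] == -1))
  expect_true(all(f$ar[is.na(f$cluster_id)] == -1))
  expect_true(all(f$c[f$c != -1] >= 1 - 1e-9))
  expect_true(all(f$ar[f$ar != -1] >= 1 - 1e-9))
})

test_that("high-separation data reproduce the class separation in features", {
  cfg <- synth_config(n_neurons = 60L, separation = 1, seed = 19L)
  prep <- prepare_neurons(generate_dataset(cfg))
  f <- prep$features[prep$features$polarity %in% c("axon", "dendrite"), ]
  expect_gt(mean(f$nl_s[f$polarity == "axon"]),
            mean(f$nl_s[f$polarity == "dendrite"]))
  cc <- f[f$c != -1, ]
  expect_gt(mean(cc$c[cc$polarity == "dendrite"]),
            mean(cc$c[cc$polarity == "axon"]))
})

test_that("feature matrices have model-specific columns and exclude dividing nodes", {
  cfg <- synth_config(n_neurons = 6L, seed = 23L)
  prep <- prepare_neurons(generate_dataset(cfg))
  f <- prep$features
  mI <- build_feature_matrix(f, "I")
  mII <- build_feature_matrix(f, "II")
  mIII <- build_feature_matrix(f, "III")
  id_cols <- c("neuron", "node_id", "swc_id", "is_leaf")
  expect_setequal(names(mI), c(id_cols, feature_columns("I"), "label"))
  expect_setequal(names(mII), c(id_cols, feature_columns("II"), "label"))
  expect_setequal(names(mIII), c(id_cols, feature_columns("III"), "label"))
  expect_error(build_feature_matrix(f, "IV"))

  # dividing nodes are dropped: row count = nodes - dividing (root already
  # absent from feature rows)
  n_div <- sum(f$polarity == "dividing")
  expect_gt(n_div, 0L)
  expect_equal(nrow(mI), nrow(f) - n_div)
  expect_false(any(mI$label == "dividing"))

  # deterministic construction: same neuron presented twice, identical rows
  again <- build_feature_matrix(f, "I")
  expect_identical(mI, again)

  # prediction mode tolerates missing labels; training mode does not
  f_unlab <- f
  f_unlab$polarity <- NA_character_
  expect_error(build_feature_matrix(f_unlab, "I", training = TRUE),
               "polarity label")
  expect_equal(nrow(build_feature_matrix(f_unlab, "I", training = FALSE)),
               nrow(f))
})
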