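# small fabricated node-feature tables with a controllable signal
fake_rows <- function(n_neurons, nodes_per_neuron = 30L, sep = TRUE,
                      seed = 1L) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_neurons), function(i) {
    n <- nodes_per_neuron
    lab <- sample(c("axon", "dendrite"), n, replace = TRUE,
                  prob = c(0.3, 0.7))
    nl_s <- ifelse(lab == "axon", stats::runif(n, 0.7, 1),
                   stats::runif(n, 0, 0.3))
    if (!sep) nl_s <- stats::runif(n)
    l_s <- nl_s * 100
    tibble::tibble(
      neuron = sprintf("fk_%03d", i), node_id = seq_len(n) + 1L,
      swc_id = seq_len(n) + 1L, level = 1L,
      is_leaf = rep(c(TRUE, FALSE), length.out = n),
      cluster_id = 1L, neuron_class = "simple",
      l_s = l_s, nl_s = nl_s, d_s = l_s * 0.9, nd_s = nl_s * 0.9 + 0.1,
      l_p = stats::runif(n, 1, 10), nl_p = stats::runif(n, 0, 0.1),
      c = stats::runif(n, 1, 3), ar = stats::runif(n, 1, 5),
      rl = stats::runif(n),
      polarity = lab
    )
  })
}

test_that("both learners fit linearly separable toy features perfectly", {
  rows <- fake_rows(12L)
  tr <- build_feature_matrix(rows[rows$neuron <= "fk_008", ], "II")
  va <- build_feature_matrix(rows[rows$neuron > "fk_008", ], "II")
  for (alg in c("xgb", "dnn")) {
    fit <- train_polarity(tr, model_spec("II", alg, seed = 3L), va)
    pred <- predict(fit, tr)
    expect_equal(mean(pred$label == tr$label), 1)
    expect_true(all(abs(pred$p_axon + pred$p_dendrite - 1) < 1e-6))
  }
})

test_that("schema mismatches and degenerate training sets are errors", {
  rows <- fake_rows(4L)
  m9 <- build_feature_matrix(rows, "I")
  va <- m9
  expect_error(train_polarity(m9, model_spec("III", "xgb"), va),
               "Model III")
  one_class <- m9
  one_class$label <- "dendrite"
  expect_error(
    train_polarity(one_class, model_spec("I", "xgb"), va),
    "one polarity class"
  )
  expect_error(train_polarity(m9[0, ], model_spec("I", "xgb"), va), "empty")

  fit <- train_polarity(m9, model_spec("I", "xgb"), va)
  m4 <- build_feature_matrix(rows, "II")
  expect_error(predict(fit, m4), "expects")
})

test_that("training and protocol runs are deterministic under a fixed seed", {
  rows <- fake_rows(10L)
  tr <- build_feature_matrix(rows[rows$neuron <= "fk_006", ], "I")
  va <- build_feature_matrix(rows[rows$neuron > "fk_006", ], "I")
  for (alg in c("xgb", "dnn")) {
    f1 <- train_polarity(tr, model_spec("I", alg, seed = 11L), va)
    f2 <- train_polarity(tr, model_spec("I", alg, seed = 11L), va)
    expect_identical(predict(f1, va)$p_axon, predict(f2, va)$p_axon)
  }
  r1 <- suppressWarnings(
    run_protocol(rows, model_spec("I", "xgb", seed = 5L),
                 n_train = 5L, n_val = 2L, n_test = 3L, rounds = 3L,
                 seed = 8L))
  r2 <- suppressWarnings(
    run_protocol(rows, model_spec("I", "xgb", seed = 5L),
                 n_train = 5L, n_val = 2L, n_test = 3L, rounds = 3L,
                 seed = 8L))
  expect_identical(r1$predictions, r2$predictions)
})

test_that("prediction handles empty input and normalizes probabilities", {
  rows <- fake_rows(6L)
  tr <- build_feature_matrix(rows[rows$neuron <= "fk_004", ], "I")
  va <- build_feature_matrix(rows[rows$neuron > "fk_004", ], "I")
  fit <- train_polarity(tr, model_spec("I", "xgb", seed = 2L), va)
  empty <- tr[0, ]
  expect_equal(nrow(predict(fit, empty)), 0L)
  pred <- predict(fit, va)
  expect_true(all(abs(pred$p_axon + pred$p_dendrite - 1) < 1e-6))
})

test_that("feature importance ranks the informative feature first", {
  rows <- fake_rows(12L)
  # only nl_s carries signal; make the others noise including a constant
  rows$l_s <- stats::runif(nrow(rows))
  rows$d_s <- stats::runif(nrow(rows))
  rows$nd_s <- 0.5
  tr <- build_feature_matrix(rows[rows$neuron <= "fk_008", ], "II")
  va <- build_feature_matrix(rows[rows$neuron > "fk_008", ], "II")
  fit <- train_polarity(tr, model_spec("II", "xgb", seed = 1L), va)
  imp <- feature_importance(fit)
  expect_equal(imp$feature[1L], "nl_s")
  expect_equal(imp$gain[imp$feature == "nd_s"], 0)
  expect_equal(imp$feature[nrow(imp)], "nd_s")

  dfit <- train_polarity(tr, model_spec("II", "dnn", seed = 1L), va)
  expect_error(feature_importance(dfit), "unsupported")
})

test_that("the split protocol draws neuron-level roles with the right multiplicity", {
  ids <- sprintf("n%03d", 1:213)
  sp <- protocol_splits(ids, 100L, 25L, 50L, rounds = 20L, seed = 1L)
  expect_equal(nrow(sp), 20L * 175L)
  # roles disjoint within each round
  per_round <- dplyr::count(sp, round, neuron)
  expect_true(all(per_round$n == 1L))
  mult <- dplyr::count(sp[sp$role == "test", ], neuron)
  expect_equal(sum(mult$n), 20L * 50L)
  expect_error(protocol_splits(ids[1:100], 100L, 25L, 50L, 5L), "exceed")
})

test_that("single-round protocol with full test coverage averages trivially", {
  rows <- fake_rows(10L)
  expect_warning(
    res <- run_protocol(rows, model_spec("II", "xgb", seed = 1L),
                        n_train = 5L, n_val = 2L, n_test = 3L, rounds = 1L,
                        seed = 3L),
    "never sampled")
  expect_true(all(res$predictions$n_rounds == 1L))
  test_ids <- res$splits$neuron[res$splits$role == "test"]
  expect_setequal(unique(res$predictions$neuron), test_ids)
  g <- glance(res)
  expect_equal(g$rounds, 1L)
  expect_equal(g$mean_multiplicity, 1)
})
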