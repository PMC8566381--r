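#' Specify a nodal polarity classifier
#'
#' A model spec pairs one of the three feature models (I: soma + local
#' features, II: soma features only, III: local features only) with one of
#' the two learning algorithms — gradient boosting (`"xgb"`) or a
#' feed-forward network (`"dnn"`) — plus hyperparameters and a seed.
#'
#' Gradient-boosting defaults: binary logistic objective, 500 trees, depth
#' 6, learning rate 0.1, early stopping after 50 stagnant rounds on the
#' validation set. Network defaults: three ReLU hidden layers of 64/64/32
#' units, 2-way softmax with cross-entropy, early stopping patience 20.
#' Class weights are off by default; set `params$class_weight = TRUE` to
#' up-weight the minority class.
#'
#' @param feature_model `"I"`, `"II"`, or `"III"`.
#' @param algorithm `"xgb"` or `"dnn"`.
#' @param params Named list of hyperparameter overrides.
#' @param seed Integer seed controlling training randomness.
#' @return An object of class `npin_model_spec`.
#' @export
model_spec <- function(feature_model = c("I", "II", "III"),
                       algorithm = c("xgb", "dnn"),
                       params = list(), seed = 1L) {
  feature_model <- match.arg(feature_model)
  algorithm <- match.arg(algorithm)
  defaults <- if (algorithm == "xgb") {
    list(nrounds = 500L, max_depth = 6L, eta = 0.1,
         early_stopping_rounds = 50L, class_weight = FALSE)
  } else {
    list(hidden = c(64L, 64L, 32L), lr = 0.01, max_epochs = 400L,
         patience = 20L, class_weight = FALSE)
  }
  params <- utils::modifyList(defaults, params)
  structure(
    list(feature_model = feature_model, algorithm = algorithm,
         params = params, seed = as.integer(seed)),
    class = "npin_model_spec"
  )
}

check_matrix_schema <- function(matrix, spec) {
  cols <- feature_columns(spec$feature_model)
  have <- intersect(c(feature_columns("I")), names(matrix))
  if (!setequal(have, cols)) {
    stop("feature matrix carries columns {", paste(have, collapse = ", "),
         "} but spec for Model ", spec$feature_model, " expects {",
         paste(cols, collapse = ", "), "}", call. = FALSE)
  }
  cols
}

#' Train a nodal polarity classifier
#'
#' Fits the learner named by `spec` on a training feature matrix, with early
#' stopping monitored on a validation matrix. Both matrices come from
#' [build_feature_matrix()] and must carry the feature columns of the
#' spec's model — no more, no fewer. Training is deterministic given the
#' spec seed.
#'
#' @param matrix Training matrix (labeled, no dividing nodes).
#' @param spec An [model_spec()].
#' @param validation Validation matrix with the same schema.
#' @return An object of class `npin_model`.
#' @export
train_polarity <- function(matrix, spec, validation) {
  stopifnot(inherits(spec, "npin_model_spec"))
  cols <- check_matrix_schema(matrix, spec)
  check_matrix_schema(validation, spec)
  if (nrow(matrix) == 0L) stop("empty training matrix", call. = FALSE)
  y <- as.integer(matrix$label == "axon")
  if (length(unique(y)) < 2L) {
    stop("degenerate training set: only one polarity class present",
         call. = FALSE)
  }
  x <- as.matrix(matrix[, cols])
  xv <- as.matrix(validation[, cols])
  yv <- as.integer(validation$label == "axon")
  w <- NULL
  if (isTRUE(spec$params$class_weight)) {
    tab <- table(y)
    w <- as.numeric(length(y) / (2 * tab[as.character(y)]))
  }

  if (spec$algorithm == "xgb") {
    fit <- fit_xgb(x, y, xv, yv, w, spec)
  } else {
    fit <- fit_dnn(x, y, xv, yv, w, spec)
  }
  structure(
    list(spec = spec, feature_names = cols, fit = fit$fit,
         center = fit$center, scale = fit$scale,
         best_iter = fit$best_iter),
    class = "npin_model"
  )
}

fit_xgb <- function(x, y, xv, yv, w, spec) {
  p <- spec$params
  set.seed(spec$seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, weight = w, nthread = 1)
  dval <- xgboost::xgb.DMatrix(xv, label = yv, nthread = 1)
  booster <- xgboost::xgb.train(
    params = xgboost::xgb.params(
      objective = "binary:logistic",
      max_depth = p$max_depth, eta = p$eta,
      nthread = 1, seed = spec$seed,
      eval_metric = "logloss"
    ),
    data = dtrain, nrounds = p$nrounds,
    evals = list(val = dval),
    early_stopping_rounds = p$early_stopping_rounds,
    verbose = 0
  )
  best <- xgboost::xgb.attr(booster, "best_iteration")
  list(fit = booster, center = NULL, scale = NULL,
       best_iter = if (is.null(best)) p$nrounds else as.integer(best))
}

fit_dnn <- function(x, y, xv, yv, w, spec) {
  p <- spec$params
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[scale < 1e-9] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  xvs <- sweep(sweep(xv, 2L, center), 2L, scale, "/")
  if (!is.null(w)) {
    # replicate-free weighting: scale the learning signal by duplicating the
    # minority rows is avoided; simple resampling keeps the trainer lean
    reps <- pmax(1L, round(w / min(w)))
    idx <- rep(seq_along(y), reps)
    xs <- xs[idx, , drop = FALSE]
    y <- y[idx]
  }
  fit <- mlp_fit(xs, y, xvs, yv, hidden = p$hidden, lr = p$lr,
                 max_epochs = p$max_epochs, patience = p$patience,
                 seed = spec$seed)
  list(fit = fit, center = center, scale = scale,
       best_iter = fit$best_epoch)
}

#' Predict nodal polarity probabilities
#'
#' @param object A trained `npin_model`.
#' @param matrix Feature matrix with the schema the model was trained on
#'   (see [build_feature_matrix()]); may be empty.
#' @param ... Unused.
#' @return Tibble with one row per input row: `neuron`, `node_id`, `swc_id`,
#'   `is_leaf`, `p_axon`, `p_dendrite` (summing to 1), and the argmax
#'   `label`.
#' @export
predict.npin_model <- function(object, matrix, ...) {
  cols <- check_matrix_schema(matrix, object$spec)
  id_cols <- matrix[, c("neuron", "node_id", "swc_id", "is_leaf")]
  if (nrow(matrix) == 0L) {
    return(dplyr::bind_cols(id_cols,
                            tibble::tibble(p_axon = numeric(),
                                           p_dendrite = numeric(),
                                           label = character())))
  }
  x <- as.matrix(matrix[, cols])
  p_axon <- if (object$spec$algorithm == "xgb") {
    stats::predict(object$fit, xgboost::xgb.DMatrix(x, nthread = 1))
  } else {
    xs <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
    mlp_predict(object$fit, xs)
  }
  dplyr::bind_cols(
    id_cols,
    tibble::tibble(
      p_axon = as.numeric(p_axon),
      p_dendrite = 1 - as.numeric(p_axon),
      label = ifelse(p_axon >= 0.5, "axon", "dendrite")
    )
  )
}

#' Alias for [predict.npin_model()] with a data-frame-first signature
#' @param matrix Feature matrix.
#' @param model A trained `npin_model`.
#' @return See [predict.npin_model()].
#' @export
predict_polarity <- function(matrix, model) {
  stats::predict(model, matrix)
}

#' Feature importance ranking of a gradient-boosted model
#'
#' Features ranked by total gain. Only available for the gradient-boosting
#' learner; the feed-forward network exposes no comparable ranking.
#'
#' @param model A trained `npin_model` with `algorithm = "xgb"`.
#' @return Tibble with columns `feature`, `gain`, `cover`, `frequency`,
#'   sorted by decreasing gain; features the booster never split on are
#'   appended with zero gain.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "npin_model"))
  if (model$spec$algorithm != "xgb") {
    stop("feature importance is unsupported for the dnn learner",
         call. = FALSE)
  }
  imp <- xgboost::xgb.importance(model = model$fit)
  out <- tibble::tibble(
    feature = imp$Feature,
    gain = imp$Gain, cover = imp$Cover, frequency = imp$Frequency
  )
  unused <- setdiff(model$feature_names, out$feature)
  if (length(unused) > 0L) {
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(feature = unused, gain = 0, cover = 0, frequency = 0)
    )
  }
  dplyr::arrange(out, dplyr::desc(.data$gain))
}

#' Draw the multi-round train/validation/test splits
#'
#' Splits are drawn at the neuron level (never at the node level, to prevent
#' leakage between a neuron's own nodes): each round samples disjoint
#' training, validation and test neuron sets afresh.
#'
#' @param neurons Character vector of neuron ids.
#' @param n_train,n_val,n_test Neurons per role per round.
#' @param rounds Number of rounds.
#' @param seed Integer seed.
#' @return Tibble with columns `round`, `neuron`, `role`.
#' @export
protocol_splits <- function(neurons, n_train, n_val, n_test, rounds,
                            seed = 1L) {
  neurons <- unique(neurons)
  if (n_train + n_val + n_test > length(neurons)) {
    stop("split sizes exceed the number of neurons", call. = FALSE)
  }
  set.seed(seed)
  purrr::map_dfr(seq_len(rounds), function(r) {
    picked <- sample(neurons, n_train + n_val + n_test)
    tibble::tibble(
      round = r,
      neuron = picked,
      role = rep(c("train", "val", "test"), c(n_train, n_val, n_test))
    )
  })
}

#' Run the multi-round split, train and average protocol
#'
#' For each round a fresh neuron-level train/validation/test split is drawn,
#' a model is trained (with validation early stopping) and applied to the
#' round's test neurons. Per node, class probabilities are averaged over the
#' rounds in which its neuron landed in the test set, which damps the
#' fluctuation due to dataset selection; the per-neuron test multiplicity is
#' reported alongside. With the reference protocol (213 neurons, 50 test per
#' round, 20 rounds) each neuron is tested 4-5 times on average.
#'
#' @param features Per-node feature rows for all neurons
#'   ([extract_features()] output bound together, labeled).
#' @param spec An [model_spec()].
#' @param n_train,n_val,n_test Neurons per role per round.
#' @param rounds Number of rounds.
#' @param seed Integer seed for the splits (training seeds are derived per
#'   round from the spec seed).
#' @return An object of class `protocol_result`: list with `predictions`
#'   (per-node averaged probabilities, argmax `label`, `n_rounds` tested),
#'   `multiplicity` (per-neuron test count), `splits`, and `spec`.
#' @export
run_protocol <- function(features, spec, n_train = 100L, n_val = 25L,
                         n_test = 50L, rounds = 20L, seed = 1L) {
  stopifnot(inherits(spec, "npin_model_spec"))
  neurons <- unique(features$neuron)
  splits <- protocol_splits(neurons, n_train, n_val, n_test, rounds, seed)

  acc <- NULL
  for (r in seq_len(rounds)) {
    sp <- splits[splits$round == r, ]
    train_ids <- sp$neuron[sp$role == "train"]
    val_ids <- sp$neuron[sp$role == "val"]
    test_ids <- sp$neuron[sp$role == "test"]
    tr <- build_feature_matrix(features[features$neuron %in% train_ids, ],
                               spec$feature_model, training = TRUE)
    va <- build_feature_matrix(features[features$neuron %in% val_ids, ],
                               spec$feature_model, training = TRUE)
    te <- build_feature_matrix(features[features$neuron %in% test_ids, ],
                               spec$feature_model, training = FALSE)
    round_spec <- spec
    round_spec$seed <- spec$seed + r - 1L
    model <- train_polarity(tr, round_spec, va)
    pred <- stats::predict(model, te)
    pred$round <- r
    acc <- dplyr::bind_rows(acc, pred)
  }

  predictions <- acc |>
    dplyr::group_by(.data$neuron, .data$node_id, .data$swc_id,
                    .data$is_leaf) |>
    dplyr::summarise(
      p_axon = mean(.data$p_axon),
      p_dendrite = mean(.data$p_dendrite),
      n_rounds = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(label = ifelse(.data$p_axon >= 0.5, "axon", "dendrite"))

  tested <- unique(acc$neuron)
  never <- setdiff(neurons, tested)
  if (length(never) > 0L) {
    warning(length(never), " neuron(s) never sampled into a test set; ",
            "excluded from scoring: ",
            paste(utils::head(never, 5L), collapse = ", "), call. = FALSE)
  }
  multiplicity <- splits |>
    dplyr::filter(.data$role == "test") |>
    dplyr::count(.data$neuron, name = "n_test_rounds")

  structure(
    list(predictions = predictions, multiplicity = multiplicity,
         splits = splits, spec = spec, rounds = rounds),
    class = "protocol_result"
  )
}
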