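#' Score predicted terminal polarity against ground truth
#'
#' Builds the 2x2 terminal-level confusion matrix (rows: actual polarity,
#' columns: predicted) and the per-class precision/recall table. Only
#' terminals are scored — nodal labels are an internal device — and dividing
#' nodes never enter (terminals are never dividing). A report is flagged
#' unreliable when any class precision or recall falls below 0.5, the point
#' at which a class has more incorrectly than correctly identified
#' terminals.
#'
#' @param predicted Tibble of predicted terminal labels with columns
#'   `neuron`, `terminal_id`, `label`.
#' @param truth Tibble of ground-truth terminal labels with columns
#'   `neuron`, `terminal_id` (alias `point_id`), `label`.
#' @return An object of class `npin_score`: list with `confusion` (tibble
#'   `truth`, `predicted`, `n`), `metrics` (per-class precision/recall),
#'   `accuracy`, `n_terminals`, `per_neuron` (per-neuron accuracy), and
#'   `reliable`.
#' @export
score_terminals <- function(predicted, truth) {
  if ("point_id" %in% names(truth) && !"terminal_id" %in% names(truth)) {
    truth <- dplyr::rename(truth, terminal_id = "point_id")
  }
  if (!"neuron" %in% names(truth)) truth$neuron <- "neuron"
  if (!"neuron" %in% names(predicted)) predicted$neuron <- "neuron"
  joined <- dplyr::left_join(
    truth[, c("neuron", "terminal_id", "label")],
    predicted[, c("neuron", "terminal_id", "label")],
    by = c("neuron", "terminal_id"), suffix = c("_true", "_pred")
  )
  gaps <- joined[is.na(joined$label_pred), ]
  if (nrow(gaps) > 0L) {
    stop("missing predictions for ", nrow(gaps), " terminal(s): ",
         paste(utils::head(paste0(gaps$neuron, ":", gaps$terminal_id), 5L),
               collapse = ", "), call. = FALSE)
  }

  classes <- c("axon", "dendrite")
  confusion <- joined |>
    dplyr::count(truth = factor(.data$label_true, classes),
                 predicted = factor(.data$label_pred, classes),
                 .drop = FALSE, name = "n") |>
    dplyr::mutate(truth = as.character(.data$truth),
                  predicted = as.character(.data$predicted))

  cnt <- function(t, p) {
    confusion$n[confusion$truth == t & confusion$predicted == p]
  }
  metrics <- purrr::map_dfr(classes, function(cl) {
    tp <- cnt(cl, cl)
    fp <- sum(confusion$n[confusion$predicted == cl]) - tp
    fn <- sum(confusion$n[confusion$truth == cl]) - tp
    tibble::tibble(
      class = cl,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_
    )
  })
  accuracy <- sum(cnt("axon", "axon"), cnt("dendrite", "dendrite")) /
    sum(confusion$n)
  per_neuron <- joined |>
    dplyr::group_by(.data$neuron) |>
    dplyr::summarise(
      n = dplyr::n(),
      accuracy = mean(.data$label_true == .data$label_pred),
      .groups = "drop"
    )
  structure(
    list(
      confusion = confusion,
      metrics = metrics,
      accuracy = accuracy,
      n_terminals = sum(confusion$n),
      per_neuron = per_neuron,
      reliable = all(metrics$precision >= 0.5, na.rm = FALSE) &&
        all(metrics$recall >= 0.5, na.rm = FALSE)
    ),
    class = "npin_score"
  )
}

#' @export
print.npin_score <- function(x, ...) {
  cat("Terminal polarity score over", x$n_terminals, "terminals\n")
  cat(sprintf("  overall accuracy: %.4f%s\n", x$accuracy,
              if (isTRUE(x$reliable)) "" else "  [unreliable: precision or recall < 0.5]"))
  for (i in seq_len(nrow(x$metrics))) {
    cat(sprintf("  %-9s precision %.4f  recall %.4f\n",
                x$metrics$class[i], x$metrics$precision[i],
                x$metrics$recall[i]))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a terminal polarity score into per-class rows
#' @param x An `npin_score`.
#' @param ... Unused.
#' @return Tibble with columns `class`, `precision`, `recall`.
#' @method tidy npin_score
#' @export
tidy.npin_score <- function(x, ...) x$metrics

#' One-row summary of a terminal polarity score
#' @param x An `npin_score`.
#' @param ... Unused.
#' @return Tibble with `accuracy`, `n_terminals`, `n_neurons`,
#'   `frac_perfect_neurons`, `reliable`.
#' @method glance npin_score
#' @export
glance.npin_score <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    n_terminals = x$n_terminals,
    n_neurons = nrow(x$per_neuron),
    frac_perfect_neurons = mean(x$per_neuron$accuracy == 1),
    reliable = x$reliable
  )
}

#' Tidy a protocol result into its per-node predictions
#' @param x A `protocol_result`.
#' @param ... Unused.
#' @return The predictions tibble.
#' @method tidy protocol_result
#' @export
tidy.protocol_result <- function(x, ...) x$predictions

#' One-row summary of a protocol run
#' @param x A `protocol_result`.
#' @param ... Unused.
#' @return Tibble with `rounds`, `n_neurons_tested`, `mean_multiplicity`.
#' @method glance protocol_result
#' @export
glance.protocol_result <- function(x, ...) {
  tibble::tibble(
    rounds = x$rounds,
    n_neurons_tested = nrow(x$multiplicity),
    mean_multiplicity = mean(x$multiplicity$n_test_rounds)
  )
}

#' Compare feature models under identical splits
#'
#' Runs the split/train/average protocol once per model spec with a shared
#' split seed, projects the averaged nodal predictions onto terminals, and
#' scores each spec stratified by neuron class (`simple` / `complex` /
#' `all`).
#'
#' @param dataset A prepared dataset from [prepare_neurons()].
#' @param specs List of [model_spec()] objects (at least two).
#' @param n_train,n_val,n_test,rounds,seed Protocol parameters shared by all
#'   specs.
#' @return Tibble with one row per spec and stratum: `feature_model`,
#'   `algorithm`, `stratum`, `n_neurons`, `n_terminals`, `accuracy`,
#'   `precision_axon`, `recall_axon`, `precision_dendrite`,
#'   `recall_dendrite`, `reliable`.
#' @export
compare_models <- function(dataset, specs, n_train, n_val, n_test,
                           rounds = 5L, seed = 1L) {
  if (length(specs) < 2L) {
    stop("compare_models needs at least two model specs", call. = FALSE)
  }
  truth <- dataset$truth_terminals
  classes <- dataset$index[, c("neuron", "neuron_class")]
  purrr::map_dfr(specs, function(spec) {
    res <- run_protocol(dataset$features, spec, n_train, n_val, n_test,
                        rounds, seed)
    term <- protocol_terminals(res, dataset)
    purrr::map_dfr(c("simple", "complex", "all"), function(stratum) {
      keep <- if (stratum == "all") classes$neuron else
        classes$neuron[classes$neuron_class == stratum]
      keep <- intersect(keep, unique(term$neuron))
      if (length(keep) == 0L) {
        warning("stratum '", stratum, "' is empty; skipped", call. = FALSE)
        return(NULL)
      }
      sc <- score_terminals(term[term$neuron %in% keep, ],
                            truth[truth$neuron %in% keep, ])
      m <- sc$metrics
      tibble::tibble(
        feature_model = spec$feature_model,
        algorithm = spec$algorithm,
        stratum = stratum,
        n_neurons = length(keep),
        n_terminals = sc$n_terminals,
        accuracy = sc$accuracy,
        precision_axon = m$precision[m$class == "axon"],
        recall_axon = m$recall[m$class == "axon"],
        precision_dendrite = m$precision[m$class == "dendrite"],
        recall_dendrite = m$recall[m$class == "dendrite"],
        reliable = sc$reliable
      )
    })
  })
}

#' Project a protocol result onto terminals
#'
#' @param result A `protocol_result`.
#' @param dataset The prepared dataset ([prepare_neurons()]) it was run on.
#' @return Tibble `neuron`, `terminal_id`, `label`, `p_axon`, `p_dendrite`.
#' @export
protocol_terminals <- function(result, dataset) {
  pred <- result$predictions
  pred[pred$is_leaf, ] |>
    dplyr::transmute(
      neuron = .data$neuron,
      terminal_id = .data$swc_id,
      label = .data$label,
      p_axon = .data$p_axon,
      p_dendrite = .data$p_dendrite
    )
}
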