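#' Configuration of the synthetic projection-neuron generator
#'
#' The generator emulates the morphological structure that node-based
#' polarity classification exploits in insect projection neurons: a tortuous
#' main trunk leaving the soma, 2-4 compact terminal clusters hanging off
#' the trunk on long stems, dendritic clusters attaching closer to the soma
#' and axonal ones farther, and dendritic arbors wigglier (more tortuous)
#' than axonal ones. A single separation knob `separation` (delta) scales
#' both class differences; at `separation = 0` the two classes are
#' morphologically identical and only the class imbalance remains.
#'
#' @param n_neurons Number of neurons to generate.
#' @param cluster_count_range Integer vector of admissible cluster counts
#'   per neuron (2 = simple, >2 = complex with middle clusters of random
#'   class).
#' @param terminals_per_cluster Integer vector of terminal counts drawn per
#'   axonal cluster; dendritic clusters get `dendrite_axon_ratio` times as
#'   many, reproducing the roughly 3:1 dendrite:axon terminal imbalance of
#'   curated projection-neuron datasets.
#' @param dendrite_axon_ratio Terminal-count multiplier for dendritic
#'   clusters.
#' @param trunk_length Range (micrometres) of the trunk path length.
#' @param stem_length Range (micrometres) of the stem joining a cluster to
#'   the trunk.
#' @param cluster_radius Range (micrometres) of the cluster extent; arbor
#'   edge lengths are scaled by arbor depth so the extent does not grow with
#'   terminal count.
#' @param separation delta in \[0, 1\]: class gap in trunk attachment
#'   position and in arbor tortuosity.
#' @param wiggle Baseline perpendicular wiggle amplitude of branch
#'   polylines, as a fraction of segment chord length; dendritic branches
#'   use `wiggle * (1 + 0.7 * separation)`.
#' @param seed Integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_neurons = 100L,
                         cluster_count_range = 2:4,
                         terminals_per_cluster = 4:8,
                         dendrite_axon_ratio = 3,
                         trunk_length = c(150, 250),
                         stem_length = c(40, 55),
                         cluster_radius = c(8, 14),
                         separation = 1,
                         wiggle = 0.35,
                         seed = 1L) {
  if (separation < 0 || separation > 1) {
    stop("separation must lie in [0, 1]", call. = FALSE)
  }
  if (any(cluster_count_range < 2L)) {
    stop("cluster_count_range must be >= 2", call. = FALSE)
  }
  if (any(terminals_per_cluster < 1L) || any(trunk_length <= 0) ||
      any(stem_length <= 0) || any(cluster_radius <= 0) || wiggle < 0 ||
      dendrite_axon_ratio < 1) {
    stop("all generator ranges must be positive", call. = FALSE)
  }
  structure(
    list(n_neurons = as.integer(n_neurons),
         cluster_count_range = as.integer(cluster_count_range),
         terminals_per_cluster = as.integer(terminals_per_cluster),
         dendrite_axon_ratio = dendrite_axon_ratio,
         trunk_length = trunk_length, stem_length = stem_length,
         cluster_radius = cluster_radius, separation = separation,
         wiggle = wiggle, seed = as.integer(seed)),
    class = "synth_config"
  )
}

runif1 <- function(range) stats::runif(1L, range[1L], range[2L])

unit <- function(v) v / max(sqrt(sum(v^2)), 1e-12)

random_unit <- function() unit(stats::rnorm(3L))

# a unit vector at a given angle (radians) from `dir`
rotate_towards <- function(dir, angle) {
  perp <- stats::rnorm(3L)
  perp <- unit(perp - sum(perp * dir) * dir)
  unit(cos(angle) * dir + sin(angle) * perp)
}

#' Generate one synthetic projection neuron
#'
#' Builds the skeleton point by point: a random-walk trunk from the soma,
#' cluster attachment points at trunk path fractions drawn per class (the
#' dendrite/axon gap proportional to `separation`), and per cluster a stem
#' plus a balanced random arbor whose polyline wiggle — hence tortuosity —
#' is larger for dendrites by an amount proportional to `separation`.
#' Complex neurons (more than two clusters) receive middle clusters of
#' random class whose tortuosity follows their class. All terminals are
#' labeled; the skeleton type column carries the labels (2 = axon,
#' 3 = dendrite).
#'
#' Called directly it seeds the generator from `config$seed`; inside
#' [generate_dataset()] the surrounding RNG stream is used.
#'
#' @param config A [synth_config()].
#' @param name Neuron identifier.
#' @param .seeded Internal: set `TRUE` when the RNG is already seeded.
#' @return List with `skeleton` (a [neuron_skeleton]), `labels` (terminal
#'   label tibble), `truth` (tibble `terminal_id`, `cluster`, `class`),
#'   `k` (cluster count), and `neuron_class`.
#' @export
generate_neuron <- function(config, name = "synth", .seeded = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  if (!.seeded) set.seed(config$seed)
  delta <- config$separation

  k <- if (length(config$cluster_count_range) == 1L) {
    config$cluster_count_range
  } else {
    sample(config$cluster_count_range, 1L)
  }
  # one dendritic and one axonal end cluster; middles of random class whose
  # attachment position carries no class information. The dendrite/axon
  # attachment gap is proportional to the separation knob, so at delta = 0
  # class and position are independent.
  classes <- c("dendrite",
               if (k > 2L) sample(c("axon", "dendrite"), k - 2L,
                                  replace = TRUE),
               "axon")
  is_middle <- seq_len(k) %in% (if (k > 2L) 2:(k - 1L) else integer(0))
  base_frac <- stats::runif(k, 0.2, 0.8)
  base_frac[is_middle] <- stats::runif(sum(is_middle), 0.35, 0.65)
  shift <- ifelse(classes == "dendrite", -0.35 * delta, 0.35 * delta)
  # middle clusters keep most of their positional ambiguity: their class
  # shows mainly in arbor tortuosity, only weakly in attachment position
  shift[is_middle] <- shift[is_middle] * (0.18 / 0.35)
  frac <- pmin(pmax(base_frac + shift, 0.05), 0.95)

  trunk_len <- runif1(config$trunk_length)
  seg_len <- 8
  ord <- order(frac)
  arc_target <- frac[ord] * trunk_len
  classes <- classes[ord]
  is_middle <- is_middle[ord]

  # ---- point store ----------------------------------------------------
  pts <- list(id = integer(), type = integer(), xyz = NULL,
              parent = integer())
  add_point <- function(xyz, parent, type = 0L) {
    id <- length(pts$id) + 1L
    pts$id[id] <<- id
    pts$type[id] <<- type
    pts$xyz <<- rbind(pts$xyz, xyz)
    pts$parent[id] <<- parent
    id
  }

  soma <- add_point(c(0, 0, 0), -1L, type = 1L)

  # trunk random walk up to the last attachment
  dir <- random_unit()
  cur <- soma
  arc <- 0
  attach_id <- integer(k)
  next_attach <- 1L
  while (next_attach <= k) {
    step <- min(seg_len, arc_target[next_attach] - arc)
    if (step < 1e-6) step <- 1e-6
    dir <- rotate_towards(dir, abs(stats::rnorm(1L, 0, 0.25)))
    cur <- add_point(pts$xyz[cur, ] + step * dir, cur)
    arc <- arc + step
    while (next_attach <= k && arc >= arc_target[next_attach] - 1e-9) {
      attach_id[next_attach] <- cur
      next_attach <- next_attach + 1L
    }
  }

  # wiggly polyline for one branch: chord from a to b, perpendicular
  # sinusoidal offsets scaled by `amp`; returns the far end point id
  grow_edge <- function(from_id, target, amp, type = 0L) {
    a <- pts$xyz[from_id, ]
    chord <- target - a
    len <- sqrt(sum(chord^2))
    u <- unit(chord)
    perp <- stats::rnorm(3L)
    perp <- unit(perp - sum(perp * u) * u)
    prev <- from_id
    n_seg <- 4L
    phase <- stats::runif(1L, 0, pi)
    for (i in seq_len(n_seg)) {
      p <- a + (i / n_seg) * chord +
        sin(i / n_seg * pi + phase) * sin(i / n_seg * pi) * amp * len * perp
      prev <- add_point(p, prev, type = if (i == n_seg) type else 0L)
    }
    prev
  }

  # balanced arbor: split terminal count evenly, scale edge chords by depth
  truth <- NULL
  grow_cluster <- function(ci) {
    cl_class <- classes[ci]
    # per-cluster amplitude jitter: tortuosity is class-typical, not
    # class-deterministic, so local features overlap between classes
    amp <- config$wiggle * exp(stats::rnorm(1L, 0, 0.3)) *
      (if (cl_class == "dendrite") 1 + 0.7 * delta else 1)
    n_term <- sample(rep(config$terminals_per_cluster, 2L), 1L)
    if (cl_class == "dendrite") {
      n_term <- round(n_term * config$dendrite_axon_ratio)
    }
    radius <- runif1(config$cluster_radius)
    depth <- max(1L, ceiling(log2(n_term)))
    edge_len <- radius / depth
    stem <- runif1(config$stem_length)
    tdir <- if (attach_id[ci] == soma) random_unit() else
      unit(pts$xyz[attach_id[ci], ] - pts$xyz[pts$parent[attach_id[ci]], ])
    sdir <- rotate_towards(tdir, stats::runif(1L, 0.9, 1.5))
    croot <- grow_edge(attach_id[ci],
                       pts$xyz[attach_id[ci], ] + stem * sdir,
                       amp = amp * 0.4,
                       type = if (n_term == 1L) type_code(cl_class) else 0L)
    rec <- function(node, n_left) {
      if (n_left == 1L) return(invisible(NULL))
      n1 <- ceiling(n_left / 2); n2 <- n_left - n1
      for (nn in c(n1, n2)) {
        bdir <- rotate_towards(
          unit(pts$xyz[node, ] - pts$xyz[pts$parent[node], ]),
          stats::runif(1L, 0.2, 0.7))
        blen <- edge_len * exp(stats::rnorm(1L, 0, 0.25))
        child <- grow_edge(node, pts$xyz[node, ] + blen * bdir, amp = amp,
                           type = if (nn == 1L) type_code(cl_class) else 0L)
        rec(child, nn)
      }
      invisible(NULL)
    }
    rec(croot, n_term)
    # record ground truth for this cluster's terminals (added points with a
    # terminal type code since the cluster started)
    term_ids <- pts$id[pts$type %in% c(2L, 3L)]
    new_terms <- setdiff(term_ids, truth$terminal_id)
    truth <<- dplyr::bind_rows(
      truth,
      tibble::tibble(terminal_id = new_terms, cluster = ci,
                     class = cl_class,
                     middle = is_middle[ci])
    )
    invisible(NULL)
  }
  for (ci in seq_len(k)) grow_cluster(ci)

  skeleton <- as_neuron_skeleton(
    tibble::tibble(
      point_id = pts$id,
      type_code = pts$type,
      x = round(pts$xyz[, 1L], 4L),
      y = round(pts$xyz[, 2L], 4L),
      z = round(pts$xyz[, 3L], 4L),
      radius = ifelse(pts$type == 1L, 1.5, 0.5),
      parent_id = pts$parent
    ),
    name = name
  )
  labels <- labels_from_types(skeleton)
  list(skeleton = skeleton, labels = labels, truth = truth, k = k,
       neuron_class = if (k == 2L) "simple" else "complex")
}

type_code <- function(class) if (class == "axon") 2L else 3L

#' Generate a synthetic dataset, optionally writing SWC files
#'
#' Draws `config$n_neurons` neurons from [generate_neuron()] under a single
#' seeded RNG stream. When `dir` is given, one SWC file per neuron plus a
#' `manifest.json` (per-neuron class, cluster ground truth and label counts)
#' are written there.
#'
#' @param config A [synth_config()].
#' @param dir Output directory, or `NULL` for in-memory only.
#' @return Tibble with one row per neuron: `neuron`, `neuron_class`, `k`,
#'   `n_terminals`, `n_dendrite`, `n_axon`, and list-columns `skeleton`,
#'   `labels`, `truth`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  rows <- purrr::map(seq_len(config$n_neurons), function(i) {
    nm <- sprintf("synth_%03d", i)
    g <- generate_neuron(config, name = nm, .seeded = TRUE)
    tibble::tibble(
      neuron = nm,
      neuron_class = g$neuron_class,
      k = g$k,
      n_terminals = nrow(g$labels),
      n_dendrite = sum(g$labels$label == "dendrite"),
      n_axon = sum(g$labels$label == "axon"),
      skeleton = list(g$skeleton),
      labels = list(g$labels),
      truth = list(g$truth)
    )
  })
  out <- if (length(rows) == 0L) {
    tibble::tibble(neuron = character(), neuron_class = character(),
                   k = integer(), n_terminals = integer(),
                   n_dendrite = integer(), n_axon = integer(),
                   skeleton = list(), labels = list(), truth = list())
  } else {
    dplyr::bind_rows(rows)
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) {
      ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
    }
    for (i in seq_len(nrow(out))) {
      write_swc(out$skeleton[[i]],
                file.path(dir, paste0(out$neuron[i], ".swc")),
                labels = out$labels[[i]])
    }
    manifest <- purrr::map(seq_len(nrow(out)), function(i) {
      list(
        neuron = out$neuron[i],
        neuron_class = out$neuron_class[i],
        k = out$k[i],
        n_terminals = out$n_terminals[i],
        n_dendrite = out$n_dendrite[i],
        n_axon = out$n_axon[i],
        clusters = out$truth[[i]]
      )
    })
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
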