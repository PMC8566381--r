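#' Read a neuron skeleton from an SWC file
#'
#' Parses the standard whitespace-delimited 7-column SWC format
#' (`id type x y z radius parent`, coordinates in micrometres, `#` comment
#' lines allowed), validates the tree structure, and optionally extracts
#' ground-truth terminal polarity labels.
#'
#' Multiple soma points (type code 1) are contracted to the first one before
#' any downstream tree building, the common SWC idiom for blob-traced somata;
#' the contracted segments contribute no path length.
#'
#' @param path Path to an SWC file.
#' @param label_source Where terminal polarity labels come from:
#'   `"type_column"` reads them off the SWC type codes (2 = axon,
#'   3 = dendrite; terminals with any other code stay unlabeled),
#'   `"sidecar"` reads a two-column TSV (`terminal_id<TAB>axon|dendrite`)
#'   given in `sidecar`, `"none"` returns an empty label map.
#' @param sidecar Path to the sidecar TSV, required when
#'   `label_source = "sidecar"`.
#' @param name Neuron identifier; defaults to the file name without extension.
#' @return A list with elements `skeleton` (a [neuron_skeleton] tibble) and
#'   `labels` (a tibble with columns `point_id`, `label`).
#' @seealso [write_swc()], [as_neuron_skeleton()]
#' @export
read_swc <- function(path, label_source = c("type_column", "sidecar", "none"),
                     sidecar = NULL, name = NULL) {
  label_source <- match.arg(label_source)
  if (!file.exists(path)) {
    stop("SWC file not found: ", path, call. = FALSE)
  }
  if (is.null(name)) {
    name <- sub("\\.[sS][wW][cC]$", "", basename(path))
  }
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  line_no <- seq_along(raw)[keep]
  if (length(lines) == 0L) {
    stop("SWC file contains no data lines: ", path, call. = FALSE)
  }
  fields <- strsplit(trimws(lines), "\\s+")
  n_fields <- lengths(fields)
  bad <- which(n_fields != 7L)
  if (length(bad) > 0L) {
    stop("malformed SWC line ", line_no[bad[1L]], " (expected 7 fields, got ",
         n_fields[bad[1L]], ")", call. = FALSE)
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  )
  nas <- which(rowSums(is.na(vals)) > 0L)
  if (length(nas) > 0L) {
    stop("malformed SWC line ", line_no[nas[1L]], " (non-numeric field)",
         call. = FALSE)
  }
  points <- tibble::tibble(
    point_id  = as.integer(vals[, 1L]),
    type_code = as.integer(vals[, 2L]),
    x = vals[, 3L], y = vals[, 4L], z = vals[, 5L],
    radius    = vals[, 6L],
    parent_id = as.integer(vals[, 7L])
  )
  skeleton <- as_neuron_skeleton(points, name = name)
  labels <- switch(label_source,
    type_column = labels_from_types(skeleton),
    sidecar = read_terminal_labels(sidecar, skeleton),
    none = empty_label_map()
  )
  list(skeleton = skeleton, labels = labels)
}

empty_label_map <- function() {
  tibble::tibble(point_id = integer(), label = character())
}

labels_from_types <- function(skeleton) {
  term <- terminals(skeleton)
  codes <- skeleton$type_code[match(term, skeleton$point_id)]
  keep <- codes %in% c(2L, 3L)
  tibble::tibble(
    point_id = term[keep],
    label = c("axon", "dendrite")[codes[keep] - 1L]
  )
}

#' Read terminal polarity labels from a sidecar TSV
#'
#' The sidecar format is two tab-separated columns, `terminal_id` and
#' `axon|dendrite`, supporting datasets whose SWC type codes are unreliable.
#'
#' @param path Path to the TSV file (no header).
#' @param skeleton Optional [neuron_skeleton]; when given, label ids are
#'   checked to be terminals of the skeleton.
#' @return Tibble with columns `point_id`, `label`.
#' @export
read_terminal_labels <- function(path, skeleton = NULL) {
  if (is.null(path) || !file.exists(path)) {
    stop("terminal label sidecar not found: ",
         if (is.null(path)) "<missing path>" else path, call. = FALSE)
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("point_id", "label"),
                           colClasses = c("integer", "character"))
  lab <- tibble::as_tibble(tab)
  bad <- !lab$label %in% c("axon", "dendrite")
  if (any(bad)) {
    stop("invalid polarity label '", lab$label[which(bad)[1L]],
         "' (expected axon or dendrite)", call. = FALSE)
  }
  if (!is.null(skeleton)) {
    term <- terminals(skeleton)
    extra <- setdiff(lab$point_id, term)
    if (length(extra) > 0L) {
      stop("label sidecar refers to non-terminal point(s): ",
           paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
    }
  }
  lab
}

#' Construct and validate a neuron skeleton
#'
#' Takes a data frame of SWC-style points and returns a validated
#' `neuron_skeleton` tibble: unique positive point ids, exactly one root
#' (`parent_id = -1`), all parents present, and no cycles. Multiple soma
#' points (type 1) are contracted to the first; children of merged points are
#' re-parented onto the retained soma and their original segment lengths are
#' preserved so the contraction adds no path length.
#'
#' @param points Data frame with columns `point_id`, `type_code`, `x`, `y`,
#'   `z`, `radius`, `parent_id`.
#' @param name Neuron identifier.
#' @return A `neuron_skeleton`: a tibble of points with attributes `soma_id`,
#'   `name`, and (when soma contraction rerouted segments) `seg_override`, a
#'   named vector of preserved segment lengths.
#' @export
as_neuron_skeleton <- function(points, name = "neuron") {
  points <- tibble::as_tibble(points)
  req <- c("point_id", "type_code", "x", "y", "z", "radius", "parent_id")
  missing_cols <- setdiff(req, names(points))
  if (length(missing_cols) > 0L) {
    stop("skeleton is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  points <- points[req]
  if (anyDuplicated(points$point_id)) {
    dup <- points$point_id[duplicated(points$point_id)][1L]
    stop("duplicate point_id ", dup, call. = FALSE)
  }
  if (any(points$point_id <= 0L)) {
    stop("point_id must be positive", call. = FALSE)
  }
  if (any(points$radius < 0)) {
    stop("negative radius at point_id ",
         points$point_id[which(points$radius < 0)[1L]], call. = FALSE)
  }
  roots <- points$point_id[points$parent_id == -1L]
  if (length(roots) == 0L) {
    stop("no root point (parent_id -1) found", call. = FALSE)
  }
  if (length(roots) > 1L) {
    stop("multiple roots: point_id ", paste(roots, collapse = ", "),
         call. = FALSE)
  }
  dangling <- setdiff(points$parent_id, c(-1L, points$point_id))
  if (length(dangling) > 0L) {
    bad_pt <- points$point_id[match(dangling[1L], points$parent_id)]
    stop("dangling parent ", dangling[1L], " (referenced by point ", bad_pt,
         ")", call. = FALSE)
  }

  contracted <- contract_soma(points, roots)
  points <- contracted$points
  root <- contracted$root

  # reachability walk from the root doubles as the cycle check
  idx <- match(points$parent_id, points$point_id)
  kids <- split(seq_len(nrow(points)), idx)
  seen <- logical(nrow(points))
  frontier <- which(points$point_id == root)
  seen[frontier] <- TRUE
  while (length(frontier) > 0L) {
    nxt <- unlist(kids[as.character(frontier)], use.names = FALSE)
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  if (!all(seen)) {
    stop("point ", points$point_id[which(!seen)[1L]],
         " is disconnected from the root or lies on a cycle", call. = FALSE)
  }

  structure(
    points,
    soma_id = root,
    name = name,
    seg_override = contracted$seg_override,
    class = c("neuron_skeleton", class(tibble::tibble()))
  )
}

# Merge all type-1 points into one (the root if it is a soma point, else the
# first soma point); rerouted children keep the length of their original
# segment so the soma blob contributes no path length.
contract_soma <- function(points, root) {
  soma_ids <- points$point_id[points$type_code == 1L]
  if (length(soma_ids) <= 1L) {
    return(list(points = points, root = root, seg_override = NULL))
  }
  keep_id <- if (root %in% soma_ids) root else soma_ids[1L]
  drop_ids <- setdiff(soma_ids, keep_id)
  seg_override <- numeric(0)
  first_kept_ancestor <- function(pid) {
    while (pid %in% drop_ids) {
      pid <- points$parent_id[match(pid, points$point_id)]
    }
    pid
  }
  moved <- which(points$parent_id %in% drop_ids &
                   !points$point_id %in% drop_ids)
  for (i in moved) {
    pid <- points$parent_id[i]
    prow <- match(pid, points$point_id)
    seg <- sqrt((points$x[i] - points$x[prow])^2 +
                  (points$y[i] - points$y[prow])^2 +
                  (points$z[i] - points$z[prow])^2)
    new_parent <- if (points$point_id[i] == keep_id) {
      first_kept_ancestor(pid)
    } else {
      keep_id
    }
    if (new_parent == keep_id && points$point_id[i] != keep_id) {
      seg_override[as.character(points$point_id[i])] <- seg
    }
    points$parent_id[i] <- new_parent
  }
  points <- points[!points$point_id %in% drop_ids, , drop = FALSE]
  list(points = points, root = root,
       seg_override = if (length(seg_override)) seg_override else NULL)
}

#' Terminal points of a skeleton
#'
#' Terminals are the degree-one, non-root points: they carry the
#' experimentally determined polarity labels.
#'
#' @param skeleton A [neuron_skeleton].
#' @return Integer vector of terminal point ids, sorted.
#' @export
terminals <- function(skeleton) {
  ids <- skeleton$point_id
  has_child <- ids %in% skeleton$parent_id
  root <- attr(skeleton, "soma_id")
  sort(ids[!has_child & ids != root])
}

#' Write a neuron skeleton to an SWC file
#'
#' Coordinates and radii are printed at fixed 4-decimal precision, so a
#' written file re-reads to an identical skeleton (round-trip identity up to
#' comment lines). When `labels` are given, labeled terminals are written
#' with type code 2 (axon) or 3 (dendrite) and unlabeled terminals with
#' type 0; all other points keep their stored type codes.
#'
#' @param skeleton A [neuron_skeleton].
#' @param path Output file path.
#' @param labels Optional tibble of terminal labels (`point_id`, `label`);
#'   `NULL` preserves the stored type codes unchanged.
#' @return Invisibly, `path`.
#' @export
write_swc <- function(skeleton, path, labels = NULL) {
  type <- skeleton$type_code
  if (!is.null(labels)) {
    term <- terminals(skeleton)
    type[skeleton$point_id %in% term] <- 0L
    hit <- match(labels$point_id, skeleton$point_id)
    if (anyNA(hit)) {
      stop("label refers to unknown point_id ",
           labels$point_id[which(is.na(hit))[1L]], call. = FALSE)
    }
    type[hit] <- ifelse(labels$label == "axon", 2L, 3L)
  }
  lines <- sprintf(
    "%d %d %.4f %.4f %.4f %.4f %d",
    skeleton$point_id, type, skeleton$x, skeleton$y, skeleton$z,
    skeleton$radius, skeleton$parent_id
  )
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) {
    stop("cannot write SWC file: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Write a terminal label sidecar TSV
#'
#' @param labels Tibble with columns `point_id`, `label`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_terminal_labels <- function(labels, path) {
  utils::write.table(labels[, c("point_id", "label")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
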