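#' Linear homotopy between two values
#'
#' `(1 - u) * v0 + u * v1` — straight-line interpolation along the
#' condition axis, used for node and edge weights between two discrete
#' conditions/time points.
#'
#' @param v0,v1 Endpoint values (vectorised).
#' @param u Interpolation parameter in `[0, 1]`.
#' @return Interpolated value(s).
#' @export
interpolate_value <- function(v0, v1, u) {
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1)) {
    abort("interpolation parameter `u` must lie in [0, 1]")
  }
  (1 - u) * v0 + u * v1
}

#' Build an interpolated frame sequence across conditions
#'
#' Interpolates node weights linearly between consecutive conditions and
#' re-evaluates the cut-off rule on the interpolated weight at every frame,
#' so a node whose |weight| crosses below `min_abs_weight` mid-transition
#' disappears at that frame. Edge weights are recomputed from the
#' interpolated node weights with [edge_weight()]; an edge is visible only
#' when both endpoints are. Frames at integer positions along the
#' condition axis reproduce the corresponding per-condition differential
#' networks exactly.
#'
#' Significance is not interpolated: an intermediate frame inherits the
#' significance pass/fail of the transition's source condition for
#' `u < 0.5` and of its destination for `u >= 0.5`
#' (`sig_rule = "nearest"`), or requires both (`sig_rule = "both"`). A
#' node with no measurement at one endpoint ramps from/to weight 0 and is
#' never significance-passing at that endpoint.
#'
#' @param diffnets List of `differential_network`s in condition order (at
#'   least two), sharing one background subnetwork.
#' @param frames_per_transition Number of frames per transition (>= 1).
#' @param th Thresholds applied to interpolated weights; defaults to the
#'   first network's thresholds with `weight_is_interpolated = TRUE`.
#' @param sig_rule `"nearest"` (default) or `"both"`, see Description.
#' @param scale,base_size Visual-encoding parameters (see
#'   [encode_visuals()]); `scale` defaults to the maximal absolute
#'   measured weight across the series, floored at 1.
#' @return A `frame_sequence`: list with tibbles `node_frames` (`frame`,
#'   `t`, `node_id`, `weight`, `size`, `colour_value`, `visible`) and
#'   `edge_frames` (`frame`, `t`, `source_id`, `target_id`,
#'   `interaction_type`, `directed`, `edge_weight`, `visible`), plus
#'   `frames_per_transition`, `condition_labels`, `thresholds`, `scale`,
#'   `base_size`. Frame count is `(C - 1) * frames_per_transition + 1`.
#' @export
build_frames <- function(diffnets, frames_per_transition = 10L, th = NULL,
                         sig_rule = c("nearest", "both"),
                         scale = NULL, base_size = 1) {
  sig_rule <- match.arg(sig_rule)
  C <- length(diffnets)
  if (C < 2) {
    abort(paste0(
      "need at least two conditions to interpolate; ",
      "use the per-condition differential network for a static export"
    ))
  }
  stopifnot(frames_per_transition >= 1)
  purrr::walk(diffnets, function(d) {
    stopifnot(inherits(d, "differential_network"))
  })
  if (is.null(th)) {
    th <- diffnets[[1]]$thresholds
    th$weight_is_interpolated <- TRUE
  }
  background <- diffnets[[1]]$background
  labels <- purrr::map_chr(diffnets, "condition_label")
  universe <- sort(unique(unlist(
    purrr::map(diffnets, function(d) d$measurements$node_id)
  )))
  universe <- intersect(background$nodes$node_id, universe)
  if (is.null(scale)) {
    maxw <- max(c(1, abs(unlist(
      purrr::map(diffnets, function(d) d$measurements$weight)
    ))), na.rm = TRUE)
    scale <- maxw
  }
  # per-condition weight (missing -> 0) and significance-pass vectors
  wmat <- matrix(0, nrow = length(universe), ncol = C,
    dimnames = list(universe, NULL))
  sigp <- matrix(FALSE, nrow = length(universe), ncol = C,
    dimnames = list(universe, NULL))
  for (i in seq_len(C)) {
    m <- diffnets[[i]]$measurements
    m <- m[m$node_id %in% universe & !is.na(m$weight), , drop = FALSE]
    wmat[m$node_id, i] <- m$weight
    ok <- !is.na(m$significance) & m$significance < th$alpha
    sigp[m$node_id[ok], i] <- TRUE
  }
  ed <- filter(background$edges,
    .data$source_id %in% universe & .data$target_id %in% universe)

  frame_at <- function(i, u, frame, t) {
    w <- interpolate_value(wmat[, i], wmat[, i + 1], u)
    sp <- if (sig_rule == "both") {
      sigp[, i] & sigp[, i + 1]
    } else if (u < 0.5) sigp[, i] else sigp[, i + 1]
    visible <- sp & abs(w) >= th$min_abs_weight
    nodes <- tibble(
      frame = frame, t = t, node_id = universe,
      weight = unname(w),
      size = base_size * (1 + abs(unname(w)) / scale),
      colour_value = pmin(pmax(unname(w), -scale), scale),
      visible = unname(visible)
    )
    ew <- if (nrow(ed) > 0) edge_weight(w[ed$source_id], w[ed$target_id]) else numeric()
    edges <- tibble(
      frame = frame, t = t,
      source_id = ed$source_id, target_id = ed$target_id,
      interaction_type = ed$interaction_type, directed = ed$directed,
      edge_weight = unname(ew),
      visible = unname(visible[ed$source_id] & visible[ed$target_id])
    )
    list(nodes = nodes, edges = edges)
  }

  frames <- list(frame_at(1, 0, 1L, 0))
  frame <- 1L
  for (i in seq_len(C - 1)) {
    for (j in seq_len(frames_per_transition)) {
      u <- j / frames_per_transition
      frame <- frame + 1L
      frames <- c(frames, list(
        frame_at(i, u, frame, (i - 1) + u)
      ))
    }
  }
  structure(
    list(
      node_frames = bind_rows(purrr::map(frames, "nodes")),
      edge_frames = bind_rows(purrr::map(frames, "edges")),
      frames_per_transition = as.integer(frames_per_transition),
      condition_labels = labels,
      thresholds = th,
      sig_rule = sig_rule,
      scale = scale,
      base_size = base_size
    ),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf(
    "<frame_sequence> %d frame(s) over %d condition(s) (%s), %d per transition\n",
    max(x$node_frames$frame), length(x$condition_labels),
    paste(x$condition_labels, collapse = " -> "), x$frames_per_transition
  ))
  invisible(x)
}

#' Extract one frame from a sequence
#'
#' @param seq A `frame_sequence`.
#' @param frame Frame index (1-based) or, via `t`, a position along the
#'   condition axis matching an existing frame.
#' @param t Alternative to `frame`.
#' @return List with `nodes` and `edges` tibbles for that frame.
#' @export
get_frame <- function(seq, frame = NULL, t = NULL) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (is.null(frame)) {
    if (is.null(t)) abort("supply `frame` or `t`")
    tv <- unique(seq$node_frames$t)
    hit <- which(abs(tv - t) < 1e-9)
    if (length(hit) == 0) abort(paste0("no frame at t = ", t))
    frame <- unique(seq$node_frames$frame[abs(seq$node_frames$t - tv[hit[1]]) < 1e-9])
  }
  list(
    nodes = filter(seq$node_frames, .data$frame == !!frame),
    edges = filter(seq$edge_frames, .data$frame == !!frame)
  )
}

#' @rdname build_frames
#' @param x A `frame_sequence`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.frame_sequence <- function(x, ...) x$node_frames

#' @rdname build_frames
#' @exportS3Method generics::glance
glance.frame_sequence <- function(x, ...) {
  tibble(
    n_frames = max(x$node_frames$frame),
    n_conditions = length(x$condition_labels),
    frames_per_transition = x$frames_per_transition,
    n_elements = dplyr::n_distinct(x$node_frames$node_id),
    scale = x$scale
  )
}

#' Export / read a frame sequence as structured text
#'
#' One self-describing TSV: comment header lines (`#key: value`) carrying
#' the sequence metadata, then one record per frame per element with a
#' `record_type` column (`node` or `edge`).
#'
#' @param seq A `frame_sequence`.
#' @param path Output file.
#' @return `export_frames` returns `path` invisibly; `read_frames`
#'   returns the parsed `frame_sequence`.
#' @export
export_frames <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"))
  header <- c(
    "#dinet-frames: v1",
    paste0("#conditions: ", paste(seq$condition_labels, collapse = "|")),
    paste0("#frames_per_transition: ", seq$frames_per_transition),
    paste0("#alpha: ", format(seq$thresholds$alpha, digits = 17)),
    paste0("#min_abs_weight: ", format(seq$thresholds$min_abs_weight, digits = 17)),
    paste0("#sig_rule: ", seq$sig_rule),
    paste0("#scale: ", format(seq$scale, digits = 17)),
    paste0("#base_size: ", format(seq$base_size, digits = 17))
  )
  nodes <- mutate(seq$node_frames,
    record_type = "node", source_id = NA_character_,
    target_id = NA_character_, interaction_type = NA_character_,
    directed = NA, edge_weight = NA_real_
  )
  edges <- mutate(seq$edge_frames,
    record_type = "edge", node_id = NA_character_, weight = NA_real_,
    size = NA_real_, colour_value = NA_real_
  )
  cols <- c(
    "record_type", "frame", "t", "node_id", "source_id", "target_id",
    "interaction_type", "directed", "weight", "size", "colour_value",
    "edge_weight", "visible"
  )
  records <- bind_rows(nodes[, cols], edges[, cols]) |>
    arrange(.data$frame, .data$record_type)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(cols, collapse = "\t"), con)
  body <- do.call(paste, c(
    lapply(records, function(col) {
      out <- if (is.numeric(col)) {
        format(col, digits = 17, trim = TRUE, scientific = FALSE)
      } else {
        as.character(col)
      }
      out[is.na(col)] <- ""
      out
    }),
    sep = "\t"
  ))
  writeLines(body, con)
  invisible(path)
}

#' @rdname export_frames
#' @export
read_frames <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  meta <- setNames(
    trimws(sub("^#[^:]+:\\s*", "", hdr)),
    sub("^#([^:]+):.*$", "\\1", hdr)
  )
  body <- lines[!grepl("^#", lines)]
  df <- readr::read_tsv(I(paste(body, collapse = "\n")),
    show_col_types = FALSE, progress = FALSE, na = ""
  )
  nodes <- df |>
    filter(.data$record_type == "node") |>
    select("frame", "t", "node_id", "weight", "size", "colour_value", "visible")
  edges <- df |>
    filter(.data$record_type == "edge") |>
    select("frame", "t", "source_id", "target_id", "interaction_type",
      "directed", "edge_weight", "visible")
  structure(
    list(
      node_frames = nodes, edge_frames = edges,
      frames_per_transition = as.integer(meta[["frames_per_transition"]]),
      condition_labels = strsplit(meta[["conditions"]], "|", fixed = TRUE)[[1]],
      thresholds = thresholds(
        alpha = as.numeric(meta[["alpha"]]),
        min_abs_weight = as.numeric(meta[["min_abs_weight"]]),
        weight_is_interpolated = TRUE
      ),
      sig_rule = meta[["sig_rule"]],
      scale = as.numeric(meta[["scale"]]),
      base_size = as.numeric(meta[["base_size"]])
    ),
    class = "frame_sequence"
  )
}
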