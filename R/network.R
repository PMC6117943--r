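#' Background knowledge network
#'
#' A knowledge network couples a node table and a typed edge table. Nodes are
#' identified by `node_id` (which must match the identifiers used in
#' experimental measurement tables); edges carry an `interaction_type`
#' (`"activation"`, `"inhibition"`, `"binding"` or `"unknown"`) and a
#' `directed` flag. Optional node columns hold a short name, a free-text
#' description, a hierarchical functional-bin code (dot-separated), a cluster
#' assignment, layout coordinates and the node degree.
#'
#' @param nodes A data frame with at least a `node_id` column. Recognised
#'   optional columns: `short_name`, `description`, `bin_code`, `cluster_id`,
#'   `x`, `y`, `degree`. Extra columns are kept.
#' @param edges A data frame with `source_id` and `target_id` columns and
#'   optional `interaction_type` and `directed` columns (defaults
#'   `"unknown"` and `TRUE`).
#' @param name Network name.
#' @param provenance Free-text provenance metadata (e.g. source file and
#'   checksum), a character vector.
#'
#' @return An object of class `knowledge_network`: a list with tibbles
#'   `nodes` and `edges` plus `name` and `provenance`.
#' @examples
#' net <- knowledge_network(
#'   nodes = data.frame(node_id = c("A", "B", "C")),
#'   edges = data.frame(
#'     source_id = c("A", "B"), target_id = c("B", "C"),
#'     interaction_type = c("activation", "inhibition")
#'   )
#' )
#' net
#' @export
knowledge_network <- function(nodes, edges = NULL, name = "network",
                              provenance = character()) {
  nodes <- normalise_node_table(as_tibble(nodes))
  if (is.null(edges)) {
    edges <- tibble(
      source_id = character(), target_id = character(),
      interaction_type = character(), directed = logical()
    )
  }
  edges <- normalise_edge_table(as_tibble(edges))
  net <- structure(
    list(nodes = nodes, edges = edges, name = name, provenance = provenance),
    class = "knowledge_network"
  )
  stop_on_invalid(net)
  net
}

INTERACTION_TYPES <- c("activation", "inhibition", "binding", "unknown")

normalise_node_table <- function(nodes) {
  if (!"node_id" %in% names(nodes)) {
    abort("node table must contain a `node_id` column", class = "dinet_format_error")
  }
  nodes$node_id <- as.character(nodes$node_id)
  defaults <- list(
    short_name = NA_character_, description = NA_character_,
    bin_code = NA_character_, cluster_id = NA_integer_,
    x = NA_real_, y = NA_real_, degree = NA_integer_
  )
  for (col in names(defaults)) {
    if (!col %in% names(nodes)) nodes[[col]] <- defaults[[col]]
  }
  nodes$cluster_id <- as.integer(nodes$cluster_id)
  nodes$degree <- as.integer(nodes$degree)
  nodes$x <- as.numeric(nodes$x)
  nodes$y <- as.numeric(nodes$y)
  select(nodes, "node_id", names(defaults), dplyr::everything())
}

normalise_edge_table <- function(edges, synonyms = NULL) {
  need <- c("source_id", "target_id")
  if (!all(need %in% names(edges))) {
    abort("edge table must contain `source_id` and `target_id` columns",
      class = "dinet_format_error"
    )
  }
  edges$source_id <- as.character(edges$source_id)
  edges$target_id <- as.character(edges$target_id)
  if (!"interaction_type" %in% names(edges)) edges$interaction_type <- "unknown"
  if (!"directed" %in% names(edges)) edges$directed <- TRUE
  edges$interaction_type <- map_interaction_types(edges$interaction_type, synonyms)
  edges$directed <- as.logical(edges$directed)
  select(edges, "source_id", "target_id", "interaction_type", "directed",
    dplyr::everything())
}

#' Map free-text interaction types onto the canonical vocabulary
#'
#' @param x Character vector of raw interaction-type labels.
#' @param synonyms Named character vector mapping raw labels to canonical
#'   types, e.g. `c("act." = "activation")`. Matching is case-insensitive
#'   after trimming. Canonical labels always map to themselves.
#' @return Character vector over `activation`, `inhibition`, `binding`,
#'   `unknown`; unmapped labels become `"unknown"` with a warning.
#' @export
map_interaction_types <- function(x, synonyms = NULL) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x == ""] <- "unknown"
  map <- c(setNames(INTERACTION_TYPES, INTERACTION_TYPES), default_type_synonyms())
  if (!is.null(synonyms)) {
    map <- c(map, setNames(as.character(synonyms), tolower(names(synonyms))))
  }
  out <- unname(map[x])
  bad <- is.na(out)
  if (any(bad)) {
    warn(paste0(
      "unrecognised interaction type(s) mapped to \"unknown\": ",
      paste(unique(x[bad]), collapse = ", ")
    ))
    out[bad] <- "unknown"
  }
  out
}

default_type_synonyms <- function() {
  c(
    "act" = "activation", "act." = "activation", "activates" = "activation",
    "positive" = "activation", "+" = "activation",
    "inh" = "inhibition", "inh." = "inhibition", "inhibits" = "inhibition",
    "repression" = "inhibition", "negative" = "inhibition", "-" = "inhibition",
    "bind" = "binding", "binds" = "binding", "pp" = "binding",
    "interaction" = "binding", "na" = "unknown", "?" = "unknown"
  )
}

stop_on_invalid <- function(net) {
  dup <- net$nodes$node_id[duplicated(net$nodes$node_id)]
  if (length(dup) > 0) {
    abort(
      paste0("duplicate node_id: ", paste(unique(dup), collapse = ", ")),
      class = "dinet_validation_error"
    )
  }
  missing <- setdiff(
    c(net$edges$source_id, net$edges$target_id),
    net$nodes$node_id
  )
  if (length(missing) > 0) {
    abort(
      paste0(
        "edge(s) reference node id(s) absent from the node table: ",
        paste(sort(missing), collapse = ", ")
      ),
      class = "dinet_validation_error"
    )
  }
  invisible(net)
}

#' Convert a knowledge network to an igraph graph
#'
#' Directed edges become arcs; undirected edges are represented as single
#' edges in an undirected graph, or as reciprocal arcs when `directed = TRUE`
#' is forced. Node and edge attributes are carried across.
#'
#' @param net A `knowledge_network`.
#' @param directed `"auto"` (directed graph iff any edge is directed;
#'   undirected edges become reciprocal arcs), `TRUE` or `FALSE` (undirected
#'   view used by degree/community computations).
#' @return An igraph object with a `name` vertex attribute.
#' @export
as_igraph <- function(net, directed = "auto") {
  stopifnot(inherits(net, "knowledge_network"))
  if (identical(directed, "auto")) directed <- any(net$edges$directed)
  if (isTRUE(directed)) {
    ed <- net$edges
    undir <- filter(ed, !.data$directed)
    if (nrow(undir) > 0) {
      back <- rename(undir, source_id = "target_id", target_id = "source_id")
      ed <- bind_rows(ed, back)
    }
    g <- igraph::graph_from_data_frame(
      select(ed, "source_id", "target_id", dplyr::everything()),
      directed = TRUE,
      vertices = net$nodes
    )
  } else {
    g <- igraph::graph_from_data_frame(
      select(net$edges, "source_id", "target_id", dplyr::everything()),
      directed = FALSE,
      vertices = net$nodes
    )
  }
  g
}

#' Extract the subnetwork induced by a node set or a cluster
#'
#' @param net A `knowledge_network`.
#' @param node_ids Character vector of node identifiers, or `NULL` to use
#'   `cluster`.
#' @param cluster A cluster id to select (matched against `nodes$cluster_id`).
#' @return A `knowledge_network` restricted to the selected nodes and the
#'   edges with both endpoints selected.
#' @export
induced_network <- function(net, node_ids = NULL, cluster = NULL) {
  stopifnot(inherits(net, "knowledge_network"))
  if (is.null(node_ids)) {
    if (is.null(cluster)) abort("supply `node_ids` or `cluster`")
    node_ids <- net$nodes$node_id[!is.na(net$nodes$cluster_id) &
      net$nodes$cluster_id == cluster]
  }
  nodes <- filter(net$nodes, .data$node_id %in% node_ids)
  edges <- filter(
    net$edges,
    .data$source_id %in% node_ids & .data$target_id %in% node_ids
  )
  knowledge_network(nodes, edges,
    name = net$name,
    provenance = net$provenance
  )
}

#' @export
print.knowledge_network <- function(x, ...) {
  cat(sprintf(
    "<knowledge_network> %s: %d nodes, %d edges\n",
    x$name, nrow(x$nodes), nrow(x$edges)
  ))
  ncl <- length(unique(stats::na.omit(x$nodes$cluster_id)))
  if (ncl > 0) cat(sprintf("  clusters assigned: %d\n", ncl))
  if (length(x$provenance) > 0) {
    cat("  provenance:", paste(x$provenance, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @rdname knowledge_network
#' @param x A `knowledge_network`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.knowledge_network <- function(x, ...) x$nodes

#' @rdname knowledge_network
#' @exportS3Method generics::glance
glance.knowledge_network <- function(x, ...) {
  tibble(
    name = x$name,
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_clusters = length(unique(stats::na.omit(x$nodes$cluster_id))),
    n_directed_edges = sum(x$edges$directed),
    has_coordinates = all(is.finite(x$nodes$x) & is.finite(x$nodes$y)) &&
      nrow(x$nodes) > 0
  )
}

#' Validate a network (and optionally a measurement series) for consistency
#'
#' Checks referential integrity between edges and nodes, uniqueness of node
#' identifiers, and — when a measurement series is supplied — that every
#' measured identifier exists in the node table and that significance values
#' lie in `[0, 1]`.
#'
#' @param net A `knowledge_network`.
#' @param series Optional `condition_series` to cross-check.
#' @return A list of class `dinet_validation` with `ok` (logical) and
#'   `issues`, a tibble with columns `kind`, `id`, `detail`. Measured
#'   identifiers absent from the network are reported with kind
#'   `"unmatched_measurement"` and should be excluded from analysis.
#' @export
validate_network <- function(net, series = NULL) {
  stopifnot(inherits(net, "knowledge_network"))
  issues <- list()
  dup <- unique(net$nodes$node_id[duplicated(net$nodes$node_id)])
  if (length(dup) > 0) {
    issues <- c(issues, list(tibble(
      kind = "duplicate_node_id", id = dup, detail = "node_id not unique"
    )))
  }
  missing <- sort(unique(setdiff(
    c(net$edges$source_id, net$edges$target_id), net$nodes$node_id
  )))
  if (length(missing) > 0) {
    issues <- c(issues, list(tibble(
      kind = "dangling_edge_endpoint", id = missing,
      detail = "edge endpoint absent from node table"
    )))
  }
  if (!is.null(series)) {
    m <- series$measurements
    unmatched <- sort(unique(setdiff(m$node_id, net$nodes$node_id)))
    if (length(unmatched) > 0) {
      issues <- c(issues, list(tibble(
        kind = "unmatched_measurement", id = unmatched,
        detail = "measured node_id absent from network; excluded from analysis"
      )))
    }
    bad_sig <- m$node_id[!is.na(m$significance) &
      (m$significance < 0 | m$significance > 1)]
    if (length(bad_sig) > 0) {
      issues <- c(issues, list(tibble(
        kind = "significance_out_of_range", id = unique(bad_sig),
        detail = "significance outside [0, 1]"
      )))
    }
  }
  issues <- if (length(issues) > 0) {
    bind_rows(issues)
  } else {
    tibble(kind = character(), id = character(), detail = character())
  }
  structure(list(ok = nrow(issues) == 0, issues = issues),
    class = "dinet_validation"
  )
}

#' @export
print.dinet_validation <- function(x, ...) {
  if (x$ok) {
    cat("network validation: OK\n")
  } else {
    cat(sprintf("network validation: %d issue(s)\n", nrow(x$issues)))
    print(x$issues)
  }
  invisible(x)
}
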