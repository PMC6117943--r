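#' Default GraphML/XGMML attribute-name mapping
#'
#' Exports and imports map package fields to graph attributes by this
#' convention (field = attribute): `node_id = name`/`id`,
#' `short_name = shortName`, `description = annotation`, `bin_code = bin`,
#' `cluster_id = clusterID`, `x = x`, `y = y`, `degree = degree`;
#' edge `interaction_type = type`, `directed = directed`. Cytoscape/yEd
#' exports differ, so the map is user-overridable: supply a named character
#' vector `c(field = "attributeName", ...)` to the readers.
#'
#' @return Named character vector (field = attribute name).
#' @export
graphml_attribute_map <- function() {
  c(
    short_name = "shortName", description = "annotation", bin_code = "bin",
    cluster_id = "clusterID", x = "x", y = "y", degree = "degree",
    interaction_type = "type", directed = "directed"
  )
}

#' Read a knowledge network from GraphML
#'
#' @param path GraphML file path.
#' @param attribute_map Field-to-attribute mapping, see
#'   [graphml_attribute_map()].
#' @return A [knowledge_network()]. Graphs without coordinate attributes get
#'   unset `x`, `y`.
#' @export
read_graphml <- function(path, attribute_map = graphml_attribute_map()) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "dinet_format_error")
  }
  g <- tryCatch(
    igraph::read_graph(path, format = "graphml"),
    error = function(e) {
      abort(paste0("malformed GraphML: ", conditionMessage(e)),
        class = "dinet_parse_error"
      )
    }
  )
  if (igraph::vcount(g) == 0) {
    abort("GraphML contains no nodes", class = "dinet_validation_error")
  }
  va <- igraph::vertex_attr(g)
  if (is.null(va$name)) {
    if (!is.null(va$id)) {
      va$name <- as.character(va$id)
    } else {
      va$name <- as.character(seq_len(igraph::vcount(g)))
    }
  }
  nodes <- tibble(node_id = as.character(va$name))
  for (field in c("short_name", "description", "bin_code", "cluster_id",
    "x", "y", "degree")) {
    attr_name <- attribute_map[[field]]
    if (!is.null(attr_name) && attr_name %in% names(va)) {
      nodes[[field]] <- blank_to_na(va[[attr_name]])
    }
  }
  ed <- igraph::as_data_frame(g, what = "edges")
  edges <- tibble(source_id = as.character(ed$from),
    target_id = as.character(ed$to))
  type_attr <- attribute_map[["interaction_type"]]
  if (type_attr %in% names(ed)) edges$interaction_type <- ed[[type_attr]]
  dir_attr <- attribute_map[["directed"]]
  if (dir_attr %in% names(ed)) {
    edges$directed <- as.logical(as.numeric(ed[[dir_attr]]))
  } else {
    edges$directed <- igraph::is_directed(g)
  }
  knowledge_network(nodes, edges,
    name = tools::file_path_sans_ext(basename(path)),
    provenance = paste0("graphml:", basename(path))
  )
}

blank_to_na <- function(x) {
  if (is.character(x)) x[!is.na(x) & x == ""] <- NA_character_
  if (is.numeric(x)) x[!is.finite(x)] <- NA
  x
}

#' Write a knowledge network to GraphML
#'
#' Lossless for all set fields: unset (NA) attributes are written as empty
#' strings / NaN and restored to NA by [read_graphml()]. Edges are written
#' in a directed graph with a `directed` edge attribute preserving the
#' per-edge flag.
#'
#' @param net A `knowledge_network`.
#' @param path Output file path.
#' @param attribute_map See [graphml_attribute_map()].
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(net, path, attribute_map = graphml_attribute_map()) {
  stopifnot(inherits(net, "knowledge_network"))
  nodes <- net$nodes
  edges <- net$edges
  g <- igraph::graph_from_data_frame(
    select(edges, "source_id", "target_id"),
    directed = TRUE, vertices = select(nodes, "node_id")
  )
  for (field in c("short_name", "description", "bin_code", "cluster_id",
    "x", "y", "degree")) {
    v <- nodes[[field]]
    if (all(is.na(v))) next
    if (is.character(v)) v[is.na(v)] <- ""
    if (is.integer(v)) v <- as.numeric(v)
    g <- igraph::set_vertex_attr(g, attribute_map[[field]], value = v)
  }
  g <- igraph::set_edge_attr(g, attribute_map[["interaction_type"]],
    value = edges$interaction_type
  )
  g <- igraph::set_edge_attr(g, attribute_map[["directed"]],
    value = as.numeric(edges$directed)
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Merge user-defined coordinates from an XGMML file
#'
#' Cytoscape-style XGMML carries node `<graphics x="..." y="...">` records.
#' Coordinates of nodes whose XGMML `label` (or `id`) matches a network
#' `node_id` are overwritten; unmatched network nodes are left untouched and
#' reported. When both the GraphML and the XGMML carry coordinates the XGMML
#' wins (and the merge report says how many were overwritten).
#'
#' @param net A `knowledge_network`.
#' @param path XGMML file path.
#' @return The updated network, with a `merge_report` attribute: tibble with
#'   `n_matched`, `n_overwritten`, `unmatched_network_nodes`,
#'   `unmatched_xgmml_labels` (list columns for the id sets).
#' @export
merge_xgmml_coordinates <- function(net, path) {
  stopifnot(inherits(net, "knowledge_network"))
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("malformed XGMML: ", conditionMessage(e)),
      class = "dinet_parse_error"
    )
  })
  xml2::xml_ns_strip(doc)
  node_els <- xml2::xml_find_all(doc, ".//node")
  coords <- purrr::map_dfr(node_els, function(el) {
    gr <- xml2::xml_find_first(el, "./graphics")
    if (inherits(gr, "xml_missing")) {
      return(tibble(label = character(), x = numeric(), y = numeric()))
    }
    label <- xml2::xml_attr(el, "label")
    if (is.na(label)) label <- xml2::xml_attr(el, "id")
    tibble(
      label = label,
      x = as.numeric(xml2::xml_attr(gr, "x")),
      y = as.numeric(xml2::xml_attr(gr, "y"))
    )
  })
  coords <- filter(coords, !is.na(.data$label) & is.finite(.data$x) &
    is.finite(.data$y))
  if (nrow(coords) == 0) {
    abort("XGMML carries no usable graphics coordinates",
      class = "dinet_validation_error"
    )
  }
  matched <- intersect(coords$label, net$nodes$node_id)
  if (length(matched) == 0) {
    abort("no XGMML node labels match network node identifiers",
      class = "dinet_validation_error"
    )
  }
  had_coords <- net$nodes$node_id[is.finite(net$nodes$x) &
    net$nodes$node_id %in% matched]
  idx <- match(coords$label, net$nodes$node_id)
  keep <- !is.na(idx)
  net$nodes$x[idx[keep]] <- coords$x[keep]
  net$nodes$y[idx[keep]] <- coords$y[keep]
  report <- tibble(
    n_matched = length(matched),
    n_overwritten = length(had_coords),
    unmatched_network_nodes = list(setdiff(net$nodes$node_id, matched)),
    unmatched_xgmml_labels = list(setdiff(coords$label, net$nodes$node_id))
  )
  if (length(report$unmatched_network_nodes[[1]]) > 0) {
    inform(sprintf(
      "XGMML coordinates merged for %d node(s); %d network node(s) unmatched",
      length(matched), length(report$unmatched_network_nodes[[1]])
    ))
  }
  attr(net, "merge_report") <- report
  net
}
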