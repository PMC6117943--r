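#' Clustering pipeline parameters
#'
#' Defaults encode the pipeline's structural rules: communities smaller
#' than `min_cluster_size = 5` nodes are dropped; a cluster is densely
#' connected when its directed edge count reaches `n(n-1)` (within
#' `dense_tolerance`, default accept >= 90 percent); hubs are nodes with
#' degree at or above `hub_fraction = 0.60` of the cluster's maximal
#' degree; star-like clusters need exactly one hub, an edge count within
#' `max(star_edge_slack_abs, star_edge_slack_frac * n)` of `n`, maximal hub
#' closeness and hub betweenness within `star_betweenness_tolerance` of
#' `(n-1)(n-2)/2`; clusters with fewer than `subdivide_min_nodes = 2^10`
#' nodes and fewer than `subdivide_min_edges = 2^11` edges are not
#' subdivided further (`gate_rule = "and"`; set `"or"` to exclude when
#' either count is below threshold); per-cluster layouts switch from
#' Fruchterman-Reingold to Kamada-Kawai above `layout_switch = 2^6` nodes
#' or edges.
#'
#' @param min_cluster_size,dense_tolerance,hub_fraction Structural rule
#'   settings, see Description.
#' @param star_edge_slack_abs,star_edge_slack_frac,star_betweenness_tolerance
#'   Star-likeness tolerances ("close to" bounds), see Description.
#' @param subdivide_min_nodes,subdivide_min_edges,gate_rule Sub-clustering
#'   gate settings.
#' @param layout_switch Node/edge count at or below which the
#'   Fruchterman-Reingold layout is used.
#' @param seed Integer seed driving community detection and layouts.
#' @return A list of class `clustering_params`.
#' @export
clustering_params <- function(min_cluster_size = 5L,
                              dense_tolerance = 0.10,
                              hub_fraction = 0.60,
                              star_edge_slack_abs = 2,
                              star_edge_slack_frac = 0.10,
                              star_betweenness_tolerance = 0.10,
                              subdivide_min_nodes = 2L^10L,
                              subdivide_min_edges = 2L^11L,
                              gate_rule = c("and", "or"),
                              layout_switch = 2L^6L,
                              seed = 1L) {
  gate_rule <- match.arg(gate_rule)
  stopifnot(
    min_cluster_size >= 1, hub_fraction > 0, hub_fraction <= 1,
    dense_tolerance >= 0, dense_tolerance < 1,
    subdivide_min_nodes > 0, subdivide_min_edges > 0, layout_switch > 0
  )
  structure(
    list(
      min_cluster_size = as.integer(min_cluster_size),
      dense_tolerance = dense_tolerance,
      hub_fraction = hub_fraction,
      star_edge_slack_abs = star_edge_slack_abs,
      star_edge_slack_frac = star_edge_slack_frac,
      star_betweenness_tolerance = star_betweenness_tolerance,
      subdivide_min_nodes = as.integer(subdivide_min_nodes),
      subdivide_min_edges = as.integer(subdivide_min_edges),
      gate_rule = gate_rule,
      layout_switch = as.integer(layout_switch),
      seed = as.integer(seed)
    ),
    class = "clustering_params"
  )
}

#' Partition a network with multi-level modularity optimisation
#'
#' Louvain-style multi-level community detection on the undirected simple
#' view of the network. Communities with fewer than `min_cluster_size`
#' nodes are removed from the partition and listed in `dropped`. Retained
#' clusters are renumbered 1..K by decreasing size (ties broken by smallest
#' member identifier) so the labelling is deterministic under a fixed seed.
#'
#' @param net A simplified `knowledge_network`.
#' @param seed Integer seed.
#' @param min_cluster_size Minimum community size retained (default 5).
#' @return A list of class `partition` with `assignment` (tibble `node_id`,
#'   `cluster_id`) and `dropped` (character vector of removed node ids).
#' @export
partition_multilevel <- function(net, seed = 1L, min_cluster_size = 5L) {
  stopifnot(inherits(net, "knowledge_network"))
  if (nrow(net$nodes) == 0) {
    abort("cannot partition an empty network", class = "dinet_validation_error")
  }
  g <- igraph::simplify(as_igraph(net, directed = FALSE))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g)
  memb <- igraph::membership(comm)
  ids <- names(memb)
  raw <- split(ids, as.integer(memb))
  sizes <- lengths(raw)
  keep <- raw[sizes >= min_cluster_size]
  dropped <- sort(unlist(raw[sizes < min_cluster_size], use.names = FALSE))
  if (is.null(dropped)) dropped <- character()
  ord <- order(-lengths(keep), purrr::map_chr(keep, min))
  keep <- keep[ord]
  assignment <- purrr::imap_dfr(keep, function(members, i) {
    tibble(node_id = sort(members), cluster_id = as.integer(i))
  })
  if (nrow(assignment) == 0) {
    assignment <- tibble(node_id = character(), cluster_id = integer())
  }
  structure(
    list(assignment = assignment, dropped = dropped,
      modularity = igraph::modularity(comm)),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  k <- length(unique(x$assignment$cluster_id))
  cat(sprintf(
    "<partition> %d cluster(s) over %d node(s); %d node(s) dropped (tiny communities)\n",
    k, nrow(x$assignment), length(x$dropped)
  ))
  invisible(x)
}

#' @rdname partition_multilevel
#' @param x A `partition`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.partition <- function(x, ...) x$assignment

#' Hub nodes of a cluster subgraph
#'
#' A hub has degree (undirected view) greater than or equal to
#' `hub_fraction` times the maximal degree of the cluster. The maximal-
#' degree node always qualifies, so the hub set is never empty for a
#' non-empty subgraph.
#'
#' @param subnet A `knowledge_network` (one cluster's subgraph).
#' @param hub_fraction Fraction of the maximal degree (default 0.60).
#' @return Character vector of hub node identifiers.
#' @export
find_hubs <- function(subnet, hub_fraction = 0.60) {
  stopifnot(inherits(subnet, "knowledge_network"), nrow(subnet$nodes) > 0)
  deg <- node_degrees(subnet)
  thr <- hub_fraction * max(deg)
  names(deg)[deg >= thr]
}

node_degrees <- function(subnet) {
  counts <- table(c(subnet$edges$source_id, subnet$edges$target_id))
  deg <- setNames(integer(nrow(subnet$nodes)), subnet$nodes$node_id)
  deg[names(counts)] <- as.integer(counts)
  deg
}

#' Structural classification of one cluster
#'
#' Computes per-cluster summary statistics and classifies the cluster:
#' * `densely_connected` — directed edge count (undirected edges count
#'   twice) at least `n(n-1) * (1 - dense_tolerance)`, i.e. approximately
#'   fully connected;
#' * `star_like` — exactly one hub, edge count close to the node count,
#'   maximal hub closeness, and hub betweenness in the undirected subgraph
#'   within tolerance of `(n-1)(n-2)/2` (the exact value for a pure star);
#' * `small` — neither of the above and below the sub-clustering gate
#'   thresholds;
#' * `regular` — everything else (eligible for spinglass subdivision).
#'
#' @param subnet A non-empty `knowledge_network` (one cluster's subgraph).
#' @param params A [clustering_params()].
#' @param cluster_id Optional id recorded in the output.
#' @return One-row tibble of class `cluster_stats`: `cluster_id`,
#'   `n_nodes`, `n_edges`, `n_edges_directed`, `max_degree`, `n_hubs`,
#'   `hub_ids` (list column), `classification`.
#' @export
classify_cluster <- function(subnet, params = clustering_params(),
                             cluster_id = NA_integer_) {
  stopifnot(inherits(subnet, "knowledge_network"), nrow(subnet$nodes) > 0)
  n <- nrow(subnet$nodes)
  m <- nrow(subnet$edges)
  m_dir <- sum(subnet$edges$directed) + 2L * sum(!subnet$edges$directed)
  deg <- node_degrees(subnet)
  max_deg <- max(deg)
  hubs <- find_hubs(subnet, params$hub_fraction)

  dense <- n >= 2 && m_dir >= n * (n - 1) * (1 - params$dense_tolerance)
  star <- FALSE
  if (!dense && n >= 3 && length(hubs) == 1) {
    edge_slack <- max(params$star_edge_slack_abs, params$star_edge_slack_frac * n)
    if (abs(m - n) <= edge_slack) {
      g <- igraph::simplify(as_igraph(subnet, directed = FALSE))
      btw <- igraph::betweenness(g, directed = FALSE)
      cls <- suppressWarnings(igraph::closeness(g))
      hub <- hubs[1]
      target <- (n - 1) * (n - 2) / 2
      star <- isTRUE(cls[hub] >= max(cls, na.rm = TRUE) - 1e-12) &&
        abs(btw[hub] - target) <= params$star_betweenness_tolerance * target
    }
  }
  classification <- if (dense) {
    "densely_connected"
  } else if (star) {
    "star_like"
  } else if (below_gate(n, m, params)) {
    "small"
  } else {
    "regular"
  }
  structure(
    tibble(
      cluster_id = as.integer(cluster_id), n_nodes = n, n_edges = m,
      n_edges_directed = as.integer(m_dir), max_degree = as.integer(max_deg),
      n_hubs = length(hubs), hub_ids = list(hubs),
      classification = classification
    ),
    class = c("cluster_stats", class(tibble()))
  )
}

below_gate <- function(n_nodes, n_edges, params) {
  below_n <- n_nodes < params$subdivide_min_nodes
  below_m <- n_edges < params$subdivide_min_edges
  if (identical(params$gate_rule, "and")) below_n && below_m else below_n || below_m
}

#' Sub-clustering eligibility gate
#'
#' A cluster is clustered further (spinglass) only when it is `regular` —
#' densely connected and star-like clusters are excluded — and its size is
#' not below the gate thresholds (fewer than `2^10` nodes and fewer than
#' `2^11` edges under the default AND rule).
#'
#' @param stats A `cluster_stats` row (see [classify_cluster()]).
#' @param params A [clustering_params()].
#' @return Logical: eligible for subdivision.
#' @export
subdivision_gate <- function(stats, params = clustering_params()) {
  stats$classification == "regular" &
    !purrr::map2_lgl(stats$n_nodes, stats$n_edges, below_gate, params = params)
}

#' Subdivide a cluster with spinglass community detection
#'
#' Runs the spinglass algorithm with as many spins as the cluster has hub
#' nodes (`k`), yielding at most `k` sub-clusters. Spinglass requires a
#' connected graph; a disconnected cluster is subdivided per connected
#' component with spins allocated by per-component hub counts (at least one
#' each), with a warning.
#'
#' @param subnet A `knowledge_network` (one cluster's subgraph).
#' @param k Spin count, normally the number of hubs; capped at the
#'   component size.
#' @param seed Integer seed (spinglass is stochastic).
#' @param hub_fraction Used only to re-locate hubs per component when the
#'   graph is disconnected.
#' @return A `partition` whose `assignment` maps node_id to sub-cluster ids
#'   1..K (K <= k); `dropped` is empty.
#' @export
subdivide_spinglass <- function(subnet, k, seed = 1L, hub_fraction = 0.60) {
  stopifnot(inherits(subnet, "knowledge_network"), k >= 1)
  n <- nrow(subnet$nodes)
  if (k == 1 || n == 1) {
    return(structure(
      list(assignment = tibble(node_id = sort(subnet$nodes$node_id),
        cluster_id = 1L), dropped = character()),
      class = "partition"
    ))
  }
  g <- igraph::simplify(as_igraph(subnet, directed = FALSE))
  comps <- igraph::components(g)
  if (comps$no == 1) {
    memb <- spinglass_membership(g, k, seed)
  } else {
    warn(sprintf(
      "cluster is disconnected (%d components); subdividing per component",
      comps$no
    ))
    hubs <- find_hubs(subnet, hub_fraction)
    memb <- integer(0)
    offset <- 0L
    for (ci in seq_len(comps$no)) {
      vids <- names(comps$membership)[comps$membership == ci]
      sub_g <- igraph::induced_subgraph(g, vids)
      k_c <- max(1L, sum(hubs %in% vids))
      mc <- if (k_c == 1 || length(vids) < 3) {
        setNames(rep(1L, length(vids)), vids)
      } else {
        spinglass_membership(sub_g, k_c, seed + ci)
      }
      memb <- c(memb, mc + offset)
      offset <- offset + max(mc)
    }
  }
  groups <- split(names(memb), memb)
  ord <- order(-lengths(groups), purrr::map_chr(groups, min))
  assignment <- purrr::imap_dfr(groups[ord], function(members, i) {
    tibble(node_id = sort(members), cluster_id = as.integer(i))
  })
  structure(list(assignment = assignment, dropped = character()),
    class = "partition"
  )
}

spinglass_membership <- function(g, k, seed) {
  set.seed(seed)
  comm <- igraph::cluster_spinglass(g, spins = min(k, igraph::vcount(g)))
  m <- igraph::membership(comm)
  setNames(as.integer(m), names(m))
}

#' Per-cluster layout with size-dependent algorithm choice
#'
#' Grid initialisation ([layout_grid()]) followed by Fruchterman-Reingold
#' when the cluster has at most `layout_switch` (default `2^6`) nodes AND
#' at most `layout_switch` edges, otherwise Kamada-Kawai. The chosen
#' algorithm is recorded in the `algorithm` attribute of the result.
#'
#' @param subnet A `knowledge_network` (one cluster's subgraph).
#' @param params A [clustering_params()].
#' @param seed Integer seed.
#' @return Tibble `node_id`, `x`, `y` with attribute `algorithm`
#'   (`"fruchterman_reingold"` or `"kamada_kawai"`).
#' @export
layout_cluster <- function(subnet, params = clustering_params(), seed = 1L) {
  stopifnot(inherits(subnet, "knowledge_network"))
  n <- nrow(subnet$nodes)
  m <- nrow(subnet$edges)
  algorithm <- if (n <= params$layout_switch && m <= params$layout_switch) {
    "fruchterman_reingold"
  } else {
    "kamada_kawai"
  }
  init <- layout_grid(subnet$nodes$node_id)
  if (n == 1) {
    out <- tibble(node_id = subnet$nodes$node_id, x = 0, y = 0)
    attr(out, "algorithm") <- algorithm
    return(out)
  }
  g <- as_igraph(subnet, directed = FALSE)
  set.seed(seed)
  coords <- if (algorithm == "fruchterman_reingold") {
    igraph::layout_with_fr(g, coords = cbind(init$x, init$y), niter = 500)
  } else {
    igraph::layout_with_kk(g, coords = cbind(init$x, init$y), maxiter = 50L * n)
  }
  out <- tibble(node_id = subnet$nodes$node_id, x = coords[, 1], y = coords[, 2])
  attr(out, "algorithm") <- algorithm
  out
}

#' Full clustering pipeline
#'
#' Composes the clustering stages over a simplified network: multi-level
#' community detection with the small-community drop; structural
#' classification of each cluster; spinglass subdivision of eligible
#' clusters into as many sub-clusters as hubs; per-cluster layouts; and
#' degree computation. Sub-cluster identities are hierarchical labels
#' (`"7.1"`, `"7.2"`); a flat integer renumbering is stored in
#' `cluster_id` for table export. Edges between clusters are retained so
#' between-cluster relations are preserved in the edge table.
#'
#' @param net A simplified `knowledge_network` (run [simplify_network()]
#'   first).
#' @param params A [clustering_params()].
#' @return A `knowledge_network` (additional class `clustered_network`)
#'   whose retained nodes all carry `cluster_id`, `cluster_label`, `x`,
#'   `y`, `degree`; attributes `cluster_stats` (classification table),
#'   `dropped` (node ids removed with tiny communities), `layouts`
#'   (per-cluster layout algorithm) and `params`.
#' @export
clusterize <- function(net, params = clustering_params()) {
  stopifnot(inherits(net, "knowledge_network"))
  net <- compute_degrees(net)
  part <- partition_multilevel(net,
    seed = params$seed,
    min_cluster_size = params$min_cluster_size
  )
  top_ids <- sort(unique(part$assignment$cluster_id))
  labels <- setNames(character(nrow(part$assignment)), part$assignment$node_id)
  stats_rows <- list()
  for (cid in top_ids) {
    members <- part$assignment$node_id[part$assignment$cluster_id == cid]
    sub <- induced_network(net, node_ids = members)
    stats <- classify_cluster(sub, params, cluster_id = cid)
    eligible <- subdivision_gate(stats, params)
    stats$subdivided <- eligible
    if (eligible) {
      subpart <- subdivide_spinglass(sub,
        k = stats$n_hubs,
        seed = params$seed + cid, hub_fraction = params$hub_fraction
      )
      labels[subpart$assignment$node_id] <-
        paste0(cid, ".", subpart$assignment$cluster_id)
      stats$n_subclusters <- length(unique(subpart$assignment$cluster_id))
    } else {
      labels[members] <- as.character(cid)
      stats$n_subclusters <- 1L
    }
    stats_rows <- c(stats_rows, list(stats))
  }
  stats <- bind_rows(stats_rows)

  # flat renumbering: numeric-aware ordering of hierarchical labels
  uniq <- unique(labels[order(label_sort_key(labels))])
  flat <- setNames(seq_along(uniq), uniq)

  keep <- net$nodes$node_id %in% names(labels)
  nodes <- net$nodes[keep, , drop = FALSE]
  nodes$cluster_label <- unname(labels[nodes$node_id])
  nodes$cluster_id <- as.integer(flat[nodes$cluster_label])
  edges <- filter(
    net$edges,
    .data$source_id %in% nodes$node_id & .data$target_id %in% nodes$node_id
  )

  layouts <- list()
  for (lab in uniq) {
    members <- nodes$node_id[nodes$cluster_label == lab]
    sub <- induced_network(net, node_ids = members)
    coords <- layout_cluster(sub, params, seed = params$seed + flat[[lab]])
    idx <- match(coords$node_id, nodes$node_id)
    nodes$x[idx] <- coords$x
    nodes$y[idx] <- coords$y
    layouts <- c(layouts, list(tibble(
      cluster_label = lab, cluster_id = as.integer(flat[[lab]]),
      n_nodes = length(members), algorithm = attr(coords, "algorithm")
    )))
  }
  out <- knowledge_network(nodes, edges, name = net$name,
    provenance = net$provenance)
  class(out) <- c("clustered_network", class(out))
  attr(out, "cluster_stats") <- stats
  attr(out, "dropped") <- part$dropped
  attr(out, "layouts") <- bind_rows(layouts)
  attr(out, "params") <- params
  out
}

label_sort_key <- function(labels) {
  parts <- strsplit(labels, ".", fixed = TRUE)
  top <- as.integer(purrr::map_chr(parts, 1))
  sub <- as.integer(purrr::map_chr(parts, function(p) if (length(p) > 1) p[2] else "0"))
  top * 1e6 + sub
}

#' @exportS3Method generics::glance
glance.clustered_network <- function(x, ...) {
  stats <- attr(x, "cluster_stats")
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_clusters = length(unique(x$nodes$cluster_id)),
    n_top_clusters = nrow(stats),
    n_dropped = length(attr(x, "dropped")),
    n_densely_connected = sum(stats$classification == "densely_connected"),
    n_star_like = sum(stats$classification == "star_like"),
    n_subdivided = sum(stats$subdivided)
  )
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement between two partitions of the same node
#' set, corrected for chance: 1 for identical partitions, about 0 for
#' independent ones. Computed from the contingency-table closed form.
#'
#' @param a,b Vectors of cluster labels over the same elements (order
#'   aligned).
#' @return The adjusted Rand index, a real number <= 1.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
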