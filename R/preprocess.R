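#' Simplify a network: drop self-loops and duplicated edges
#'
#' Duplicates are matched per `(source, target, interaction_type)`. For
#' directed edges direction is respected, so reciprocal arcs A->B and B->A
#' are both kept; undirected edges match regardless of endpoint order.
#' Edges of differing interaction type between the same pair stay distinct.
#' The first occurrence of each duplicate group is retained.
#'
#' @param net A `knowledge_network`.
#' @return A list with `network` (the simplified `knowledge_network`) and
#'   `report`, a one-row tibble with `removed_self_loops` and
#'   `removed_duplicate_edges` (original edge count = simplified count +
#'   removed counts). Idempotent: simplifying twice changes nothing.
#' @export
simplify_network <- function(net) {
  stopifnot(inherits(net, "knowledge_network"))
  edges <- net$edges
  is_loop <- edges$source_id == edges$target_id
  n_loops <- sum(is_loop)
  edges <- edges[!is_loop, , drop = FALSE]
  key <- ifelse(
    edges$directed,
    paste("D", edges$source_id, edges$target_id, edges$interaction_type,
      sep = "\r"),
    paste("U", pmin(edges$source_id, edges$target_id),
      pmax(edges$source_id, edges$target_id), edges$interaction_type,
      sep = "\r")
  )
  dup <- duplicated(key)
  n_dup <- sum(dup)
  edges <- edges[!dup, , drop = FALSE]
  out <- net
  out$edges <- edges
  list(
    network = out,
    report = tibble(
      removed_self_loops = n_loops,
      removed_duplicate_edges = n_dup
    )
  )
}

#' Compute node degrees (undirected view)
#'
#' Fills the `degree` node column with the number of incident edges,
#' ignoring edge direction. Expects a simplified network (see
#' [simplify_network()]); the sum of degrees then equals twice the edge
#' count.
#'
#' @param net A `knowledge_network`.
#' @return The network with `nodes$degree` set.
#' @export
compute_degrees <- function(net) {
  stopifnot(inherits(net, "knowledge_network"))
  counts <- table(c(net$edges$source_id, net$edges$target_id))
  net$nodes$degree <- as.integer(counts[net$nodes$node_id])
  net$nodes$degree[is.na(net$nodes$degree)] <- 0L
  net
}

#' Deterministic square-grid positions for a node set
#'
#' Nodes are sorted lexicographically by identifier and placed row-major on
#' the smallest square lattice that holds them: node `i` (1-based, sorted)
#' sits at `x = (i-1) %% side`, `y = (i-1) %/% side` with
#' `side = ceiling(sqrt(n))`.
#'
#' @param node_ids Character vector of node identifiers.
#' @return Tibble `node_id`, `x`, `y` in the original input order.
#' @export
layout_grid <- function(node_ids) {
  node_ids <- as.character(node_ids)
  ord <- order(node_ids, method = "radix")
  n <- length(node_ids)
  side <- max(1L, ceiling(sqrt(n)))
  pos <- tibble(
    node_id = node_ids[ord],
    x = as.numeric((seq_len(n) - 1L) %% side),
    y = as.numeric((seq_len(n) - 1L) %/% side)
  )
  pos[match(node_ids, pos$node_id), , drop = FALSE]
}

#' Assign layout coordinates (grid initialisation + Kamada-Kawai)
#'
#' Nodes without coordinates are initialised on a deterministic square grid
#' ([layout_grid()]) and refined with the Kamada-Kawai force layout under a
#' fixed iteration budget; nodes that already carry user-supplied
#' coordinates are never moved (they anchor the refinement). A single node
#' is placed at the origin. Same network + same seed gives identical
#' coordinates.
#'
#' @param net A `knowledge_network`.
#' @param seed Integer seed (Kamada-Kawai itself is deterministic given the
#'   grid start, but the seed is fixed for contract clarity).
#' @param maxiter Kamada-Kawai iteration budget; default `50 * n`.
#' @return The network with finite `x`, `y` for every node.
#' @export
assign_layout <- function(net, seed = 1L, maxiter = NULL) {
  stopifnot(inherits(net, "knowledge_network"))
  n <- nrow(net$nodes)
  if (n == 0) return(net)
  has_user <- is.finite(net$nodes$x) & is.finite(net$nodes$y)
  if (all(has_user)) return(net)
  if (n == 1) {
    net$nodes$x <- 0
    net$nodes$y <- 0
    return(net)
  }
  if (is.null(maxiter)) maxiter <- 50L * n
  init <- layout_grid(net$nodes$node_id)
  init$x[has_user] <- net$nodes$x[has_user]
  init$y[has_user] <- net$nodes$y[has_user]
  g <- as_igraph(net, directed = FALSE)
  set.seed(seed)
  coords <- igraph::layout_with_kk(
    g, coords = cbind(init$x, init$y), maxiter = maxiter
  )
  net$nodes$x <- ifelse(has_user, net$nodes$x, coords[, 1])
  net$nodes$y <- ifelse(has_user, net$nodes$y, coords[, 2])
  net
}
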