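# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (and igraph's centrality routines) so that
# agreement is informative.

# Brute-force shortest-path betweenness on a tiny undirected graph:
# enumerate every shortest s-t path by depth-limited DFS and count the
# paths passing through each intermediate node. O(n!) worst case; fine
# for n <= 12.
bf_betweenness <- function(nodes, edges) {
  adj <- lapply(setNames(nodes, nodes), function(v) {
    c(edges$target_id[edges$source_id == v], edges$source_id[edges$target_id == v])
  })
  dist_from <- function(s) {
    d <- setNames(rep(Inf, length(nodes)), nodes)
    d[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    d
  }
  all_shortest_paths <- function(s, t, dmax) {
    paths <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        paths[[length(paths) + 1]] <<- path
        return()
      }
      if (length(path) - 1 >= dmax) return()
      for (w in adj[[v]]) {
        if (!w %in% path) walk(c(path, w))
      }
    }
    walk(s)
    paths[vapply(paths, length, integer(1)) == dmax + 1]
  }
  btw <- setNames(rep(0, length(nodes)), nodes)
  for (i in seq_along(nodes)) {
    d <- dist_from(nodes[i])
    for (j in seq_along(nodes)) {
      if (j <= i || is.infinite(d[nodes[j]])) next
      sp <- all_shortest_paths(nodes[i], nodes[j], d[nodes[j]])
      if (length(sp) == 0) next
      through <- table(unlist(lapply(sp, function(p) p[-c(1, length(p))])))
      if (length(through) > 0) {
        btw[names(through)] <- btw[names(through)] +
          as.numeric(through) / length(sp)
      }
    }
  }
  btw
}

# Hypergeometric upper-tail by direct combinatorial summation.
hyper_tail <- function(k, K, N, n) {
  j <- seq(k, min(K, n))
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Small structural builders -------------------------------------------------

star_network <- function(n, directed = FALSE) {
  ids <- c("hub", sprintf("leaf%02d", seq_len(n - 1)))
  knowledge_network(
    data.frame(node_id = ids),
    data.frame(
      source_id = "hub", target_id = ids[-1],
      interaction_type = "activation", directed = directed
    )
  )
}

complete_network <- function(n, directed = TRUE) {
  ids <- sprintf("v%02d", seq_len(n))
  if (directed) {
    pairs <- expand.grid(source_id = ids, target_id = ids,
      stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source_id != pairs$target_id, ]
    edges <- data.frame(pairs, interaction_type = "activation", directed = TRUE)
  } else {
    pairs <- t(utils::combn(ids, 2))
    edges <- data.frame(
      source_id = pairs[, 1], target_id = pairs[, 2],
      interaction_type = "binding", directed = FALSE
    )
  }
  knowledge_network(data.frame(node_id = ids), edges)
}

two_cliques_bridged <- function(n_each = 10) {
  a <- sprintf("a%02d", seq_len(n_each))
  b <- sprintf("b%02d", seq_len(n_each))
  ed <- function(ids) {
    p <- t(utils::combn(ids, 2))
    data.frame(source_id = p[, 1], target_id = p[, 2],
      interaction_type = "binding", directed = FALSE)
  }
  knowledge_network(
    data.frame(node_id = c(a, b)),
    rbind(ed(a), ed(b), data.frame(
      source_id = a[1], target_id = b[1],
      interaction_type = "binding", directed = FALSE
    ))
  )
}

# Well-separated 3-community fixture per the recovery property:
# within-cluster edge probability at least 5x the between-cluster rate.
separated_fixture_spec <- function(seed) {
  fixture_spec(
    clusters = list(
      list(type = "random", n = 30, p = 0.35),
      list(type = "random", n = 40, p = 0.30),
      list(type = "random", n = 50, p = 0.25)
    ),
    n_bridges = 8L, n_conditions = 2L, seed = seed
  )
}

# Wide measurement file for run_analysis()/replay() round trips.
write_toy_inputs <- function(dir) {
  toy <- worked_toy()
  net_file <- file.path(dir, "toy.graphml")
  write_graphml(toy$network, net_file)
  m <- toy$series$measurements
  wide <- data.frame(geneID = unique(m$node_id))
  for (lab in toy$series$labels) {
    mi <- m[m$condition == lab, ]
    idx <- match(wide$geneID, mi$node_id)
    wide[[paste0(lab, "_logFC")]] <- mi$weight[idx]
    wide[[paste0(lab, "_padj")]] <- mi$significance[idx]
  }
  meas_file <- file.path(dir, "toy_measurements.tsv")
  readr::write_tsv(wide, meas_file)
  list(network = net_file, measurements = meas_file, toy = toy)
}

toy_diffnets <- function(th = thresholds(), scale = NULL) {
  toy <- worked_toy()
  if (is.null(scale)) scale <- max(1, abs(toy$series$measurements$weight))
  lapply(toy$series$labels, function(lab) {
    encode_visuals(
      active_subnetwork(toy$network, condition_measurements(toy$series, lab),
        th, condition_label = lab),
      scale = scale
    )
  })
}
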