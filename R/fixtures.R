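#' Specification for synthetic background networks and measurements
#'
#' Describes planted structure (per-cluster topology), inter-cluster
#' bridges, and the generative model for multi-condition measurements:
#' responsive nodes draw |weight| from a shifted folded normal
#' (`effect_shift + |N(0, effect_sd)|`, so effects sit above an intended
#' threshold) with balanced signs and significance uniform on
#' `[0, sig_alpha)`; non-responsive nodes get weight `N(0, noise_sd)` and
#' significance uniform on `[0, 1]`. Between consecutive conditions a
#' fraction `persistence` of the responsive set is kept and the rest
#' resampled, emulating modules switching on and off (network rewiring).
#'
#' @param clusters List of cluster descriptors, each a list with `type`
#'   (`"clique"`, `"star"` or `"random"`), `n` (nodes) and, for random
#'   clusters, `p` (edge probability).
#' @param n_bridges Number of inter-cluster bridge edges.
#' @param n_conditions Number of conditions/time points.
#' @param responsive_fraction Fraction of nodes responsive per condition.
#' @param effect_shift,effect_sd Location and spread of responsive
#'   |weight|.
#' @param noise_sd Spread of non-responsive weights around 0.
#' @param sig_alpha Upper bound of responsive significance values.
#' @param persistence Fraction of the responsive set retained between
#'   consecutive conditions.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(clusters = list(
                           list(type = "clique", n = 10),
                           list(type = "star", n = 9),
                           list(type = "random", n = 30, p = 0.2)
                         ),
                         n_bridges = 3L, n_conditions = 3L,
                         responsive_fraction = 0.3,
                         effect_shift = 1.0, effect_sd = 0.5,
                         noise_sd = 0.15, sig_alpha = 0.05,
                         persistence = 0.7, seed = 1L) {
  stopifnot(
    length(clusters) >= 1,
    all(vapply(clusters, function(cl) cl$n >= 1, logical(1))),
    responsive_fraction >= 0, responsive_fraction <= 1,
    persistence >= 0, persistence <= 1,
    sig_alpha > 0, sig_alpha <= 1, n_conditions >= 1
  )
  structure(
    list(
      clusters = clusters, n_bridges = as.integer(n_bridges),
      n_conditions = as.integer(n_conditions),
      responsive_fraction = responsive_fraction,
      effect_shift = effect_shift, effect_sd = effect_sd,
      noise_sd = noise_sd, sig_alpha = sig_alpha,
      persistence = persistence, seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

#' Generate a background network with planted cluster structure
#'
#' Planted cliques carry all `n(n-1)/2` undirected edges; planted stars
#' have one hub and `n-1` directed edges; random clusters are
#' Erdos-Renyi with the given edge probability. Bridges connect uniformly
#' sampled node pairs from distinct clusters. Deterministic under the
#' spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @return List with `network` (a `knowledge_network`) and `truth`, a
#'   tibble `node_id`, `cluster` (planted label), `topology`.
#' @export
generate_background <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  nodes <- list()
  edges <- list()
  for (ci in seq_along(spec$clusters)) {
    cl <- spec$clusters[[ci]]
    ids <- sprintf("c%02d_n%03d", ci, seq_len(cl$n))
    nodes <- c(nodes, list(tibble(
      node_id = ids, cluster = ci, topology = cl$type
    )))
    e <- switch(cl$type,
      clique = {
        pairs <- utils::combn(ids, 2)
        tibble(
          source_id = pairs[1, ], target_id = pairs[2, ],
          interaction_type = "binding", directed = FALSE
        )
      },
      star = tibble(
        source_id = ids[1], target_id = ids[-1],
        interaction_type = "activation", directed = TRUE
      ),
      random = {
        g <- igraph::sample_gnp(cl$n, cl$p)
        el <- igraph::as_edgelist(g)
        if (nrow(el) == 0) {
          tibble(source_id = character(), target_id = character(),
            interaction_type = character(), directed = logical())
        } else {
          tibble(
            source_id = ids[el[, 1]], target_id = ids[el[, 2]],
            interaction_type = sample(c("activation", "inhibition", "binding"),
              nrow(el), replace = TRUE, prob = c(0.45, 0.35, 0.2)),
            directed = TRUE
          ) |> mutate(directed = .data$interaction_type != "binding")
        }
      },
      abort(paste0("unknown cluster topology: ", cl$type))
    )
    edges <- c(edges, list(e))
  }
  truth <- bind_rows(nodes)
  n_cl <- length(spec$clusters)
  if (n_cl > 1 && spec$n_bridges > 0) {
    cross <- sum(utils::combn(vapply(spec$clusters, function(cl) cl$n,
      numeric(1)), 2, prod))
    if (spec$n_bridges > cross) {
      abort("bridge count exceeds the number of distinct cross-cluster pairs")
    }
    bridges <- purrr::map_dfr(seq_len(spec$n_bridges), function(i) {
      cls <- sample.int(n_cl, 2)
      tibble(
        source_id = sample(truth$node_id[truth$cluster == cls[1]], 1),
        target_id = sample(truth$node_id[truth$cluster == cls[2]], 1),
        interaction_type = "activation", directed = TRUE
      )
    })
    edges <- c(edges, list(bridges))
  }
  net <- knowledge_network(
    select(truth, "node_id"), bind_rows(edges),
    name = "synthetic-background",
    provenance = sprintf("generated: fixture_spec seed=%d", spec$seed)
  )
  list(network = net, truth = truth)
}

#' Generate a multi-condition measurement series over a network
#'
#' See [fixture_spec()] for the generative model. The responsive set of
#' each condition evolves from the previous one (a `persistence` fraction
#' is retained), producing rewiring between conditions.
#'
#' @param net A `knowledge_network`.
#' @param spec A [fixture_spec()].
#' @return List with `series` (a [condition_series()]) and `responsive`,
#'   a tibble `condition`, `node_id` listing the planted responsive sets.
#' @export
generate_measurements <- function(net, spec = fixture_spec()) {
  stopifnot(inherits(net, "knowledge_network"), inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1L)
  ids <- net$nodes$node_id
  n_resp <- round(spec$responsive_fraction * length(ids))
  labels <- sprintf("t%d", seq_len(spec$n_conditions))
  responsive <- list()
  prev <- character()
  rows <- list()
  for (ci in seq_len(spec$n_conditions)) {
    resp <- if (ci == 1 || n_resp == 0) {
      sample(ids, n_resp)
    } else {
      kept <- sample(prev, min(length(prev), round(spec$persistence * n_resp)))
      pool <- setdiff(ids, kept)
      c(kept, sample(pool, n_resp - length(kept)))
    }
    prev <- resp
    is_resp <- ids %in% resp
    w <- rnorm(length(ids), 0, spec$noise_sd)
    sig <- runif(length(ids))
    if (any(is_resp)) {
      k <- sum(is_resp)
      w[is_resp] <- sample(c(-1, 1), k, replace = TRUE) *
        (spec$effect_shift + abs(rnorm(k, 0, spec$effect_sd)))
      sig[is_resp] <- runif(k, 0, spec$sig_alpha)
    }
    rows <- c(rows, list(tibble(
      condition = labels[ci], node_id = ids, weight = w, significance = sig
    )))
    responsive <- c(responsive, list(tibble(
      condition = labels[ci], node_id = sort(resp)
    )))
  }
  list(
    series = condition_series(bind_rows(rows), labels = labels),
    responsive = bind_rows(responsive)
  )
}

#' Fixed worked example: a 12-node, 2-cluster network with 3 conditions
#'
#' A hand-written toy used by the documentation and golden tests: cluster
#' 1 is a 6-node star (hub `a_hub`, directed activation edges), cluster 2
#' a 6-node binding clique, joined by one inhibition bridge. The three
#' conditions show the star module switching off while the clique module
#' switches on (downregulated) — a minimal rewiring event. All values are
#' constants, so the toy is byte-stable across runs.
#'
#' @return List with `network` (a `knowledge_network` with coordinates and
#'   functional-bin codes) and `series` (a [condition_series()] with
#'   conditions `t1`, `t2`, `t3`).
#' @export
worked_toy <- function() {
  star_ids <- c("a_hub", paste0("a_l", 1:5))
  clique_ids <- paste0("b_", sprintf("%02d", 1:6))
  nodes <- tibble(
    node_id = c(star_ids, clique_ids),
    short_name = c(
      "HUB1", "LF1", "LF2", "LF3", "LF4", "LF5",
      "CQ1", "CQ2", "CQ3", "CQ4", "CQ5", "CQ6"
    ),
    bin_code = c(rep("1.1", 6), rep("2.3", 6)),
    x = c(0, -2, -1, 0, 1, 2, 5, 7, 8, 7, 5, 4),
    y = c(0, 2, 3, 3.5, 3, 2, 0, 0, 2, 4, 4, 2)
  )
  pairs <- utils::combn(clique_ids, 2)
  edges <- bind_rows(
    tibble(
      source_id = "a_hub", target_id = star_ids[-1],
      interaction_type = c("activation", "activation", "inhibition",
        "activation", "inhibition"),
      directed = TRUE
    ),
    tibble(
      source_id = pairs[1, ], target_id = pairs[2, ],
      interaction_type = "binding", directed = FALSE
    ),
    tibble(
      source_id = "a_hub", target_id = "b_01",
      interaction_type = "inhibition", directed = TRUE
    )
  )
  net <- knowledge_network(nodes, edges,
    name = "worked-toy",
    provenance = "built-in worked example (synthetic)"
  )
  w <- c(
    # t1: star module on (up), clique silent
    2.0, 1.6, 1.4, -1.2, 1.8, 1.5, 0.1, -0.2, 0.05, 0.1, -0.1, 0.0,
    # t2: star fading, clique waking (down)
    0.9, 0.6, 0.3, -0.4, 0.7, 0.4, -1.1, -1.4, -0.9, -1.2, -0.3, -0.2,
    # t3: star off, clique fully on (down)
    0.1, 0.2, -0.1, 0.0, 0.3, 0.1, -2.1, -2.4, -1.8, -2.0, -1.6, -1.9
  )
  s <- c(
    0.001, 0.004, 0.010, 0.020, 0.003, 0.008, 0.60, 0.45, 0.80, 0.70, 0.55, 0.90,
    0.010, 0.030, 0.20, 0.04, 0.020, 0.15, 0.002, 0.001, 0.010, 0.005, 0.30, 0.40,
    0.50, 0.35, 0.70, 0.90, 0.25, 0.60, 0.001, 0.001, 0.002, 0.001, 0.004, 0.003
  )
  ids <- nodes$node_id
  series <- condition_series(tibble(
    condition = rep(c("t1", "t2", "t3"), each = length(ids)),
    node_id = rep(ids, times = 3),
    weight = w,
    significance = s
  ), labels = c("t1", "t2", "t3"))
  list(network = net, series = series)
}
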