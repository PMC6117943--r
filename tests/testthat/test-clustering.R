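test_that("multi-level partitioning recovers planted blocks and drops tiny communities", {
  two <- two_cliques_bridged(10)
  part <- partition_multilevel(two, seed = 4)
  expect_equal(length(unique(part$assignment$cluster_id)), 2)
  sides <- split(part$assignment$node_id, part$assignment$cluster_id)
  expect_true(all(startsWith(sides[[1]], "a")) || all(startsWith(sides[[1]], "b")))
  expect_length(part$dropped, 0)

  # 20 isolated triangles: all communities below the 5-node retention rule
  tri_nodes <- sprintf("t%02d_%d", rep(1:20, each = 3), 1:3)
  tri_edges <- do.call(rbind, lapply(1:20, function(i) {
    ids <- sprintf("t%02d_%d", i, 1:3)
    data.frame(source_id = ids, target_id = ids[c(2, 3, 1)],
      interaction_type = "binding", directed = FALSE)
  }))
  tris <- knowledge_network(data.frame(node_id = tri_nodes), tri_edges)
  part2 <- partition_multilevel(tris, seed = 1)
  expect_equal(nrow(part2$assignment), 0)
  expect_length(part2$dropped, 60)

  part3 <- partition_multilevel(complete_network(6, directed = FALSE), seed = 1)
  expect_equal(unique(part3$assignment$cluster_id), 1L)
  expect_length(part3$dropped, 0)

  expect_error(
    partition_multilevel(knowledge_network(data.frame(node_id = character()))),
    class = "dinet_validation_error"
  )
})

test_that("hub rule: degree at or above 60 percent of the maximum", {
  # degrees {10, 6, 5, 1}: threshold 6 keeps exactly the 10 and 6 nodes
  hub_net <- function(degs) {
    nodes <- sprintf("h%02d", seq_along(degs))
    leaves <- unlist(lapply(seq_along(degs), function(i) {
      sprintf("l%02d_%02d", i, seq_len(degs[i]))
    }))
    edges <- do.call(rbind, lapply(seq_along(degs), function(i) {
      data.frame(
        source_id = nodes[i],
        target_id = sprintf("l%02d_%02d", i, seq_len(degs[i])),
        interaction_type = "activation", directed = TRUE
      )
    }))
    knowledge_network(data.frame(node_id = c(nodes, leaves)), edges)
  }
  net <- hub_net(c(10, 6, 5))
  hubs <- find_hubs(net, 0.6)
  expect_setequal(hubs, c("h01", "h02"))

  net2 <- hub_net(c(10, 5))
  expect_setequal(find_hubs(net2, 0.6), "h01")

  ring <- knowledge_network(
    data.frame(node_id = sprintf("r%d", 1:6)),
    data.frame(source_id = sprintf("r%d", 1:6),
      target_id = sprintf("r%d", c(2:6, 1)),
      interaction_type = "binding", directed = FALSE)
  )
  expect_length(find_hubs(ring, 0.6), 6)
})

test_that("hub set is never empty (property over random graphs)", {
  set.seed(42)
  for (i in 1:25) {
    g <- igraph::sample_gnp(sample(3:20, 1), runif(1, 0.1, 0.9))
    el <- igraph::as_edgelist(g)
    ids <- sprintf("v%02d", seq_len(igraph::vcount(g)))
    edges <- if (nrow(el) > 0) {
      data.frame(source_id = ids[el[, 1]], target_id = ids[el[, 2]],
        interaction_type = "binding", directed = FALSE)
    } else {
      NULL
    }
    net <- knowledge_network(data.frame(node_id = ids), edges)
    expect_gt(length(find_hubs(net, 0.6)), 0)
  }
})

test_that("classification: dense complete graphs, star-like stars, cycles are neither", {
  k4 <- classify_cluster(complete_network(4, directed = TRUE))
  expect_equal(k4$n_edges_directed, 12L) # n(n-1) = 4*3 arcs
  expect_equal(k4$classification, "densely_connected")

  s9 <- classify_cluster(star_network(9))
  expect_equal(s9$n_edges, 8L)
  expect_equal(s9$n_hubs, 1L)
  expect_equal(s9$classification, "star_like")

  cyc <- knowledge_network(
    data.frame(node_id = sprintf("c%d", 1:6)),
    data.frame(source_id = sprintf("c%d", 1:6),
      target_id = sprintf("c%d", c(2:6, 1)),
      interaction_type = "binding", directed = FALSE)
  )
  st <- classify_cluster(cyc)
  expect_equal(st$n_hubs, 6L)
  expect_false(st$classification == "star_like")
})

test_that("star oracle: hub betweenness equals (n-1)(n-2)/2 vs brute-force path counting", {
  for (n in 4:12) {
    net <- star_network(n)
    oracle <- bf_betweenness(net$nodes$node_id, net$edges)
    expect_equal(unname(oracle["hub"]), (n - 1) * (n - 2) / 2)
    g <- as_igraph(net, directed = FALSE)
    expect_equal(
      unname(igraph::betweenness(g, directed = FALSE)[net$nodes$node_id]),
      unname(oracle[net$nodes$node_id])
    )
    expect_equal(classify_cluster(net)$classification, "star_like")
  }
})

test_that("dense oracle: complete graphs classify dense; heavy edge removal breaks it", {
  for (n in 3:10) {
    expect_equal(classify_cluster(complete_network(n, TRUE))$classification,
      "densely_connected")
    expect_equal(classify_cluster(complete_network(n, FALSE))$classification,
      "densely_connected")
  }
  # remove just over the 10 percent tolerance worth of arcs from K6
  k6 <- complete_network(6, directed = TRUE)
  m <- nrow(k6$edges) # 30 arcs
  drop <- ceiling(0.1 * m) + 1
  k6$edges <- k6$edges[seq_len(m - drop), ]
  expect_false(classify_cluster(k6)$classification == "densely_connected")
})

test_that("subdivision gate: AND-reading boundaries and classification filter", {
  p <- clustering_params()
  st <- function(class, n, m) {
    tibble::tibble(classification = class, n_nodes = n, n_edges = m)
  }
  expect_true(subdivision_gate(st("regular", 1024, 100), p))
  expect_false(subdivision_gate(st("regular", 1023, 2047), p))
  expect_true(subdivision_gate(st("regular", 1023, 2048), p))
  expect_false(subdivision_gate(st("star_like", 5000, 9000), p))
  expect_false(subdivision_gate(st("densely_connected", 5000, 9000), p))

  p_or <- clustering_params(gate_rule = "or")
  expect_false(subdivision_gate(st("regular", 1024, 100), p_or))
})

test_that("gate monotonicity: growing a regular cluster never loses eligibility", {
  p <- clustering_params()
  set.seed(9)
  for (i in 1:50) {
    n0 <- sample(500:1500, 1)
    m0 <- sample(1000:3000, 1)
    s0 <- tibble::tibble(classification = "regular", n_nodes = n0, n_edges = m0)
    s1 <- tibble::tibble(classification = "regular",
      n_nodes = n0 + sample(0:500, 1), n_edges = m0 + sample(0:1000, 1))
    if (subdivision_gate(s0, p)) expect_true(subdivision_gate(s1, p))
  }
})

test_that("spinglass subdivision recovers planted blocks, k = 1 is identity, seeded runs repeat", {
  two <- two_cliques_bridged(20)
  sub <- subdivide_spinglass(two, k = 2, seed = 5)
  expect_lte(length(unique(sub$assignment$cluster_id)), 2)
  sides <- split(sub$assignment$node_id, sub$assignment$cluster_id)
  expect_setequal(sides[[1]], sprintf("a%02d", 1:20))
  expect_setequal(sides[[2]], sprintf("b%02d", 1:20))

  k1 <- subdivide_spinglass(two, k = 1, seed = 5)
  expect_equal(unique(k1$assignment$cluster_id), 1L)
  expect_setequal(k1$assignment$node_id, two$nodes$node_id)

  again <- subdivide_spinglass(two, k = 2, seed = 5)
  expect_identical(sub$assignment, again$assignment)
})

test_that("spinglass on a disconnected cluster falls back to per-component handling", {
  a <- complete_network(6, directed = FALSE)
  b_ids <- sprintf("z%02d", 1:6)
  pairs <- t(utils::combn(b_ids, 2))
  disc <- knowledge_network(
    data.frame(node_id = c(a$nodes$node_id, b_ids)),
    rbind(a$edges, data.frame(source_id = pairs[, 1], target_id = pairs[, 2],
      interaction_type = "binding", directed = FALSE))
  )
  expect_warning(sub <- subdivide_spinglass(disc, k = 2, seed = 3),
    "disconnected")
  comp_of <- function(id) substr(id, 1, 1)
  by_cluster <- split(sub$assignment$node_id, sub$assignment$cluster_id)
  for (members in by_cluster) {
    expect_equal(length(unique(comp_of(members))), 1)
  }
})

test_that("cluster layout switches algorithm at the 2^6 boundary and is seeded", {
  ring <- function(n) {
    ids <- sprintf("r%03d", seq_len(n))
    knowledge_network(
      data.frame(node_id = ids),
      data.frame(source_id = ids, target_id = ids[c(2:n, 1)],
        interaction_type = "binding", directed = FALSE)
    )
  }
  at_boundary <- layout_cluster(ring(64), seed = 2) # 64 nodes, 64 edges
  expect_equal(attr(at_boundary, "algorithm"), "fruchterman_reingold")
  above <- layout_cluster(ring(65), seed = 2)
  expect_equal(attr(above, "algorithm"), "kamada_kawai")
  again <- layout_cluster(ring(64), seed = 2)
  expect_identical(at_boundary$x, again$x)
  expect_identical(at_boundary$y, again$y)
})

test_that("clusterize recovers planted communities, drops tiny ones, keeps bridges", {
  spec <- separated_fixture_spec(seed = 21)
  bg <- generate_background(spec)
  net <- simplify_network(bg$network)$network
  cn <- clusterize(net, clustering_params(seed = 21))
  est <- cn$nodes$cluster_id[match(bg$truth$node_id, cn$nodes$node_id)]
  keep <- !is.na(est)
  expect_gte(adjusted_rand_index(bg$truth$cluster[keep], est[keep]), 0.9)
  expect_true(all(!is.na(cn$nodes$cluster_id)))
  expect_true(all(is.finite(cn$nodes$x) & is.finite(cn$nodes$y)))
  expect_true(all(!is.na(cn$nodes$degree)))

  # inter-community bridge edges survive into the edge table
  crossing <- merge(
    merge(cn$edges, cn$nodes[c("node_id", "cluster_id")],
      by.x = "source_id", by.y = "node_id"),
    cn$nodes[c("node_id", "cluster_id")],
    by.x = "target_id", by.y = "node_id"
  )
  expect_gt(sum(crossing$cluster_id.x != crossing$cluster_id.y), 0)
})

test_that("a planted 4-node community lands in the dropped list", {
  spec <- fixture_spec(
    clusters = list(
      list(type = "random", n = 30, p = 0.4),
      list(type = "clique", n = 4)
    ),
    n_bridges = 0L, seed = 8
  )
  bg <- generate_background(spec)
  cn <- clusterize(simplify_network(bg$network)$network,
    clustering_params(seed = 8))
  tiny <- bg$truth$node_id[bg$truth$cluster == 2]
  expect_true(all(tiny %in% attr(cn, "dropped")))
  expect_false(any(tiny %in% cn$nodes$node_id))
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(77)
  for (i in 1:10) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})

test_that("clustering is deterministic end to end: identical output tables under one seed", {
  spec <- separated_fixture_spec(seed = 31)
  bg <- generate_background(spec)
  net <- simplify_network(bg$network)$network
  run <- function() {
    cn <- clusterize(net, clustering_params(seed = 31))
    d <- withr::local_tempdir()
    write_cluster_tables(cn, d)
    list(
      nodes = readLines(file.path(d, "nodes.tsv")),
      edges = readLines(file.path(d, "edges.tsv")),
      stats = readLines(file.path(d, "stats.tsv"))
    )
  }
  expect_identical(run(), run())
})
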