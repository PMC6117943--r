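test_that("cut-off rule: strict significance, inclusive weight, NA never passes", {
  th <- thresholds(alpha = 0.05, min_abs_weight = 0.5)
  expect_true(node_passes(0.6, 0.04, th))
  expect_true(node_passes(0.5, 0.04, th)) # weight bound is inclusive
  expect_false(node_passes(3.0, 0.05, th)) # significance bound is strict
  expect_false(node_passes(0.49, 0.01, th))
  expect_false(node_passes(NA, 0.01, th))
  expect_false(node_passes(2, NA, th))
  expect_equal(node_passes(c(1, -1, 0.2), c(0.01, 0.2, 0.01), th),
    c(TRUE, FALSE, FALSE))
})

test_that("edge weight formula reproduces the printed examples", {
  expect_equal(edge_weight(0, 0), 0)
  expect_equal(edge_weight(1, 1), 1)
  expect_equal(edge_weight(0.5, 0.25), 0.75) # 0.5 + 0.25 < 1
  expect_equal(edge_weight(2, 0.5), 1) # 1 + 0.5 saturates
  expect_error(edge_weight(Inf, 1))
  expect_error(edge_weight(1, NA))
})

test_that("edge weight properties hold over random pairs", {
  set.seed(1)
  wn <- runif(10000, -5, 5)
  wm <- runif(10000, -5, 5)
  ew <- edge_weight(wn, wm)
  expect_true(all(ew >= 0 & ew <= 1))
  expect_equal(ew, edge_weight(wm, wn)) # symmetry
  sat <- pmax(abs(wn), abs(wm)) >= 1
  expect_true(all(ew[sat] == 1))
  lin <- abs(wn) < 1 & abs(wm) < 1 & abs(wn) + abs(wm) < 1
  expect_equal(ew[lin], abs(wn[lin]) + abs(wm[lin]))
})

path_net <- function() {
  knowledge_network(
    data.frame(node_id = c("A", "B", "C")),
    data.frame(source_id = c("A", "B"), target_id = c("B", "C"),
      interaction_type = "activation", directed = TRUE)
  )
}

test_that("active subnetwork needs both edge endpoints to pass", {
  th <- thresholds()
  m_all <- data.frame(node_id = c("A", "B", "C"), weight = c(1, 2, -1),
    significance = 0.01)
  d <- active_subnetwork(path_net(), m_all, th, "t1")
  expect_setequal(paste(d$edges$source_id, d$edges$target_id),
    c("A B", "B C"))

  m_bfail <- transform(m_all, significance = c(0.01, 0.5, 0.01))
  d2 <- active_subnetwork(path_net(), m_bfail, th, "t1")
  expect_equal(nrow(d2$edges), 0)
  expect_setequal(d2$nodes$node_id, c("A", "C")) # isolated but retained
  # endpoint closure
  expect_true(all(d2$edges$source_id %in% d2$nodes$node_id))
})

test_that("stricter thresholds give nested active sets (100 random threshold pairs)", {
  spec <- fixture_spec(seed = 12)
  bg <- generate_background(spec)
  series <- generate_measurements(bg$network, spec)$series
  m <- condition_measurements(series, "t1")
  net <- simplify_network(bg$network)$network
  set.seed(99)
  for (i in 1:100) {
    a1 <- runif(1, 0.01, 0.2)
    w1 <- runif(1, 0, 1.5)
    a2 <- runif(1, 0.001, a1) # stricter
    w2 <- w1 + runif(1, 0, 1) # stricter
    loose <- active_subnetwork(net, m, thresholds(a1, w1))
    strict <- active_subnetwork(net, m, thresholds(a2, w2))
    expect_true(all(strict$nodes$node_id %in% loose$nodes$node_id))
    expect_true(all(
      paste(strict$edges$source_id, strict$edges$target_id) %in%
        paste(loose$edges$source_id, loose$edges$target_id)
    ))
  }
})

test_that("visual encoding is symmetric, clips at the scale, white at zero", {
  m <- data.frame(node_id = c("A", "B", "C"), weight = c(0, 1.5, -1.5),
    significance = 0.001)
  net <- knowledge_network(data.frame(node_id = c("A", "B", "C")))
  d <- encode_visuals(
    active_subnetwork(net, m, thresholds(min_abs_weight = 0)), scale = 1,
    base_size = 2
  )
  nd <- d$nodes[match(c("A", "B", "C"), d$nodes$node_id), ]
  expect_equal(nd$colour_value[1], 0)
  expect_equal(nd$size[1], 2) # base size at weight 0
  expect_equal(nd$size[2], nd$size[3]) # mirror weights, equal sizes
  expect_equal(nd$colour_value[2], 1) # clipped to +scale
  expect_equal(nd$colour_value[3], -1)
  expect_equal(diverging_colour(0, 1), "#FFFFFF")
  expect_error(encode_visuals(d, scale = 0))
})

test_that("degree filter uses background degree and prunes dangling edges", {
  star <- star_network(6)
  m <- data.frame(node_id = star$nodes$node_id, weight = 2, significance = 0.01)
  d <- active_subnetwork(star, m, thresholds())
  expect_identical(filter_min_degree(d, 0), d)
  d2 <- filter_min_degree(d, 2)
  expect_equal(d2$nodes$node_id, "hub") # only the hub has degree >= 2
  expect_equal(nrow(d2$edges), 0)
})

test_that("module size guard accepts exactly 2..16384 loop-free edges", {
  chain <- function(m, loops = 0) {
    ids <- sprintf("n%05d", seq_len(m + 1))
    edges <- data.frame(source_id = ids[seq_len(m)],
      target_id = ids[seq_len(m) + 1],
      interaction_type = "activation", directed = TRUE)
    if (loops > 0) {
      edges <- rbind(edges, data.frame(source_id = ids[seq_len(loops)],
        target_id = ids[seq_len(loops)],
        interaction_type = "activation", directed = TRUE))
    }
    knowledge_network(data.frame(node_id = ids), edges)
  }
  expect_false(check_module_size(chain(1)))
  expect_true(check_module_size(chain(2)))
  expect_true(check_module_size(chain(16384)))
  expect_false(check_module_size(chain(16385)))
  expect_false(check_module_size(chain(1, loops = 2))) # 3 edges, 2 are loops
  expect_true(check_module_size(chain(2, loops = 2)))
})

test_that("bin enrichment matches the exact combinatorial evaluation", {
  # bin in every cluster node and nowhere else: p = 1 / C(100, 10)
  ids <- sprintf("g%03d", 1:100)
  cl <- ids[1:10]
  ann <- data.frame(node_id = cl, bin_code = "7.2")
  rows <- bin_enrichment(cl, ids, ann)
  expect_equal(rows$p_value[rows$bin_code == "7.2"], 1 / choose(100, 10))
  # ancestor expansion
  expect_true("7" %in% rows$bin_code)
  # identical frequency inside and outside: tail at least 0.5
  ann2 <- data.frame(node_id = ids[c(1:5, 11:55)], bin_code = "3")
  rows2 <- bin_enrichment(ids[1:10], ids, ann2)
  expect_gte(rows2$p_value[rows2$bin_code == "3"], 0.5)
  # single bin: BH adjustment is the identity
  expect_equal(rows2$adjusted_p, rows2$p_value)
  expect_error(bin_enrichment(c("nope"), ids, ann),
    class = "dinet_validation_error")
})

test_that("hypergeometric p agrees with direct combinatorial sums on populations <= 30", {
  set.seed(5)
  for (i in 1:50) {
    N <- sample(5:30, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      hyper_tail(k, K, N, n)
    )
  }
  # and through the package surface on one small case
  ids <- sprintf("x%02d", 1:20)
  ann <- data.frame(node_id = ids[c(1:4, 9:12)], bin_code = "5")
  rows <- bin_enrichment(ids[1:6], ids, ann)
  expect_equal(rows$p_value[rows$bin_code == "5"], hyper_tail(4, 8, 20, 6))
})
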