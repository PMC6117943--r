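test_that("linear homotopy: endpoints, midpoint, affine values, domain check", {
  expect_equal(interpolate_value(1, 3, 0.5), 2)
  expect_equal(interpolate_value(1, 3, 0), 1)
  expect_equal(interpolate_value(1, 3, 1), 3)
  expect_equal(interpolate_value(-2, 2, 0.25), -1)
  expect_error(interpolate_value(0, 1, 1.5))
  expect_error(interpolate_value(0, 1, -0.1))
})

test_that("frame sequences have the contracted length and strictly increasing t", {
  seqs <- build_frames(toy_diffnets(), frames_per_transition = 10)
  expect_equal(max(seqs$node_frames$frame), (3 - 1) * 10 + 1)
  tv <- unique(seqs$node_frames$t)
  expect_true(all(diff(tv) > 0))
  expect_equal(range(tv), c(0, 2))
})

test_that("endpoint frames reproduce the per-condition networks exactly", {
  ds <- toy_diffnets()
  seqs <- build_frames(ds, frames_per_transition = 5)
  for (i in seq_along(ds)) {
    fr <- get_frame(seqs, t = i - 1)
    vis <- fr$nodes[fr$nodes$visible, ]
    expect_setequal(vis$node_id, ds[[i]]$nodes$node_id)
    idx <- match(vis$node_id, ds[[i]]$nodes$node_id)
    expect_identical(vis$weight, ds[[i]]$nodes$weight[idx])
    expect_identical(vis$size, ds[[i]]$nodes$size[idx])
    expect_identical(vis$colour_value, ds[[i]]$nodes$colour_value[idx])
    evis <- fr$edges[fr$edges$visible, ]
    expect_setequal(
      paste(evis$source_id, evis$target_id),
      paste(ds[[i]]$edges$source_id, ds[[i]]$edges$target_id)
    )
    eidx <- match(
      paste(evis$source_id, evis$target_id),
      paste(ds[[i]]$edges$source_id, ds[[i]]$edges$target_id)
    )
    expect_identical(evis$edge_weight, ds[[i]]$edges$edge_weight[eidx])
  }
})

test_that("interpolated weights are linear: midpoint equals the endpoint mean", {
  seqs <- build_frames(toy_diffnets(), frames_per_transition = 2)
  f0 <- get_frame(seqs, t = 0)$nodes
  fm <- get_frame(seqs, t = 0.5)$nodes
  f1 <- get_frame(seqs, t = 1)$nodes
  expect_equal(fm$weight, (f0$weight + f1$weight) / 2)
})

test_that("a node crossing the weight cut-off mid-transition loses visibility there", {
  # weights 1 -> 0 with cut-off 0.5: visible while u < 0.5
  net <- knowledge_network(data.frame(node_id = c("A", "B")),
    data.frame(source_id = "A", target_id = "B"))
  th <- thresholds(alpha = 0.05, min_abs_weight = 0.5)
  m1 <- data.frame(node_id = c("A", "B"), weight = c(1, 1), significance = 0.01)
  m2 <- data.frame(node_id = c("A", "B"), weight = c(0, 1), significance = 0.01)
  ds <- list(
    active_subnetwork(net, m1, th, "t1"),
    active_subnetwork(net, m2, th, "t2")
  )
  seqs <- build_frames(ds, frames_per_transition = 10)
  a <- seqs$node_frames[seqs$node_frames$node_id == "A", ]
  u <- a$t
  expect_equal(a$visible, (1 - u) >= 0.5)
  # visibility consistency for every element in every frame
  expect_true(all(abs(a$weight[a$visible]) >= 0.5))
  b <- seqs$edge_frames
  expect_true(all(!b$visible | (b$edge_weight >= 0)))
})

test_that("constant weights give identical frames throughout", {
  net <- knowledge_network(data.frame(node_id = c("A", "B")),
    data.frame(source_id = "A", target_id = "B"))
  m <- data.frame(node_id = c("A", "B"), weight = 1.2, significance = 0.01)
  ds <- list(
    active_subnetwork(net, m, thresholds(), "t1"),
    active_subnetwork(net, m, thresholds(), "t2")
  )
  seqs <- build_frames(ds, frames_per_transition = 4)
  per_frame <- split(seqs$node_frames[c("node_id", "weight", "visible")],
    seqs$node_frames$frame)
  for (fr in per_frame) {
    rownames(fr) <- NULL
    expect_identical(fr, {
      x <- per_frame[[1]]
      rownames(x) <- NULL
      x
    })
  }
  expect_error(build_frames(ds[1], 5), "two conditions")
})

test_that("frame export round-trips counts and values through the text schema", {
  seqs <- build_frames(toy_diffnets(), frames_per_transition = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_frames(seqs, f)
  back <- read_frames(f)
  expect_equal(back$condition_labels, seqs$condition_labels)
  expect_equal(back$frames_per_transition, seqs$frames_per_transition)
  expect_equal(nrow(back$node_frames), nrow(seqs$node_frames))
  expect_equal(back$node_frames$weight, seqs$node_frames$weight)
  expect_equal(back$edge_frames$edge_weight, seqs$edge_frames$edge_weight)
  expect_equal(back$node_frames$visible, seqs$node_frames$visible)
})

test_that("static SVG rendering is deterministic and styles edge classes distinctly", {
  ds <- toy_diffnets()
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  render_static(ds[[2]], f1)
  render_static(ds[[2]], f2)
  expect_identical(readLines(f1), readLines(f2))
  svg <- paste(readLines(f1), collapse = "\n")
  expect_match(svg, "stroke-dasharray") # binding edges dashed
  expect_match(svg, "url\\(#arrow\\)") # activation arrowheads
  expect_match(svg, "url\\(#tbar\\)") # inhibition terminator

  # empty differential network still renders the grey background
  th_strict <- thresholds(alpha = 0.0001, min_abs_weight = 10)
  toy <- worked_toy()
  empty <- encode_visuals(active_subnetwork(
    toy$network, condition_measurements(toy$series, "t1"), th_strict, "t1"
  ), scale = 1)
  f3 <- withr::local_tempfile(fileext = ".svg")
  render_static(empty, f3)
  expect_match(paste(readLines(f3), collapse = ""), "background-nodes")

  no_coords <- empty
  no_coords$background$nodes$x <- NA_real_
  expect_error(render_static(no_coords, withr::local_tempfile()), "coordinates")
})

test_that("settings-log replay reproduces byte-identical outputs; tampering is flagged", {
  d <- withr::local_tempdir()
  inputs <- write_toy_inputs(d)
  res <- run_analysis(inputs$network, inputs$measurements,
    file.path(d, "out"), seed = 2, frames_per_transition = 4)
  rep <- replay(res$log_file)
  expect_true(attr(rep, "ok"))
  expect_true(all(rep$match))

  # tamper with alpha in the log: outputs no longer match the checksums
  log <- read_settings_log(res$log_file)
  log$parameters$alpha <- 0.5
  tampered <- file.path(d, "tampered.yaml")
  yaml::write_yaml(log, tampered)
  rep2 <- replay(tampered)
  expect_false(attr(rep2, "ok"))

  # log referencing missing inputs errors and names the file
  log$inputs$network_file$file <- file.path(d, "gone.graphml")
  missing <- file.path(d, "missing.yaml")
  yaml::write_yaml(log, missing)
  expect_error(replay(missing), "gone.graphml",
    class = "dinet_validation_error")
})
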