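#' Run the full differential-network analysis and log the settings
#'
#' End-to-end pipeline: read the background network (GraphML) and a wide
#' measurement table, simplify the network, compute degrees and layout,
#' optionally cluster and select one cluster, build the per-condition
#' differential networks, interpolate animation frames, and write all
#' outputs plus a FAIR-style settings log containing every parameter,
#' seed, and a SHA-256 checksum for each input and output file. A logged
#' run can be re-executed and verified with [replay()].
#'
#' @param network_file Background network in GraphML.
#' @param measurements_file Wide measurement table (see
#'   [read_expression_table()]).
#' @param out_dir Output directory, created if needed.
#' @param alpha,min_abs_weight,min_degree Cut-off parameters, see
#'   [thresholds()].
#' @param do_cluster Run [clusterize()] on the network first.
#' @param cluster_id With `do_cluster`, restrict the analysis to this
#'   (flat) cluster id.
#' @param frames_per_transition,sig_rule Animation settings, see
#'   [build_frames()].
#' @param seed Integer seed driving clustering and layouts.
#' @param render Also write a static SVG per condition.
#' @param log_file Settings-log path (default `settings.yaml` in
#'   `out_dir`).
#' @return Invisibly, a list with `diffnets`, `frames`, `outputs` (paths)
#'   and `log_file`.
#' @export
run_analysis <- function(network_file, measurements_file, out_dir,
                         alpha = 0.05, min_abs_weight = 0.5,
                         min_degree = 0L, do_cluster = FALSE,
                         cluster_id = NULL, frames_per_transition = 10L,
                         sig_rule = "nearest", seed = 1L, render = FALSE,
                         log_file = file.path(out_dir, "settings.yaml")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- read_graphml(network_file)
  series <- read_expression_table(measurements_file)
  simp <- simplify_network(net)
  net <- compute_degrees(simp$network)
  if (do_cluster) {
    net <- clusterize(net, clustering_params(seed = seed))
  }
  net <- assign_layout(net, seed = seed)
  sub <- if (!is.null(cluster_id)) {
    induced_network(net, cluster = cluster_id)
  } else {
    net
  }
  if (!check_module_size(sub)) {
    abort(paste0(
      "module size out of the displayable range: ",
      sum(sub$edges$source_id != sub$edges$target_id),
      " loop-free edge(s), need between 2 and 16384"
    ), class = "dinet_validation_error")
  }
  th <- thresholds(alpha = alpha, min_abs_weight = min_abs_weight,
    min_degree = min_degree)
  maxw <- max(c(1, abs(series$measurements$weight)), na.rm = TRUE)
  diffnets <- purrr::map(series$labels, function(lab) {
    active_subnetwork(sub, condition_measurements(series, lab), th,
      condition_label = lab) |>
      filter_min_degree(k = min_degree) |>
      encode_visuals(scale = maxw)
  })
  frames <- build_frames(diffnets,
    frames_per_transition = frames_per_transition,
    sig_rule = sig_rule, scale = maxw
  )
  outputs <- character()
  for (i in seq_along(diffnets)) {
    lab <- gsub("[^A-Za-z0-9._-]", "_", series$labels[i])
    fn <- file.path(out_dir, sprintf("diffnet_%02d_%s_nodes.tsv", i, lab))
    fe <- file.path(out_dir, sprintf("diffnet_%02d_%s_edges.tsv", i, lab))
    write_tsv_plain(diffnets[[i]]$nodes, fn)
    write_tsv_plain(diffnets[[i]]$edges, fe)
    outputs <- c(outputs, fn, fe)
    if (render) {
      fs <- file.path(out_dir, sprintf("static_%02d_%s.svg", i, lab))
      render_static(diffnets[[i]], fs)
      outputs <- c(outputs, fs)
    }
  }
  ff <- file.path(out_dir, "frames.tsv")
  export_frames(frames, ff)
  outputs <- c(outputs, ff)

  config <- list(
    inputs = list(
      network_file = file_record(network_file),
      measurements_file = file_record(measurements_file)
    ),
    parameters = list(
      alpha = alpha, min_abs_weight = min_abs_weight,
      min_degree = as.integer(min_degree), do_cluster = do_cluster,
      cluster_id = cluster_id,
      frames_per_transition = as.integer(frames_per_transition),
      sig_rule = sig_rule, seed = as.integer(seed), render = render
    ),
    outputs = lapply(outputs, file_record)
  )
  write_settings_log(config, log_file)
  invisible(list(
    diffnets = diffnets, frames = frames, outputs = outputs,
    log_file = log_file
  ))
}

file_record <- function(path) {
  list(
    file = path,
    sha256 = digest::digest(file = path, algo = "sha256")
  )
}

#' Write / read the reproducibility settings log
#'
#' Human-readable YAML recording the tool version, a timestamp, and every
#' analysis setting plus SHA-256 checksums of inputs and outputs, so a run
#' is findable, accessible, interoperable and reusable. [replay()]
#' re-executes a logged run and verifies the output checksums.
#'
#' @param config Named list of settings (see [run_analysis()] for the
#'   structure it writes).
#' @param path Log file path.
#' @return `write_settings_log` returns `path` invisibly;
#'   `read_settings_log` returns the parsed list.
#' @export
write_settings_log <- function(config, path) {
  log <- c(
    list(
      tool = "dinet",
      version = as.character(utils::packageVersion("dinet")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    config
  )
  yaml::write_yaml(log, path)
  invisible(path)
}

#' @rdname write_settings_log
#' @export
read_settings_log <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("settings log not found: ", path))
  }
  yaml::read_yaml(path)
}

#' Replay a logged analysis and verify output checksums
#'
#' Re-runs [run_analysis()] with the parameters recorded in a settings
#' log, into a fresh directory, and compares the SHA-256 checksum of every
#' re-created output with the logged one. A mismatch means the log no
#' longer describes the outputs (e.g. a tampered parameter) or the inputs
#' changed.
#'
#' @param log_file Path to a settings log written by [run_analysis()].
#' @param out_dir Directory for the replayed outputs (default: fresh
#'   temporary directory).
#' @return A tibble with `file`, `checksum_logged`, `checksum_replayed`,
#'   `match`; attribute `ok` is `TRUE` when everything matches.
#' @export
replay <- function(log_file, out_dir = tempfile("dinet-replay-")) {
  log <- read_settings_log(log_file)
  inputs <- vapply(log$inputs, function(x) x$file, character(1))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0) {
    abort(paste0(
      "log references missing input file(s): ",
      paste(missing, collapse = ", ")
    ), class = "dinet_validation_error")
  }
  p <- log$parameters
  res <- run_analysis(
    network_file = log$inputs$network_file$file,
    measurements_file = log$inputs$measurements_file$file,
    out_dir = out_dir,
    alpha = p$alpha, min_abs_weight = p$min_abs_weight,
    min_degree = p$min_degree, do_cluster = isTRUE(p$do_cluster),
    cluster_id = p$cluster_id,
    frames_per_transition = p$frames_per_transition,
    sig_rule = p$sig_rule, seed = p$seed, render = isTRUE(p$render)
  )
  logged <- tibble(
    file = basename(vapply(log$outputs, function(x) x$file, character(1))),
    checksum_logged = vapply(log$outputs, function(x) x$sha256, character(1))
  )
  replayed <- tibble(
    file = basename(res$outputs),
    checksum_replayed = vapply(res$outputs, function(f) {
      digest::digest(file = f, algo = "sha256")
    }, character(1))
  )
  out <- dplyr::full_join(logged, replayed, by = "file") |>
    mutate(match = !is.na(.data$checksum_logged) &
      !is.na(.data$checksum_replayed) &
      .data$checksum_logged == .data$checksum_replayed)
  attr(out, "ok") <- all(out$match)
  out
}
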