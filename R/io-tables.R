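#' Read a delimited node table
#'
#' Accepts tab-, comma- or semicolon-separated files with a header row. The
#' documented column schema is `geneID` (or `node_id`), `shortName`,
#' `annotation`, `bin`, `clusterID`, `x`, `y`, `degree`; extra columns are
#' kept silently. Decimal points only (no comma decimals); UTF-8 encoding.
#'
#' @param path File path.
#' @param dialect Separator: `"auto"` (default; sniffed from the header
#'   line), `"\t"`, `","` or `";"`.
#' @return A tibble of node records (see [knowledge_network()] for the
#'   canonical columns).
#' @export
read_node_table <- function(path, dialect = "auto") {
  raw <- read_delim_dialect(path, dialect)
  raw <- rename_by_alias(raw, c(
    node_id = "geneID", node_id = "geneid", node_id = "id",
    short_name = "shortName", short_name = "shortname", short_name = "name",
    description = "annotation", bin_code = "bin", bin_code = "binID",
    cluster_id = "clusterID", cluster_id = "clusterid"
  ))
  if (!"node_id" %in% names(raw)) {
    abort(
      "node table is missing a node identifier column (geneID/node_id)",
      class = "dinet_format_error"
    )
  }
  nodes <- normalise_node_table(raw)
  dup <- unique(nodes$node_id[duplicated(nodes$node_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate node_id: ", paste(dup, collapse = ", ")),
      class = "dinet_validation_error"
    )
  }
  nodes
}

#' Read a delimited edge table
#'
#' Schema: `geneID1`, `geneID2` (or `source_id`, `target_id`), `type`,
#' `directed`; extra columns kept. Interaction types are mapped through
#' [map_interaction_types()]; unmapped types become `"unknown"` with a
#' warning.
#'
#' @inheritParams read_node_table
#' @param nodes Optional node tibble (or `knowledge_network`); when given,
#'   edges referencing absent nodes raise a validation error naming the
#'   offenders. Omit to defer the check to [validate_network()].
#' @param synonyms Extra interaction-type synonyms, named character vector.
#' @return A tibble of edge records.
#' @export
read_edge_table <- function(path, dialect = "auto", nodes = NULL,
                            synonyms = NULL) {
  raw <- read_delim_dialect(path, dialect)
  raw <- rename_by_alias(raw, c(
    source_id = "geneID1", source_id = "geneid1", source_id = "from",
    target_id = "geneID2", target_id = "geneid2", target_id = "to",
    interaction_type = "type"
  ))
  edges <- normalise_edge_table(raw, synonyms = synonyms)
  if (!is.null(nodes)) {
    if (inherits(nodes, "knowledge_network")) nodes <- nodes$nodes
    missing <- sort(unique(setdiff(
      c(edges$source_id, edges$target_id), nodes$node_id
    )))
    if (length(missing) > 0) {
      abort(
        paste0(
          "edge(s) reference node id(s) absent from the node table: ",
          paste(missing, collapse = ", ")
        ),
        class = "dinet_validation_error"
      )
    }
  }
  edges
}

read_delim_dialect <- function(path, dialect = "auto") {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "dinet_format_error")
  }
  if (identical(dialect, "auto")) {
    header <- readLines(path, n = 1L, encoding = "UTF-8")
    counts <- c(
      "\t" = lengths(regmatches(header, gregexpr("\t", header))),
      ";" = lengths(regmatches(header, gregexpr(";", header))),
      "," = lengths(regmatches(header, gregexpr(",", header)))
    )
    if (all(counts == 0)) {
      abort("could not detect a separator in the header row",
        class = "dinet_format_error"
      )
    }
    dialect <- names(counts)[which.max(counts)]
  }
  readr::read_delim(path,
    delim = dialect, show_col_types = FALSE, progress = FALSE,
    locale = readr::locale(decimal_mark = ".", encoding = "UTF-8"),
    na = c("", "NA")
  )
}

rename_by_alias <- function(df, aliases) {
  for (i in seq_along(aliases)) {
    canonical <- names(aliases)[i]
    alias <- aliases[[i]]
    if (!canonical %in% names(df) && alias %in% names(df)) {
      names(df)[names(df) == alias] <- canonical
    }
  }
  df
}

#' Ordered multi-condition measurement series
#'
#' Holds, per condition/time label, a weight (typically log2 fold change)
#' and a significance (typically an adjusted p value in `[0, 1]`) for each
#' measured node.
#'
#' @param measurements A tibble with columns `condition`, `node_id`,
#'   `weight`, `significance`.
#' @param labels Ordered, unique condition labels; defaults to order of
#'   first appearance in `measurements`.
#' @return A `condition_series`: list with `labels` and `measurements`.
#' @export
condition_series <- function(measurements, labels = NULL) {
  measurements <- as_tibble(measurements)
  need <- c("condition", "node_id", "weight", "significance")
  if (!all(need %in% names(measurements))) {
    abort(paste0(
      "measurements need columns: ", paste(need, collapse = ", ")
    ), class = "dinet_format_error")
  }
  measurements$condition <- as.character(measurements$condition)
  measurements$node_id <- as.character(measurements$node_id)
  if (is.null(labels)) labels <- unique(measurements$condition)
  labels <- as.character(labels)
  if (length(labels) == 0 || anyDuplicated(labels) > 0) {
    abort("condition labels must be non-empty and unique",
      class = "dinet_validation_error"
    )
  }
  extra <- setdiff(measurements$condition, labels)
  if (length(extra) > 0) {
    abort(paste0("measurements carry unknown condition(s): ",
      paste(extra, collapse = ", ")), class = "dinet_validation_error")
  }
  bad <- !is.na(measurements$significance) &
    (measurements$significance < 0 | measurements$significance > 1)
  if (any(bad)) {
    abort(
      paste0(
        "significance outside [0, 1] for node(s): ",
        paste(unique(measurements$node_id[bad]), collapse = ", ")
      ),
      class = "dinet_validation_error"
    )
  }
  structure(list(labels = labels, measurements = measurements),
    class = "condition_series"
  )
}

#' @export
print.condition_series <- function(x, ...) {
  cat(sprintf(
    "<condition_series> %d condition(s): %s\n  %d measurements over %d node(s)\n",
    length(x$labels), paste(x$labels, collapse = ", "),
    nrow(x$measurements), length(unique(x$measurements$node_id))
  ))
  invisible(x)
}

#' @rdname condition_series
#' @param x A `condition_series`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.condition_series <- function(x, ...) x$measurements

#' Measurements for one condition
#'
#' @param series A `condition_series`.
#' @param label A condition label from `series$labels`.
#' @return Tibble with `node_id`, `weight`, `significance`.
#' @export
condition_measurements <- function(series, label) {
  stopifnot(inherits(series, "condition_series"))
  if (!label %in% series$labels) {
    abort(paste0("unknown condition label: ", label))
  }
  filter(series$measurements, .data$condition == label) |>
    select("node_id", "weight", "significance")
}

#' Read a wide-layout expression/measurement table
#'
#' Expected layout: one identifier column (`geneID`/`node_id`) followed by
#' one column pair per condition, named `<label><weight_suffix>` and
#' `<label><sig_suffix>` (defaults `_logFC` and `_padj`). Condition order is
#' the order of first appearance of the weight columns.
#'
#' @inheritParams read_node_table
#' @param weight_suffix,sig_suffix Column-name suffixes identifying the
#'   weight and significance column of each pair.
#' @return A [condition_series()].
#' @export
read_expression_table <- function(path, dialect = "auto",
                                  weight_suffix = "_logFC",
                                  sig_suffix = "_padj") {
  raw <- read_delim_dialect(path, dialect)
  raw <- rename_by_alias(raw, c(node_id = "geneID", node_id = "geneid",
    node_id = "id"))
  if (!"node_id" %in% names(raw)) {
    abort("expression table is missing a node identifier column",
      class = "dinet_format_error"
    )
  }
  wcols <- grep(paste0(gsub("([.|()\\^{}+$*?]|\\[|\\])", "\\\\\\1", weight_suffix), "$"),
    names(raw), value = TRUE)
  scols <- grep(paste0(gsub("([.|()\\^{}+$*?]|\\[|\\])", "\\\\\\1", sig_suffix), "$"),
    names(raw), value = TRUE)
  wlab <- sub(paste0(weight_suffix, "$"), "", wcols)
  slab <- sub(paste0(sig_suffix, "$"), "", scols)
  if (length(wlab) == 0) {
    abort("no weight columns found (expected suffix ", weight_suffix, ")",
      class = "dinet_format_error"
    )
  }
  lone <- c(setdiff(wlab, slab), setdiff(slab, wlab))
  if (length(lone) > 0) {
    abort(
      paste0(
        "incomplete weight/significance column pair for condition(s): ",
        paste(lone, collapse = ", ")
      ),
      class = "dinet_format_error"
    )
  }
  long <- purrr::map_dfr(wlab, function(lab) {
    tibble(
      condition = lab,
      node_id = as.character(raw$node_id),
      weight = as.numeric(raw[[paste0(lab, weight_suffix)]]),
      significance = as.numeric(raw[[paste0(lab, sig_suffix)]])
    )
  })
  long <- filter(long, !(is.na(.data$weight) & is.na(.data$significance)))
  condition_series(long, labels = wlab)
}

#' Write per-cluster node and edge tables
#'
#' Emits `nodes.tsv`, `edges.tsv` and `stats.tsv` (when cluster statistics
#' are attached) into `dir`. Edge rows carry the cluster ids of both
#' endpoints so that between-cluster relations are preserved.
#'
#' @param net A clustered `knowledge_network` (see [clusterize()]).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the character vector of files written.
#' @export
write_cluster_tables <- function(net, dir) {
  stopifnot(inherits(net, "knowledge_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- select(net$nodes, "node_id", "cluster_id")
  edges <- net$edges |>
    left_join(rename(cl, source_cluster = "cluster_id"), by = c(source_id = "node_id")) |>
    left_join(rename(cl, target_cluster = "cluster_id"), by = c(target_id = "node_id"))
  files <- file.path(dir, c("nodes.tsv", "edges.tsv"))
  write_tsv_plain(net$nodes, files[1])
  write_tsv_plain(edges, files[2])
  stats <- attr(net, "cluster_stats")
  if (!is.null(stats)) {
    f <- file.path(dir, "stats.tsv")
    write_tsv_plain(select(stats, -dplyr::any_of("hub_ids")) |>
      mutate(hub_ids = purrr::map_chr(stats$hub_ids, paste, collapse = ",")), f)
    files <- c(files, f)
  }
  invisible(files)
}

# readr::write_tsv with NA written as empty string; stable column order
write_tsv_plain <- function(df, path) {
  readr::write_tsv(df, path, na = "", progress = FALSE)
}
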