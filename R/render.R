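#' Diverging red-white-blue colour for a signed value
#'
#' Maps a colour value in `[-scale, scale]` onto a symmetric diverging
#' scale: negative (downregulated) blue, zero white, positive
#' (upregulated) red. Values beyond the scale are clipped.
#'
#' @param value Signed value(s).
#' @param scale Positive half-range of the scale.
#' @return Hex colour string(s).
#' @export
diverging_colour <- function(value, scale = 1) {
  stopifnot(scale > 0)
  p <- (pmin(pmax(value, -scale), scale) / scale + 1) / 2
  ramp <- grDevices::colorRamp(c("#2166AC", "#FFFFFF", "#B2182B"))
  rgb <- ramp(p)
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

#' Render a static SVG snapshot of a differential network or frame
#'
#' Draws the background cluster in grey with the active nodes coloured by
#' the red-blue regulation scale and sized by |weight|. Directed edges get
#' unilateral arrowheads, inhibition edges a T-bar terminator, binding
#' edges are dashed with bilateral arrowheads. Output is built as plain
#' SVG markup, so rendering the same input twice yields byte-identical
#' files.
#'
#' @param diffnet A `differential_network` whose background nodes carry
#'   finite coordinates; run [encode_visuals()] first (unencoded networks
#'   are encoded with `scale = 1`).
#' @param path Output `.svg` path.
#' @param frame Optional single frame (list of `nodes`/`edges` tibbles
#'   from [get_frame()]) to draw instead of the network's own active sets;
#'   only rows with `visible = TRUE` are drawn.
#' @param width,height Canvas size in pixels.
#' @return Invisibly, `path`.
#' @export
render_static <- function(diffnet, path, frame = NULL,
                          width = 600, height = 600) {
  stopifnot(inherits(diffnet, "differential_network"))
  bg <- diffnet$background
  if (!all(is.finite(bg$nodes$x) & is.finite(bg$nodes$y))) {
    abort("background nodes lack coordinates; run assign_layout() first")
  }
  if (is.null(diffnet$encode_scale) && is.null(frame)) {
    diffnet <- encode_visuals(diffnet, scale = 1)
  }
  scale <- diffnet$encode_scale %||% 1
  if (is.null(frame)) {
    active_nodes <- diffnet$nodes
    active_edges <- diffnet$edges
  } else {
    active_nodes <- filter(frame$nodes, .data$visible)
    active_edges <- filter(frame$edges, .data$visible)
  }

  pad <- 30
  xr <- range(bg$nodes$x)
  yr <- range(bg$nodes$y)
  sx <- function(x) {
    if (diff(xr) == 0) return(rep(width / 2, length(x)))
    pad + (x - xr[1]) / diff(xr) * (width - 2 * pad)
  }
  sy <- function(y) {
    if (diff(yr) == 0) return(rep(height / 2, length(y)))
    height - (pad + (y - yr[1]) / diff(yr) * (height - 2 * pad))
  }
  px <- setNames(sx(bg$nodes$x), bg$nodes$node_id)
  py <- setNames(sy(bg$nodes$y), bg$nodes$node_id)
  fmt <- function(v) sprintf("%.2f", v)

  line_el <- function(s, t, style) {
    sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" %s/>',
      fmt(px[s]), fmt(py[s]), fmt(px[t]), fmt(py[t]), style
    )
  }
  edge_style <- function(type, directed, weight = NULL) {
    w <- if (is.null(weight)) 1 else 0.6 + 2.4 * weight
    dash <- if (type == "binding") ' stroke-dasharray="6,4"' else ""
    marker <- if (type == "binding") {
      ' marker-start="url(#arrow-rev)" marker-end="url(#arrow)"'
    } else if (type == "inhibition" && directed) {
      ' marker-end="url(#tbar)"'
    } else if (directed) {
      ' marker-end="url(#arrow)"'
    } else {
      ""
    }
    sprintf('stroke="#333333" stroke-width="%s"%s%s', fmt(w), dash, marker)
  }

  parts <- c(
    sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
      width, height, width, height
    ),
    "<defs>",
    '<marker id="arrow" viewBox="0 0 10 10" refX="9" refY="5" markerWidth="7" markerHeight="7" orient="auto-start-reverse"><path d="M 0 0 L 10 5 L 0 10 z" fill="#333333"/></marker>',
    '<marker id="arrow-rev" viewBox="0 0 10 10" refX="1" refY="5" markerWidth="7" markerHeight="7" orient="auto"><path d="M 10 0 L 0 5 L 10 10 z" fill="#333333"/></marker>',
    '<marker id="tbar" viewBox="0 0 10 10" refX="9" refY="5" markerWidth="7" markerHeight="7" orient="auto"><path d="M 8 0 L 8 10 L 10 10 L 10 0 z" fill="#333333"/></marker>',
    "</defs>",
    sprintf('<rect width="%d" height="%d" fill="#FFFFFF"/>', width, height),
    '<g class="background-edges">',
    vapply(seq_len(nrow(bg$edges)), function(i) {
      line_el(bg$edges$source_id[i], bg$edges$target_id[i],
        'stroke="#CCCCCC" stroke-width="0.7"')
    }, character(1)),
    "</g>",
    '<g class="background-nodes">',
    vapply(seq_len(nrow(bg$nodes)), function(i) {
      sprintf('<circle cx="%s" cy="%s" r="3" fill="#DDDDDD"/>',
        fmt(px[bg$nodes$node_id[i]]), fmt(py[bg$nodes$node_id[i]]))
    }, character(1)),
    "</g>",
    '<g class="active-edges">',
    if (nrow(active_edges) > 0) {
      vapply(seq_len(nrow(active_edges)), function(i) {
        line_el(
          active_edges$source_id[i], active_edges$target_id[i],
          edge_style(active_edges$interaction_type[i],
            active_edges$directed[i], active_edges$edge_weight[i])
        )
      }, character(1))
    } else {
      character()
    },
    "</g>",
    '<g class="active-nodes">',
    if (nrow(active_nodes) > 0) {
      vapply(seq_len(nrow(active_nodes)), function(i) {
        id <- active_nodes$node_id[i]
        sprintf(
          '<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="#333333" stroke-width="0.8"><title>%s</title></circle>',
          fmt(px[id]), fmt(py[id]),
          fmt(3 + 3 * active_nodes$size[i]),
          diverging_colour(active_nodes$colour_value[i], scale), id
        )
      }, character(1))
    } else {
      character()
    },
    "</g>",
    "</svg>"
  )
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>', parts), path,
    useBytes = TRUE)
  invisible(path)
}
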