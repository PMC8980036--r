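# Family heatmaps and styled network exports.
#
# Networks are rendered undirected: family structure needs directions
# internally, but no causal reading is intended, so exports suppress
# arrowheads. Heatmaps plot family members on the y-axis against all
# samples on the x-axis, presence in red and absence in blue — the
# raw-data view of one family.

#' Heatmap specification for one family
#'
#' Extracts the family members' rows and orders the sample columns so
#' that mutational patterns form contiguous blocks.
#'
#' @param fam a `bn_family`.
#' @param m an [event_matrix()] containing the members.
#' @param ordering `"blocks"` (default: samples sorted descending on
#'   the tuple of member values, parents first, giving contiguous
#'   red/blue blocks), `"cluster"` (hierarchical clustering of samples
#'   on member values), or `"input"` (cohort order).
#' @return A `heatmap_spec`: `family`, `members` (parents then child),
#'   `values` (members x samples 0/1 matrix), `column_order`
#'   (permutation of sample ids).
#' @export
family_heatmap_matrix <- function(fam, m,
                                  ordering = c("blocks", "cluster",
                                               "input")) {
  ordering <- match.arg(ordering)
  members <- c(fam$parents, fam$child)
  miss <- setdiff(members, event_names(m))
  if (length(miss) > 0) stop("unknown member(s): ",
                             paste(miss, collapse = ", "))
  sub <- t(unclass(m)[, members, drop = FALSE])  # members x samples
  ord <- switch(ordering,
    input = seq_len(ncol(sub)),
    blocks = do.call(order, c(lapply(seq_len(nrow(sub)),
                                     function(i) -sub[i, ]),
                              list(colnames(sub)))),
    cluster = {
      if (ncol(sub) > 2)
        stats::hclust(stats::dist(t(sub), method = "manhattan"))$order
      else seq_len(ncol(sub))
    })
  structure(list(family = fam, members = members,
                 values = sub[, ord, drop = FALSE],
                 column_order = colnames(sub)[ord]),
            class = "heatmap_spec")
}

#' Render a family heatmap to an image file
#'
#' Presence (1) in red, absence (0) in blue; member names label the
#' y-axis. The device is chosen by file extension: `.png`, `.pdf`, or
#' `.svg`.
#'
#' @param spec a `heatmap_spec` from [family_heatmap_matrix()].
#' @param path output image path.
#' @param width,height device size in inches (default scales with the
#'   member count).
#' @return `path`, invisibly.
#' @export
render_family_heatmap <- function(spec, path, width = 7,
                                  height = 1 + 0.6 * length(spec$members)) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150),
         pdf = grDevices::pdf(path, width = width, height = height),
         svg = grDevices::svg(path, width = width, height = height),
         stop("unsupported image extension: .", ext))
  on.exit(grDevices::dev.off())
  vals <- spec$values
  k <- nrow(vals)
  graphics::par(mar = c(2.5, 8, 2, 1))
  # image() draws row 1 at the bottom; flip so the first member is on top
  graphics::image(x = seq_len(ncol(vals)), y = seq_len(k),
                  z = t(vals[k:1, , drop = FALSE]),
                  col = c("#2166AC", "#B2182B"), zlim = c(0, 1),
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(2, at = seq_len(k), labels = rev(spec$members),
                 las = 2, tick = FALSE, cex.axis = 0.9)
  graphics::mtext(sprintf("family %s (n = %d samples)",
                          spec$family$child, ncol(vals)),
                  side = 3, line = 0.5)
  graphics::mtext("samples", side = 1, line = 1)
  invisible(path)
}

#' Events emphasised as highly mutated
#'
#' The most frequent events are drawn with a bold outline in network
#' exports; by default those above the 95th percentile of event counts.
#'
#' @param m an [event_matrix()].
#' @param quantile frequency quantile above which an event is
#'   emphasised (default 0.95).
#' @return Character vector of emphasised event names.
#' @export
emphasis_nodes <- function(m, quantile = 0.95) {
  counts <- event_counts(m)
  event_names(m)[counts > stats::quantile(counts, quantile, names = FALSE)]
}

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Export a styled network as DOT and/or GraphML
#'
#' Writes an undirected rendering of a learned network: edge colour,
#' line type and width from the Fisher styles, bold outlines on
#' emphasised nodes, and — when gate fits are supplied — a small gate
#' glyph node per fitted family, with in-edges from the parents and an
#' out-edge to the child. A legend comment records the width
#' calibration.
#'
#' @param dag a `bn_dag`.
#' @param styles named list of `edge_style` objects keyed `"a|b"`
#'   (sorted), e.g. from [dag_edge_styles()]; must cover every edge.
#' @param path output path; extension `.dot`/`.gv` or `.graphml`.
#' @param emphasis character vector of node names drawn in bold (e.g.
#'   from [emphasis_nodes()]).
#' @param gated optional list of `gate_fit` objects; when given, gate
#'   glyphs replace the plain child-parent edges of fitted families.
#' @param legend_or odds ratio whose width is quoted in the legend
#'   (default 4).
#' @param width_scale must match the scale used to build the styles
#'   (default 0.5).
#' @return `path`, invisibly.
#' @export
export_network <- function(dag, styles, path, emphasis = character(0),
                           gated = NULL, legend_or = 4,
                           width_scale = 0.5) {
  e <- dag_edges(dag)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  if (nrow(e) > 0) {
    ks <- key(e[, 1], e[, 2])
    miss <- setdiff(ks, names(styles))
    if (length(miss) > 0) stop("missing style for edge(s): ",
                               paste(miss, collapse = ", "))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dot", "gv"))
    write_dot_network(dag, styles, path, emphasis, gated, legend_or,
                      width_scale)
  else if (ext == "graphml")
    write_graphml_network(dag, styles, path, emphasis)
  else stop("unsupported network extension: .", ext)
  invisible(path)
}

write_dot_network <- function(dag, styles, path, emphasis, gated,
                              legend_or, width_scale) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  lines <- c("graph bn {",
             sprintf("  // legend: edge width %.3g corresponds to odds ratio %g",
                     width_scale * legend_or, legend_or),
             "  node [shape=ellipse];")
  for (v in dag$variables) {
    attrs <- if (v %in% emphasis) ' [penwidth=3, color=black]' else ""
    lines <- c(lines, sprintf("  %s%s;", dot_quote(v), attrs))
  }
  gated_children <- character(0)
  if (!is.null(gated) && length(gated) > 0) {
    gated_children <- vapply(gated, function(g) g$family$child,
                             character(1))
    for (g in gated) {
      gid <- paste0("gate_", g$family$child)
      lab <- formula_string(simplify_formula(g$formula))
      root_op <- if (g$formula$op == "VAR") "ID" else g$formula$op
      lines <- c(lines,
                 sprintf("  %s [shape=box, label=%s, fontsize=10];",
                         dot_quote(gid), dot_quote(root_op)),
                 sprintf("  // %s = %s (p = %.3g)", g$family$child, lab,
                         g$p_value))
      for (p in g$family$parents) {
        st <- styles[[key(p, g$family$child)]]
        lines <- c(lines, sprintf(
          "  %s -- %s [color=%s, style=%s, penwidth=%.4g];",
          dot_quote(p), dot_quote(gid), st$colour, st$line, st$width))
      }
      lines <- c(lines, sprintf("  %s -- %s;", dot_quote(gid),
                                dot_quote(g$family$child)))
    }
  }
  e <- dag_edges(dag)
  for (r in seq_len(nrow(e))) {
    if (e[r, 2] %in% gated_children) next  # replaced by the gate glyph
    st <- styles[[key(e[r, 1], e[r, 2])]]
    lines <- c(lines, sprintf(
      "  %s -- %s [color=%s, style=%s, penwidth=%.4g];",
      dot_quote(e[r, 1]), dot_quote(e[r, 2]), st$colour, st$line,
      st$width))
  }
  writeLines(c(lines, "}"), path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

write_graphml_network <- function(dag, styles, path, emphasis) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="colour" for="edge" attr.name="colour" attr.type="string"/>',
    '  <key id="line" for="edge" attr.name="line" attr.type="string"/>',
    '  <key id="width" for="edge" attr.name="width" attr.type="double"/>',
    '  <key id="bold" for="node" attr.name="bold" attr.type="boolean"/>',
    '  <graph id="bn" edgedefault="undirected">')
  for (v in dag$variables)
    lines <- c(lines, sprintf(
      '    <node id="%s"><data key="bold">%s</data></node>',
      xml_escape(v), tolower(v %in% emphasis)))
  e <- dag_edges(dag)
  for (r in seq_len(nrow(e))) {
    st <- styles[[key(e[r, 1], e[r, 2])]]
    lines <- c(lines, sprintf(
      paste0('    <edge source="%s" target="%s">',
             '<data key="colour">%s</data>',
             '<data key="line">%s</data>',
             '<data key="width">%.10g</data></edge>'),
      xml_escape(e[r, 1]), xml_escape(e[r, 2]), st$colour, st$line,
      st$width))
  }
  writeLines(c(lines, "  </graph>", "</graphml>"), path)
}

#' Parse a DOT file written by [export_network()]
#'
#' Recovers node names, emphasis flags, and per-edge style attributes;
#' used to verify that exports round-trip.
#'
#' @param path a `.dot` file produced by this package.
#' @return List with `nodes`, `emphasis`, and `edges` (data frame:
#'   from, to, colour, line, width).
#' @export
parse_dot_network <- function(path) {
  lines <- readLines(path)
  node_re <- '^  "([^"]+)"( \\[penwidth=3, color=black\\])?;$'
  edge_re <- paste0('^  "([^"]+)" -- "([^"]+)"',
                    ' \\[color=(\\w+), style=(\\w+), penwidth=([0-9.eE+-]+)\\];$')
  nodes <- character(0); emph <- character(0)
  ef <- et <- ec <- el <- character(0); ew <- numeric(0)
  for (ln in lines) {
    nm <- regmatches(ln, regexec(node_re, ln))[[1]]
    if (length(nm) > 0) {
      nodes <- c(nodes, nm[2])
      if (nchar(nm[3]) > 0) emph <- c(emph, nm[2])
      next
    }
    em <- regmatches(ln, regexec(edge_re, ln))[[1]]
    if (length(em) > 0) {
      ef <- c(ef, em[2]); et <- c(et, em[3]); ec <- c(ec, em[4])
      el <- c(el, em[5]); ew <- c(ew, as.numeric(em[6]))
    }
  }
  list(nodes = nodes, emphasis = emph,
       edges = data.frame(from = ef, to = et, colour = ec, line = el,
                          width = ew, stringsAsFactors = FALSE))
}
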