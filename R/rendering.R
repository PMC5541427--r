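## Rendering: deterministic color mapping and SVG emission for pathway
## views (single-sample, multi-sample, group-wise), the gene grid,
## bar plots / histograms, playback frame sequences, and the text summary
## report. SVG is emitted as plain text with fixed number formatting so a
## fixed plan always yields identical bytes.

#' Color specification for overlays
#'
#' Methylation betas map on a piecewise-linear gradient low -> mid -> high
#' (default dark blue at 0, white at 0.5, dark red at 1). Expression folds
#' map under -> mid -> over; note the deliberate inversion relative to
#' expression-centric conventions — over-expression is blue, matching low
#' methylation, so inverse methylation/expression patterns share a color.
#' Status colors: genes with no matching data are light green, genes whose
#' sites all fail the filter are gray; genes averaged over multiple sites
#' get a green border.
#'
#' @param meth_low,meth_mid,meth_high Methylation gradient endpoints (hex).
#' @param expr_under,expr_mid,expr_over Expression gradient endpoints (hex).
#' @param no_data,no_passing_sites Status fills (hex).
#' @param multi_site_border Border color for multi-site genes (hex).
#' @return A list of class `color_spec`.
#' @export
color_spec <- function(meth_low = "#00008B", meth_mid = "#FFFFFF",
                       meth_high = "#8B0000",
                       expr_under = "#8B0000", expr_mid = "#FFFFFF",
                       expr_over = "#00008B",
                       no_data = "#CCFFCC", no_passing_sites = "#BEBEBE",
                       multi_site_border = "#008000") {
  structure(list(meth_low = meth_low, meth_mid = meth_mid,
                 meth_high = meth_high, expr_under = expr_under,
                 expr_mid = expr_mid, expr_over = expr_over,
                 no_data = no_data, no_passing_sites = no_passing_sites,
                 multi_site_border = multi_site_border),
            class = "color_spec")
}

hex_to_rgb <- function(hex) as.integer(grDevices::col2rgb(hex)[, 1])
rgb_to_hex <- function(ch) sprintf("#%02X%02X%02X", ch[1], ch[2], ch[3])

## Linear interpolation in 8-bit RGB between two hex colors; t in [0,1].
interp_color <- function(from, to, t) {
  a <- hex_to_rgb(from); b <- hex_to_rgb(to)
  rgb_to_hex(as.integer(round(a + (b - a) * t)))
}

#' Map a beta value to its gradient color
#'
#' Piecewise-linear: low -> mid on `[0, 0.5]`, mid -> high on `[0.5, 1]`.
#' Hits the configured endpoint colors exactly at 0, 0.5 and 1.
#'
#' @param beta Beta value(s) in `[0,1]`.
#' @param spec A [color_spec()].
#' @return Hex color string(s).
#' @export
beta_to_color <- function(beta, spec = color_spec()) {
  if (anyNA(beta) || any(beta < 0 | beta > 1)) {
    stop("beta value out of range [0,1]")
  }
  vapply(beta, function(b) {
    if (b <= 0.5) interp_color(spec$meth_low, spec$meth_mid, b / 0.5)
    else interp_color(spec$meth_mid, spec$meth_high, (b - 0.5) / 0.5)
  }, character(1))
}

#' Map a clipped log2-fold value to its gradient color
#'
#' Piecewise-linear: under -> mid on `[-scale, 0]`, mid -> over on
#' `[0, +scale]`; +scale is the over-expression endpoint (blue by default),
#' -scale the under-expression endpoint (red).
#'
#' @param fold Fold value(s) with `|fold| <= scale` (callers clip first).
#' @param scale Display scale `s`, default 4.
#' @param spec A [color_spec()].
#' @return Hex color string(s).
#' @export
fold_to_color <- function(fold, scale = 4, spec = color_spec()) {
  if (anyNA(fold) || any(abs(fold) > scale)) {
    stop("fold value out of range [-scale, scale]")
  }
  vapply(fold, function(f) {
    if (f <= 0) interp_color(spec$expr_under, spec$expr_mid, (f + scale) / scale)
    else interp_color(spec$expr_mid, spec$expr_over, f / scale)
  }, character(1))
}

## Fixed-format number for SVG attributes: deterministic bytes.
svg_num <- function(x) {
  s <- formatC(x, format = "f", digits = 2)
  s <- sub("\\.?0+$", "", s)
  ifelse(s == "-0", "0", s)
}

svg_rect <- function(x, y, w, h, fill, stroke = "#000000",
                     stroke_width = 1, dash = NULL) {
  d <- if (is.null(dash)) "" else paste0(' stroke-dasharray="', dash, '"')
  paste0('<rect x="', svg_num(x), '" y="', svg_num(y), '" width="',
         svg_num(w), '" height="', svg_num(h), '" fill="', fill,
         '" stroke="', stroke, '" stroke-width="', svg_num(stroke_width),
         '"', d, '/>')
}

svg_line <- function(x1, y1, x2, y2, stroke, width = 1, dash = NULL,
                     marker = NULL) {
  d <- if (is.null(dash)) "" else paste0(' stroke-dasharray="', dash, '"')
  mk <- if (is.null(marker)) "" else paste0(' marker-end="url(#', marker, ')"')
  paste0('<line x1="', svg_num(x1), '" y1="', svg_num(y1), '" x2="',
         svg_num(x2), '" y2="', svg_num(y2), '" stroke="', stroke,
         '" stroke-width="', svg_num(width), '"', d, mk, '/>')
}

svg_text <- function(x, y, text, size = 10, anchor = "middle",
                     fill = "#000000") {
  paste0('<text x="', svg_num(x), '" y="', svg_num(y), '" font-size="',
         svg_num(size), '" font-family="Helvetica" text-anchor="', anchor,
         '" fill="', fill, '">', xml_escape(text), '</text>')
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

svg_document <- function(width, height, body) {
  paste(c(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="',
                 svg_num(width), '" height="', svg_num(height),
                 '" viewBox="0 0 ', svg_num(width), ' ', svg_num(height),
                 '">'),
          body, "</svg>"), collapse = "\n")
}

## Stroke style per relation subtype: color, dash pattern, end marker.
EDGE_STYLES <- list(
  activation      = list(color = "#000000", dash = NULL,    marker = "arrow"),
  expression      = list(color = "#000000", dash = "6,3",   marker = "arrow"),
  inhibition      = list(color = "#CC0000", dash = NULL,    marker = "tee"),
  repression      = list(color = "#CC0000", dash = "6,3",   marker = "tee"),
  methylation     = list(color = "#7B1FA2", dash = "2,4",   marker = NULL),
  phosphorylation = list(color = "#555555", dash = "1,3",   marker = NULL),
  binding         = list(color = "#777777", dash = NULL,    marker = NULL),
  indirect        = list(color = "#777777", dash = "8,4",   marker = "arrow"),
  unknown         = list(color = "#999999", dash = "1,2",   marker = NULL)
)

svg_markers <- paste(
  '<defs>',
  '<marker id="arrow" markerWidth="8" markerHeight="8" refX="7" refY="3"',
  ' orient="auto"><path d="M0,0 L7,3 L0,6 z" fill="context-stroke"/></marker>',
  '<marker id="tee" markerWidth="6" markerHeight="8" refX="2" refY="4"',
  ' orient="auto"><rect x="1" y="0" width="2" height="8"',
  ' fill="context-stroke"/></marker>',
  '</defs>', sep = "\n")

## Fill color for one display value under the overlay's value kind.
value_fill <- function(value, kind, colors, fold_scale) {
  if (is.na(value)) return(colors$no_passing_sites)
  if (kind == "methylation") beta_to_color(value, colors)
  else fold_to_color(value, fold_scale, colors)
}

## Draw one gene's display box(es): fills whole-status genes with the
## status color, otherwise one sub-box per display value.
gene_box_svg <- function(x, y, w, h, values, status, multi_site, kind,
                         colors, fold_scale) {
  stroke <- if (multi_site) colors$multi_site_border else "#000000"
  sw <- if (multi_site) 2 else 1
  if (status == "no_data") {
    return(svg_rect(x, y, w, h, colors$no_data, stroke, sw))
  }
  if (status == "no_passing_sites") {
    return(svg_rect(x, y, w, h, colors$no_passing_sites, stroke, sw))
  }
  n <- length(values)
  parts <- character(n + 1L)
  bw <- w / n
  for (j in seq_len(n)) {
    fill <- value_fill(values[j], kind, colors, fold_scale)
    parts[j] <- svg_rect(x + (j - 1) * bw, y, bw, h, fill,
                         stroke = "#666666", stroke_width = 0.5)
  }
  parts[n + 1L] <- svg_rect(x, y, w, h, "none", stroke, sw)
  paste(parts, collapse = "\n")
}

## Select the display values of one overlay for a view mode.
overlay_values <- function(ov, view_mode, sample = NULL, grouping = NULL) {
  switch(view_mode,
    single_sample = {
      if (is.null(sample)) stop("single_sample view requires a sample id")
      ov$per_sample_value[sample]
    },
    multi_sample = ov$per_sample_value,
    group_wise = {
      if (is.null(grouping)) stop("group_wise view requires a grouping")
      ov$per_group_value
    })
}

#' Render a pathway view as SVG
#'
#' Draws every gene entry as a rectangle at its KGML coordinates (KGML
#' x/y are box centers; converted to top-left here), colored by the overlay
#' display values: one box per sample group in group order for the
#' group-wise view, one per sample for the multi-sample view, a single box
#' for the single-sample view. Status coloring and the multi-site border
#' follow the [color_spec()]. Relation edges are drawn under the boxes with
#' per-subtype stroke styles. When both a methylation and an expression
#' overlay set are given, each gene shows a methylation box (left) and an
#' expression box (right) side by side. Output is byte-deterministic for a
#' fixed plan.
#'
#' @param graph A [pathway_graph()].
#' @param overlays A `gene_overlays` object from [build_overlays()].
#' @param view_mode `"group_wise"`, `"single_sample"` or `"multi_sample"`.
#' @param sample Sample id (single-sample view).
#' @param grouping A `sample_grouping` (group-wise view; its group sizes are
#'   annotated in the legend).
#' @param overlays2 Optional second `gene_overlays` (typically expression)
#'   drawn side by side with the first.
#' @param colors A [color_spec()].
#' @param title Optional title line; defaults to the pathway title.
#' @return A single character string holding the SVG document.
#' @export
render_pathway <- function(graph, overlays,
                           view_mode = c("group_wise", "single_sample",
                                         "multi_sample"),
                           sample = NULL, grouping = NULL, overlays2 = NULL,
                           colors = color_spec(), title = NULL) {
  view_mode <- match.arg(view_mode)
  if (view_mode == "group_wise" && is.null(grouping)) {
    stop("group_wise view requires a grouping")
  }
  kind1 <- attr(overlays, "kind")
  fs1 <- attr(overlays, "fold_scale")
  ov_by_entry <- stats::setNames(overlays,
                                 vapply(overlays, `[[`, character(1),
                                        "entry_id"))
  ov2_by_entry <- if (!is.null(overlays2)) {
    stats::setNames(overlays2, vapply(overlays2, `[[`, character(1),
                                      "entry_id"))
  }
  xs <- vapply(graph$entries, function(e) e$graphics$x + e$graphics$width / 2,
               numeric(1))
  ys <- vapply(graph$entries, function(e) e$graphics$y + e$graphics$height / 2,
               numeric(1))
  margin <- 20; header <- 34
  width <- max(c(xs, 200)) + margin
  height <- max(c(ys, 100)) + margin + header
  body <- c(svg_markers,
            svg_rect(0, 0, width, height, "#FFFFFF", stroke = "none",
                     stroke_width = 0))
  body <- c(body, svg_text(margin, 16,
                           if (is.null(title)) graph$title else title,
                           size = 13, anchor = "start"))
  legend <- if (!is.null(grouping) && view_mode == "group_wise") {
    sizes <- group_sizes(grouping)
    paste0("groups: ", paste0(names(sizes), " (", sizes, ")",
                              collapse = ", "))
  } else if (view_mode == "single_sample") {
    paste0("sample: ", sample)
  } else {
    paste0(length(graph$entries), " entries")
  }
  body <- c(body, svg_text(margin, 30, legend, size = 10, anchor = "start"))

  centers <- list()
  for (e in graph$entries) {
    centers[[e$entry_id]] <- c(e$graphics$x, e$graphics$y + header)
  }
  for (r in graph$relations) {
    sub <- if (length(r$subtypes)) r$subtypes[1] else "unknown"
    style <- EDGE_STYLES[[sub]]
    p1 <- centers[[r$source_entry]]; p2 <- centers[[r$target_entry]]
    body <- c(body, svg_line(p1[1], p1[2], p2[1], p2[2], style$color,
                             width = 1.2, dash = style$dash,
                             marker = style$marker))
  }
  for (e in graph$entries) {
    g <- e$graphics
    x <- g$x - g$width / 2; y <- g$y - g$height / 2 + header
    if (e$entry_type != "gene") {
      body <- c(body,
                svg_rect(x, y, g$width, g$height, "#FFFFFF", "#AAAAAA", 1),
                svg_text(g$x, g$y + header + 3.5, e$label, size = 8))
      next
    }
    ov <- ov_by_entry[[e$entry_id]]
    vals <- overlay_values(ov, view_mode, sample, grouping)
    if (is.null(ov2_by_entry)) {
      body <- c(body, gene_box_svg(x, y, g$width, g$height, vals,
                                   ov$status, ov$multi_site, kind1, colors,
                                   fs1))
    } else {
      ov2 <- ov2_by_entry[[e$entry_id]]
      vals2 <- overlay_values(ov2, view_mode, sample, grouping)
      half <- g$width / 2
      body <- c(body,
                gene_box_svg(x, y, half, g$height, vals, ov$status,
                             ov$multi_site, kind1, colors, fs1),
                gene_box_svg(x + half, y, half, g$height, vals2,
                             ov2$status, ov2$multi_site,
                             attr(overlays2, "kind"), colors,
                             attr(overlays2, "fold_scale")))
    }
    body <- c(body, svg_text(g$x, y - 2, e$label, size = 8))
  }
  svg_document(width, height, body)
}

#' Render a pathway-independent gene grid as SVG
#'
#' Lays the overlays out row-major in a fixed-size grid — the view for gene
#' sets that do not form a pathway, e.g. similar-pattern hits (reading order
#' preserves their rank order). Coloring, status and border rules are
#' identical to [render_pathway()].
#'
#' @param overlays A `gene_overlays` object (its element order defines the
#'   reading order).
#' @inheritParams render_pathway
#' @param ncols Number of columns; default `ceiling(sqrt(N))`.
#' @param cell_width,cell_height Cell size in pixels.
#' @return SVG document string.
#' @export
render_grid <- function(overlays,
                        view_mode = c("group_wise", "single_sample",
                                      "multi_sample"),
                        sample = NULL, grouping = NULL, ncols = NULL,
                        cell_width = 120, cell_height = 50,
                        colors = color_spec(), title = "gene grid") {
  view_mode <- match.arg(view_mode)
  n <- length(overlays)
  stopifnot(n >= 1)
  if (is.null(ncols)) ncols <- ceiling(sqrt(n))
  nrows <- ceiling(n / ncols)
  kind <- attr(overlays, "kind")
  fs <- attr(overlays, "fold_scale")
  margin <- 16; header <- 24; pad <- 14
  width <- margin * 2 + ncols * (cell_width + pad)
  height <- header + margin * 2 + nrows * (cell_height + pad)
  body <- c(svg_rect(0, 0, width, height, "#FFFFFF", stroke = "none",
                     stroke_width = 0),
            svg_text(margin, 16, title, size = 12, anchor = "start"))
  for (i in seq_len(n)) {
    row <- (i - 1) %/% ncols; col <- (i - 1) %% ncols
    x <- margin + col * (cell_width + pad)
    y <- header + margin + row * (cell_height + pad)
    ov <- overlays[[i]]
    vals <- overlay_values(ov, view_mode, sample, grouping)
    body <- c(body,
              gene_box_svg(x, y + 10, cell_width, cell_height - 10, vals,
                           ov$status, ov$multi_site, kind, colors, fs),
              svg_text(x + cell_width / 2, y + 7, ov$gene, size = 9))
  }
  svg_document(width, height, body)
}

#' Bar plot or histogram of one gene's values, as data + SVG
#'
#' The bar plot draws one bar per sample with bars grouped contiguously in
#' group order (group separators drawn between blocks); the histogram uses
#' fixed bins over `[0,1]` for beta values (default 20). The numbers behind
#' the plot are returned as a data frame so they can be exported as TSV
#' alongside the image.
#'
#' @param values Named per-sample display values (e.g.
#'   `overlay$per_sample_value`).
#' @param gene Gene symbol for the title.
#' @param grouping Optional `sample_grouping` for bar grouping.
#' @param kind `"barplot"` or `"histogram"`.
#' @param bins Histogram bin count over `[0,1]`.
#' @param colors A [color_spec()]; bars are colored by their value when the
#'   values are betas in `[0,1]`, otherwise a neutral fill.
#' @return List with `data` (data frame) and `svg` (document string).
#' @export
plot_gene <- function(values, gene, grouping = NULL,
                      kind = c("barplot", "histogram"), bins = 20,
                      colors = color_spec()) {
  kind <- match.arg(kind)
  is_beta <- all(is.na(values) | (values >= 0 & values <= 1))
  if (kind == "histogram") {
    v <- values[!is.na(values)]
    breaks <- seq(0, 1, length.out = bins + 1)
    h <- graphics::hist(pmin(pmax(v, 0), 1), breaks = breaks, plot = FALSE)
    data <- data.frame(bin_low = utils::head(breaks, -1),
                       bin_high = breaks[-1], count = h$counts)
    w <- 420; ht <- 240; x0 <- 40; y0 <- ht - 30; plot_h <- ht - 60
    maxc <- max(c(h$counts, 1))
    bw <- (w - x0 - 20) / bins
    body <- c(svg_rect(0, 0, w, ht, "#FFFFFF", "none", 0),
              svg_text(w / 2, 16, paste0(gene, " (histogram)"), size = 12))
    for (i in seq_len(bins)) {
      bh <- plot_h * h$counts[i] / maxc
      mid <- (breaks[i] + breaks[i + 1]) / 2
      fill <- if (is_beta) beta_to_color(mid, colors) else "#6688CC"
      body <- c(body, svg_rect(x0 + (i - 1) * bw, y0 - bh, bw, bh, fill,
                               "#333333", 0.5))
    }
    body <- c(body, svg_line(x0, y0, w - 20, y0, "#000000"),
              svg_text(x0, y0 + 14, "0", size = 8),
              svg_text(w - 20, y0 + 14, "1", size = 8))
    return(list(data = data, svg = svg_document(w, ht, body)))
  }
  ## barplot: order samples contiguously by group
  samples <- names(values)
  group <- rep("all", length(samples))
  if (!is.null(grouping)) {
    group <- unname(grouping$assignment[samples])
    ord <- order(match(group, grouping$group_order))
    samples <- samples[ord]; group <- group[ord]
  }
  vals <- unname(values[samples])
  data <- data.frame(sample = samples, group = group, value = vals,
                     stringsAsFactors = FALSE)
  n <- length(samples)
  w <- max(320, 24 + n * 14 + 20); ht <- 240
  x0 <- 24; y0 <- ht - 40; plot_h <- ht - 80
  vmax <- max(c(abs(vals), 1), na.rm = TRUE)
  body <- c(svg_rect(0, 0, w, ht, "#FFFFFF", "none", 0),
            svg_text(w / 2, 16, paste0(gene, " (bar plot)"), size = 12))
  for (i in seq_len(n)) {
    x <- x0 + (i - 1) * 14
    v <- vals[i]
    if (is.na(v)) next
    bh <- plot_h * abs(v) / vmax
    fill <- if (is_beta) beta_to_color(v, colors) else "#6688CC"
    body <- c(body, svg_rect(x, y0 - bh, 12, bh, fill, "#333333", 0.5))
  }
  if (!is.null(grouping) && length(unique(group)) > 1) {
    bounds <- which(diff(match(group, grouping$group_order)) != 0)
    for (b in bounds) {
      x <- x0 + b * 14 - 1
      body <- c(body, svg_line(x, 30, x, y0, "#888888", dash = "3,3"))
    }
    ## group labels centered under their block
    for (g in unique(group)) {
      idx <- which(group == g)
      xm <- x0 + (mean(idx) - 0.5) * 14
      body <- c(body, svg_text(xm, y0 + 14, g, size = 8))
    }
  }
  body <- c(body, svg_line(x0, y0, x0 + n * 14, y0, "#000000"))
  list(data = data, svg = svg_document(w, ht, body))
}

#' Render single-sample playback frames along an ordered cohort
#'
#' Writes one single-sample pathway SVG per sample of `order`, named
#' `frame_000.svg`, `frame_001.svg`, ... — the frame-export form of the
#' playback view (e.g. samples sorted by the methylation of one gene, so
#' the gene's color sweeps from blue to red across frames). When expression
#' overlays are supplied each gene shows its methylation and expression box
#' side by side.
#'
#' @param graph A [pathway_graph()].
#' @param overlays Methylation `gene_overlays`.
#' @param order Character vector of sample ids defining the frame sequence.
#' @param out_dir Output directory (created if absent).
#' @param overlays_expr Optional expression `gene_overlays`.
#' @param colors A [color_spec()].
#' @return Character vector of the frame file paths, invisibly.
#' @export
render_playback <- function(graph, overlays, order, out_dir,
                            overlays_expr = NULL, colors = color_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(order))
  for (i in seq_along(order)) {
    svg <- render_pathway(graph, overlays, view_mode = "single_sample",
                          sample = order[i], overlays2 = overlays_expr,
                          colors = colors,
                          title = paste0(graph$title, " - ", order[i]))
    paths[i] <- file.path(out_dir, sprintf("frame_%03d.svg", i - 1))
    writeLines(svg, paths[i])
  }
  invisible(paths)
}

#' Multi-file matching summary report
#'
#' After checking several metadata files against pathways, reports one block
#' per (file, pathway) pair: the file name, the pathway, and the
#' alphabetically sorted, de-duplicated list of matched gene symbols.
#'
#' @param checked List of lists with elements `file`, `pathway`, `genes`.
#' @return The report as a single character string.
#' @export
summary_report <- function(checked) {
  blocks <- vapply(checked, function(x) {
    genes <- sort(unique(toupper(x$genes)))
    paste0("file: ", x$file, "\npathway: ", x$pathway,
           "\nmatched genes (", length(genes), "): ",
           paste(genes, collapse = ", "), "\n")
  }, character(1))
  paste(blocks, collapse = "\n")
}

#' Annotation-lookup URLs for a gene symbol
#'
#' Builds the GeneCards, NCBI Pubmed and Ensembl query URLs for a gene
#' (URL construction only; nothing is opened).
#'
#' @param gene Gene symbol.
#' @return Named character vector `genecards`, `pubmed`, `ensembl`.
#' @export
gene_lookup_urls <- function(gene) {
  g <- utils::URLencode(gene, reserved = TRUE)
  c(genecards = paste0("https://www.genecards.org/cgi-bin/carddisp.pl?gene=", g),
    pubmed = paste0("https://www.ncbi.nlm.nih.gov/pubmed/?term=", g),
    ensembl = paste0("https://www.ensembl.org/Multi/Search/Results?q=", g))
}
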