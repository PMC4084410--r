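#' Visual style for module rendering
#'
#' @param palette Ordered vector of distinguishable ribbon colors; default
#'   is a qualitative Color-Brewer-derived scheme (Set2, 8 colors).
#' @param score_range Absolute differential-expression score mapped to the
#'   strongest green/red; scores beyond it are clipped.
#' @param scale Pixels per canvas unit (one grid tile = `tile` canvas
#'   units).
#' @param ribbon_width,halo_width,dash_pattern,font_size,radius_max
#'   Stroke/glyph metrics in pixels.
#' @param overview_width Width in pixels of the set-overview pane on the
#'   left of the network pane.
#' @return An object of class `render_style`.
#' @export
default_style <- function(palette = RColorBrewer::brewer.pal(8, "Set2"),
                          score_range = 2, scale = 28,
                          ribbon_width = 1, halo_width = 5,
                          dash_pattern = "4,3", font_size = 11,
                          radius_max = 9, overview_width = 230) {
  stopifnot(length(palette) >= 2)
  structure(list(palette = palette, score_range = score_range, scale = scale,
                 ribbon_width = ribbon_width, halo_width = halo_width,
                 dash_pattern = dash_pattern, font_size = font_size,
                 radius_max = radius_max, overview_width = overview_width,
                 ink = "#404040"),  # dark gray, not black
            class = "render_style")
}

#' Cyclic color assignment for active sets
#'
#' Colors are taken from the palette in selection order, cycling when there
#' are more sets than colors, so consecutive selections never share a color
#' and the first `length(palette)` sets are all distinct.
#'
#' @param active_sets Character vector of active set ids in selection order.
#' @param style [default_style()].
#' @return Named character vector, set id -> color.
#' @export
assign_colors <- function(active_sets, style = default_style()) {
  n <- length(active_sets)
  if (n == 0L) return(stats::setNames(character(), character()))
  pal <- style$palette
  stats::setNames(pal[(seq_len(n) - 1L) %% length(pal) + 1L], active_sets)
}

#' Significance glyph for an enrichment p-value
#'
#' The p-value is shown as a circle scaled logarithmically — radius
#' proportional to -log10(p), clipped at `radius_max` (reached at
#' p = 1e-10) — and annotated with the base-10 exponent of its scientific
#' notation.
#'
#' @param p_value Enrichment p-value in (0, 1].
#' @param style [default_style()].
#' @return List with `radius` (pixels) and `exponent_text` (e.g. `"-6"` for
#'   5.6e-6).
#' @export
significance_glyph <- function(p_value, style = default_style()) {
  if (!is.numeric(p_value) || length(p_value) != 1L || is.na(p_value) ||
      p_value <= 0) {
    stop("p-value must be a number in (0, 1]", call. = FALSE)
  }
  lg <- -log10(p_value)
  radius <- style$radius_max * min(1, max(0, lg) / 10)
  expo <- if (p_value >= 1) 0L else as.integer(floor(log10(p_value) + 1e-12))
  list(radius = radius, exponent_text = as.character(expo))
}

# fixed 3-decimal formatting, no negative zero: renders are byte-stable
fmt <- function(v) {
  v <- round(v, 3) + 0
  formatC(v, format = "f", digits = 3)
}

score_color <- function(score, style) {
  if (is.na(score)) return("#b0b0b0")
  s <- max(-1, min(1, score / style$score_range))
  ramp <- grDevices::colorRamp(c("#1a9850", "#f5f5f5", "#d73027"))
  grDevices::rgb(ramp((s + 1) / 2), maxColorValue = 255)
}

#' Quadratic link curve between two placed nodes
#'
#' The curve runs between the endpoint cell centers with its control point
#' offset perpendicular to the segment at 10% of its length; the side is
#' chosen by lexicographic endpoint-id order, so swapping the endpoints
#' yields identical geometry. The halo is the same path, stroked wider
#' underneath in the background color.
#'
#' @param layout A `module_layout`.
#' @param interaction List or row with node ids `a`, `b`.
#' @param style [default_style()].
#' @return List with `d` (SVG path data), `halo_width` and `width`.
#' @export
edge_path <- function(layout, interaction, style = default_style()) {
  a <- as.character(interaction$a)
  b <- as.character(interaction$b)
  if (a > b) { tmp <- a; a <- b; b <- tmp }  # canonical undirected order
  ia <- match(a, layout$id)
  ib <- match(b, layout$id)
  if (is.na(ia) || is.na(ib)) {
    stop("interaction endpoint not placed: ", if (is.na(ia)) a else b,
         call. = FALSE)
  }
  tile <- attr(layout, "tile")
  s <- style$scale
  p1 <- c(layout$x[ia] + 0.5, layout$y[ia] + 0.5) * tile * s
  p2 <- c(layout$x[ib] + 0.5, layout$y[ib] + 0.5) * tile * s
  mid <- (p1 + p2) / 2
  d <- p2 - p1
  len <- sqrt(sum(d^2))
  ctrl <- if (len > 0) mid + 0.1 * c(-d[2], d[1]) else mid
  list(d = paste0("M", fmt(p1[1]), ",", fmt(p1[2]),
                  " Q", fmt(ctrl[1]), ",", fmt(ctrl[2]),
                  " ", fmt(p2[1]), ",", fmt(p2[2])),
       halo_width = style$halo_width, width = 1.5)
}

ps_path_data <- function(ps, ox, oy, s) {
  paste(vapply(ps, function(r) {
    paste0("M", paste(paste0(fmt(r$x * s + ox), ",", fmt(r$y * s + oy)),
                      collapse = " L"), " Z")
  }, ""), collapse = " ")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render an annotated module as a static SVG document
#'
#' Emits a two-pane figure: a set overview on the left (sets grouped by
#' category, sorted by ascending p-value, each with its significance glyph)
#' and the network visualization on the right. Painting order in the
#' network pane is: opaque set ribbons (largest set first), link halos,
#' link curves, dashed contour outlines (so occluded sections can be
#' inferred), then node labels on white background boxes whose border color
#' encodes the differential-expression score (green under, red over). The
#' output is a pure function of its inputs: no timestamps, coordinates at
#' fixed precision, byte-identical across repeated calls.
#'
#' @param module The `annotated_module`.
#' @param layout Its `module_layout`.
#' @param contours List of `set_contour` from [set_contours()] (may be
#'   empty).
#' @param style [default_style()].
#' @param file Optional path; when given the document is also written there.
#' @return The SVG document as a single character string (invisibly when
#'   `file` is given).
#' @export
render_svg <- function(module, layout, contours, style = default_style(),
                       file = NULL) {
  stopifnot(inherits(module, "annotated_module"))
  s <- style$scale
  tile <- attr(layout, "tile")
  N <- attr(layout, "side")
  ox <- style$overview_width + 20
  oy <- 20
  net_w <- N * tile * s
  colors <- assign_colors(module$active, style)

  # ---- set overview pane (left) ----------------------------------------
  ov <- character()
  yy <- 30
  cats <- unique(vapply(module$sets, `[[`, "", "category"))
  for (cat in cats) {
    in_cat <- Filter(function(x) x$category == cat, module$sets)
    ord <- order(vapply(in_cat, `[[`, 0, "p_value"),
                 vapply(in_cat, `[[`, "", "id"))
    in_cat <- in_cat[ord]
    ov <- c(ov, sprintf(
      '<text x="10" y="%s" font-size="%s" font-weight="bold" fill="%s">%s</text>',
      fmt(yy), fmt(style$font_size + 1), style$ink, xml_escape(cat)))
    yy <- yy + 18
    for (st in in_cat) {
      g <- significance_glyph(st$p_value, style)
      active <- st$id %in% module$active
      col <- if (active) colors[[st$id]] else "#ffffff"
      ov <- c(ov, sprintf(
        '<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="%s" stroke-width="1"/>',
        fmt(20), fmt(yy - 4), fmt(max(g$radius, 1)), col, style$ink))
      ov <- c(ov, sprintf(
        '<text x="34" y="%s" font-size="%s" fill="%s">%s</text>',
        fmt(yy), fmt(style$font_size - 2), style$ink, g$exponent_text))
      ov <- c(ov, sprintf(
        '<text x="52" y="%s" font-size="%s"%s fill="%s">%s</text>',
        fmt(yy), fmt(style$font_size),
        if (active) ' font-weight="bold"' else "", style$ink,
        xml_escape(st$label)))
      yy <- yy + 16
    }
    yy <- yy + 8
  }

  # ---- network pane ----------------------------------------------------
  net <- character()
  for (ct in contours) {  # already in z order, largest first
    if (!ps_is_empty(ct$ribbon)) {
      net <- c(net, sprintf(
        '<path class="ribbon" fill-rule="evenodd" d="%s" fill="%s" stroke="none"/>',
        ps_path_data(ct$ribbon, ox, oy, s), colors[[ct$set_id]]))
    }
  }
  edge_specs <- lapply(seq_len(nrow(module$interactions)), function(i) {
    edge_path(layout, module$interactions[i, ], style)
  })
  for (ep in edge_specs) {
    net <- c(net, sprintf(
      '<path class="halo" d="%s" fill="none" stroke="#ffffff" stroke-width="%s" stroke-linecap="round"/>',
      ep$d, fmt(ep$halo_width)))
  }
  for (ep in edge_specs) {
    net <- c(net, sprintf(
      '<path class="link" d="%s" fill="none" stroke="%s" stroke-width="%s" stroke-linecap="round"/>',
      ep$d, style$ink, fmt(ep$width)))
  }
  for (ct in contours) {
    if (!ps_is_empty(ct$body)) {
      net <- c(net, sprintf(
        '<path class="outline" fill-rule="evenodd" d="%s" fill="none" stroke="%s" stroke-width="1" stroke-dasharray="%s"/>',
        ps_path_data(ct$body, ox, oy, s), colors[[ct$set_id]],
        style$dash_pattern))
    }
  }
  for (i in seq_len(nrow(module$nodes))) {
    id <- module$nodes$id[i]
    k <- match(id, layout$id)
    cx <- (layout$x[k] + 0.5) * tile * s + ox
    cy <- (layout$y[k] + 0.5) * tile * s + oy
    label <- module$nodes$label[i]
    bw <- 0.62 * style$font_size * nchar(label) + 8
    bh <- style$font_size + 6
    net <- c(net, sprintf(
      '<rect class="labelbox" x="%s" y="%s" width="%s" height="%s" rx="3" fill="#ffffff" stroke="%s" stroke-width="2"/>',
      fmt(cx - bw / 2), fmt(cy - bh / 2), fmt(bw), fmt(bh),
      score_color(module$nodes$score[i], style)))
    net <- c(net, sprintf(
      '<text class="label" x="%s" y="%s" text-anchor="middle" font-size="%s" fill="%s">%s</text>',
      fmt(cx), fmt(cy + 0.35 * style$font_size), fmt(style$font_size),
      style$ink, xml_escape(label)))
  }

  width <- ox + net_w + 20
  height <- max(yy + 20, oy + N * tile * s + 20)
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%s" ',
                   'height="%s" viewBox="0 0 %s %s" ',
                   'font-family="Helvetica, Arial, sans-serif">\n'),
            fmt(width), fmt(height), fmt(width), fmt(height)),
    '<rect x="0" y="0" width="100%" height="100%" fill="#ffffff"/>\n',
    paste(ov, collapse = "\n"), "\n",
    paste(net, collapse = "\n"), "\n",
    "</svg>\n"
  )
  if (!is.null(file)) {
    con <- file(file, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(doc), con)
    return(invisible(doc))
  }
  doc
}
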