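#' Rendering configuration
#'
#' Controls the drawing vocabulary of [render_svg()]: canvas padding, node
#' sizes, background, and which node attributes make up the labels. The shape
#' vocabulary is fixed — reactions are squares, regular metabolites circles,
#' currency metabolites small grey circles — and edges are straight lines
#' between node centres.
#'
#' @param padding Canvas padding in canvas units.
#' @param reaction_size Side of the reaction square.
#' @param metabolite_radius,currency_radius Circle radii.
#' @param reaction_label_attrs,metabolite_label_attrs Character vectors over
#'   `"label"`, `"id"`, `"model_ids"`: which attributes to concatenate into
#'   the node label, in order.
#' @param background Background colour (`NA` for none).
#' @return A `render_config` list.
#' @export
render_config <- function(padding = 40, reaction_size = 14,
                          metabolite_radius = 9, currency_radius = 5,
                          reaction_label_attrs = "label",
                          metabolite_label_attrs = "label",
                          background = "#FFFFFF") {
  structure(
    list(padding = padding, reaction_size = reaction_size,
         metabolite_radius = metabolite_radius, currency_radius = currency_radius,
         reaction_label_attrs = reaction_label_attrs,
         metabolite_label_attrs = metabolite_label_attrs,
         background = background),
    class = "render_config"
  )
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

compose_label <- function(row, attrs) {
  parts <- map_chr(attrs, function(a) {
    switch(a,
           label = row$label,
           id = row$id,
           model_ids = paste(row$model_ids[[1]], collapse = ","),
           "")
  })
  paste(parts[nzchar(parts)], collapse = " | ")
}

#' Render a layout (plus optional overlay) to SVG
#'
#' Produces a static SVG 1.1 document: one shape per visible node, one
#' straight path per visible edge. Arrowhead markers encode reversibility —
#' an irreversible reaction's arrows point only at its products, a
#' reversible reaction's at both metabolite ends. An overlay contributes
#' edge widths and colours, arrowhead colours, glyphs (knockout cross,
#' up/down expression arrows drawn beside the reaction node) and label
#' suffixes. Filters named in `active_filters` (resolved against the
#' overlay's filters, or given directly as `visibility_filter` objects) hide
#' their nodes together with incident edges and attached info annotations;
#' a hidden node's id does not occur anywhere in the output. Element order
#' is sorted by node id so output is reproducible byte for byte.
#'
#' All visible nodes must be positioned — run [run_fdl()] first if needed.
#'
#' @param layout A `metabolic_layout`.
#' @param overlay Optional `fluxmapr_overlay`.
#' @param active_filters Filter names (matched against `overlay$filters`) or
#'   `visibility_filter` objects.
#' @param config A [render_config()].
#' @param style A [style_config()].
#' @return SVG document text (single string).
#' @export
render_svg <- function(layout, overlay = NULL, active_filters = NULL,
                       config = render_config(), style = style_config()) {
  filters <- list()
  for (f in (active_filters %||% list())) {
    if (inherits(f, "visibility_filter")) {
      filters[[length(filters) + 1]] <- f
    } else if (is.character(f) && !is.null(overlay)) {
      hit <- purrr::keep(overlay$filters, ~ .x$name == f)
      if (!length(hit)) stop_not_found(f, "filter")
      filters <- c(filters, hit)
    } else {
      stop_argument("active_filters must be filter names or visibility_filter objects")
    }
  }
  vis <- visible_subgraph(layout, filters)
  mets <- arrange(vis$metabolites, .data$id)
  rxns <- arrange(vis$reactions, .data$id)
  edges <- arrange(vis$edges, .data$reaction_id, .data$metabolite_id, .data$role)
  infos <- arrange(vis$info_nodes, .data$id)

  for (tab in list(mets, rxns)) {
    bad <- tab$id[is.na(tab$x) | is.na(tab$y)]
    if (length(bad)) {
      stop_fluxmapr(sprintf("cannot render: node '%s' has no position (run run_fdl first)", bad[1]),
                    "render")
    }
  }

  xs <- c(mets$x, rxns$x); ys <- c(mets$y, rxns$y)
  if (!length(xs)) { xs <- 0; ys <- 0 }
  x0 <- min(xs) - config$padding; x1 <- max(xs) + config$padding
  y0 <- min(ys) - config$padding; y1 <- max(ys) + config$padding

  pos <- rbind(
    if (nrow(rxns)) data.frame(id = rxns$id, x = rxns$x, y = rxns$y),
    if (nrow(mets)) data.frame(id = mets$id, x = mets$x, y = mets$y)
  )
  getpos <- function(id) pos[pos$id == id, c("x", "y")]

  estyle <- function(rid, mid, role) {
    out <- list(width = style$min_width, color = style$default_edge_color,
                marker_color = NA_character_)
    if (!is.null(overlay) && nrow(overlay$edge_style)) {
      es <- overlay$edge_style
      i <- which(es$reaction_id == rid & es$metabolite_id == mid & es$role == role)
      if (length(i)) {
        i <- i[1]
        if (!is.na(es$width[i])) out$width <- es$width[i]
        if (!is.na(es$color[i])) out$color <- es$color[i]
        out$marker_color <- es$marker_color[i]
      }
    }
    out
  }

  body <- character()
  marker_colors <- character()
  rev_lookup <- stats::setNames(rxns$reversible, rxns$id)
  for (i in seq_len(nrow(edges))) {
    rid <- edges$reaction_id[i]; mid <- edges$metabolite_id[i]; role <- edges$role[i]
    p1 <- getpos(rid); p2 <- getpos(mid)
    es <- estyle(rid, mid, role)
    arrowed <- role == "product" || isTRUE(rev_lookup[[rid]])
    mcol <- if (!is.na(es$marker_color)) es$marker_color else es$color
    marker <- ""
    if (arrowed) {
      key <- gsub("#", "", tolower(mcol))
      marker_colors[key] <- mcol
      marker <- sprintf(' marker-end="url(#arrow-%s)"', key)
    }
    body <- c(body, sprintf(
      '<line class="edge" x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="%s" stroke-width="%.3f"%s/>',
      p1$x, p1$y, p2$x, p2$y, es$color, es$width, marker))
  }

  suffix_of <- function(id) {
    if (is.null(overlay) || !nrow(overlay$label_suffix)) return(NULL)
    s <- overlay$label_suffix$suffix[overlay$label_suffix$reaction_id == id]
    if (length(s)) s[1] else NULL
  }
  glyph_of <- function(id) {
    if (is.null(overlay) || !nrow(overlay$node_glyph)) return(NULL)
    g <- overlay$node_glyph[overlay$node_glyph$reaction_id == id, ]
    if (nrow(g)) g[1, ] else NULL
  }

  for (i in seq_len(nrow(mets))) {
    r <- if (mets$kind[i] == "currency") config$currency_radius else config$metabolite_radius
    fill <- if (mets$kind[i] == "currency") style$currency_fill else style$metabolite_fill
    lbl <- compose_label(mets[i, ], config$metabolite_label_attrs)
    body <- c(body,
      sprintf('<circle class="metabolite" id="%s" cx="%.2f" cy="%.2f" r="%.1f" fill="%s" stroke="#333333"/>',
              xml_escape(mets$id[i]), mets$x[i], mets$y[i], r, fill),
      sprintf('<text x="%.2f" y="%.2f" font-family="%s" font-size="%.1f" text-anchor="middle">%s</text>',
              mets$x[i], mets$y[i] + r + 11, style$font_family, style$font_size * 0.9,
              xml_escape(lbl)))
  }
  half <- config$reaction_size / 2
  for (i in seq_len(nrow(rxns))) {
    id <- rxns$id[i]; x <- rxns$x[i]; y <- rxns$y[i]
    lbl <- compose_label(rxns[i, ], config$reaction_label_attrs)
    sfx <- suffix_of(id)
    if (!is.null(sfx)) lbl <- paste(lbl, sfx)
    body <- c(body,
      sprintf('<rect class="reaction" id="%s" x="%.2f" y="%.2f" width="%.1f" height="%.1f" fill="%s" stroke="#333333"/>',
              xml_escape(id), x - half, y - half, config$reaction_size,
              config$reaction_size, style$reaction_fill),
      sprintf('<text x="%.2f" y="%.2f" font-family="%s" font-size="%.1f" text-anchor="middle">%s</text>',
              x, y + half + 12, style$font_family, style$font_size, xml_escape(lbl)))
    g <- glyph_of(id)
    if (!is.null(g)) {
      if (g$glyph == "knockout_cross") {
        s <- config$reaction_size * 0.9
        body <- c(body, sprintf(
          '<g class="glyph knockout_cross" stroke="%s" stroke-width="3"><line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f"/><line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f"/></g>',
          g$color, x - s, y - s, x + s, y + s, x - s, y + s, x + s, y - s))
      } else if (g$glyph == "up_arrow") {
        body <- c(body, sprintf(
          '<polygon class="glyph up_arrow" points="%.2f,%.2f %.2f,%.2f %.2f,%.2f" fill="%s"/>',
          x - 5, y - half - 3, x + 5, y - half - 3, x, y - half - 13, g$color))
      } else if (g$glyph == "down_arrow") {
        body <- c(body, sprintf(
          '<polygon class="glyph down_arrow" points="%.2f,%.2f %.2f,%.2f %.2f,%.2f" fill="%s"/>',
          x - 5, y - half - 13, x + 5, y - half - 13, x, y - half - 3, g$color))
      }
    }
  }
  for (i in seq_len(nrow(infos))) {
    rp <- getpos(infos$reaction_id[i])
    body <- c(body, sprintf(
      '<text class="info" id="%s" x="%.2f" y="%.2f" font-family="%s" font-size="%.1f" fill="#666666">%s</text>',
      xml_escape(infos$id[i]), rp$x + half + 4, rp$y - half - 4,
      style$font_family, style$font_size * 0.8, xml_escape(infos$text[i])))
  }

  defs <- map_chr(names(marker_colors), function(key) {
    sprintf(paste0(
      '<marker id="arrow-%s" class="arrowhead" viewBox="0 0 10 10" refX="9" refY="5" ',
      'markerWidth="7" markerHeight="7" orient="auto-start-reverse">',
      '<path d="M 0 0 L 10 5 L 0 10 z" fill="%s"/></marker>'),
      key, marker_colors[[key]])
  })

  bg <- if (!is.na(config$background)) {
    sprintf('<rect x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="%s"/>',
            x0, y0, x1 - x0, y1 - y0, config$background)
  } else character()

  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" viewBox="%.2f %.2f %.2f %.2f" width="%.0f" height="%.0f">\n',
            x0, y0, x1 - x0, y1 - y0, x1 - x0, y1 - y0),
    '<defs>', paste(defs, collapse = ""), '</defs>\n',
    paste(c(bg, body), collapse = "\n"),
    '\n</svg>\n'
  )
}

# Which external SVG->PDF converter, if any, is usable.
pdf_converter <- function() {
  if (requireNamespace("rsvg", quietly = TRUE)) return("rsvg")
  for (tool in c("rsvg-convert", "cairosvg", "inkscape")) {
    if (nzchar(Sys.which(tool))) return(tool)
  }
  NA_character_
}

#' Convert rendered SVG to PDF
#'
#' PDF export is delegated to an SVG converter (the rsvg package or an
#' rsvg-convert / cairosvg / inkscape executable). When none is present the
#' function raises a classed `fluxmapr_unsupported_error`; SVG output itself
#' never depends on a converter.
#'
#' @param svg SVG document text (validated as XML before conversion).
#' @param path Optional output file path.
#' @return PDF bytes (raw vector), invisibly if `path` is given.
#' @export
svg_to_pdf <- function(svg, path = NULL) {
  tryCatch(read_xml(svg), error = function(e) {
    stop_parse(sprintf("input is not valid SVG/XML: %s", conditionMessage(e)))
  })
  conv <- pdf_converter()
  if (is.na(conv)) {
    stop_unsupported("no SVG-to-PDF converter available (install rsvg, rsvg-convert, cairosvg or inkscape)")
  }
  out <- path %||% tempfile(fileext = ".pdf")
  if (conv == "rsvg") {
    rsvg::rsvg_pdf(charToRaw(svg), file = out)
  } else {
    tmp <- tempfile(fileext = ".svg")
    writeLines(svg, tmp)
    args <- switch(conv,
                   "rsvg-convert" = c("-f", "pdf", "-o", out, tmp),
                   "cairosvg" = c(tmp, "-o", out),
                   "inkscape" = c(tmp, "--export-type=pdf", paste0("--export-filename=", out)))
    status <- system2(conv, args, stdout = FALSE, stderr = FALSE)
    unlink(tmp)
    if (!identical(status, 0L)) stop_fluxmapr("SVG to PDF conversion failed", "conversion")
  }
  bytes <- readBin(out, "raw", n = file.info(out)$size)
  if (is.null(path)) unlink(out) else return(invisible(bytes))
  bytes
}
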