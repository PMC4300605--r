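#' Visual style configuration
#'
#' Collects the tunable visual parameters shared by the overlay builders and
#' the SVG renderer: the edge-width range that flux magnitudes are normalized
#' into, the colours of the genetic-condition glyphs, the two simulation
#' colours of the comparison gradient, and label formatting.
#'
#' @param min_width,max_width Edge width range in canvas units
#'   (`min_width < max_width`).
#' @param knockout_color Colour of the knockout cross and its edges.
#' @param over_color Colour for over-expressed reactions (up arrow).
#' @param under_color Colour for under-expressed reactions (down arrow).
#' @param sim1_color,sim2_color Endpoint colours of the comparison gradient.
#' @param neutral_color Gradient midpoint (equal fluxes).
#' @param default_edge_color Edge colour when no overlay applies.
#' @param flux_label_decimals Decimals in flux label suffixes.
#' @param reaction_fill,metabolite_fill,currency_fill Node fill colours.
#' @param font_family,font_size Label font.
#' @return A `style_config` list.
#' @export
style_config <- function(min_width = 1, max_width = 8,
                         knockout_color = "#CC0000", over_color = "#00AA00",
                         under_color = "#E69500",
                         sim1_color = "#CC0000", sim2_color = "#00AA00",
                         neutral_color = "#000000",
                         default_edge_color = "#555555",
                         flux_label_decimals = 3,
                         reaction_fill = "#D9D9D9", metabolite_fill = "#FFFFFF",
                         currency_fill = "#BBBBBB",
                         font_family = "sans-serif", font_size = 11) {
  if (!(min_width < max_width)) stop_argument("min_width must be < max_width")
  structure(
    list(min_width = min_width, max_width = max_width,
         knockout_color = knockout_color, over_color = over_color,
         under_color = under_color, sim1_color = sim1_color,
         sim2_color = sim2_color, neutral_color = neutral_color,
         default_edge_color = default_edge_color,
         flux_label_decimals = as.integer(flux_label_decimals),
         reaction_fill = reaction_fill, metabolite_fill = metabolite_fill,
         currency_fill = currency_fill,
         font_family = font_family, font_size = font_size),
    class = "style_config"
  )
}

#' Genetic conditions of a simulated mutant
#'
#' The genetic changes imposed in a phenotype simulation: reaction knockouts
#' (flux forced to zero) plus over- and under-expressed reactions. The three
#' sets must be pairwise disjoint.
#'
#' @param knockouts,over_expressed,under_expressed Character vectors of model
#'   reaction ids.
#' @return A `genetic_conditions` list.
#' @export
genetic_conditions <- function(knockouts = character(), over_expressed = character(),
                               under_expressed = character()) {
  k <- unique(as.character(knockouts))
  o <- unique(as.character(over_expressed))
  u <- unique(as.character(under_expressed))
  if (length(intersect(k, o)) || length(intersect(k, u)) || length(intersect(o, u))) {
    stop_argument("knockout / over-expressed / under-expressed sets must be pairwise disjoint")
  }
  structure(list(knockouts = k, over_expressed = o, under_expressed = u),
            class = "genetic_conditions")
}

#' Read genetic conditions from a TSV file
#'
#' Expects `reaction_id<TAB>{KO|OVER|UNDER}` lines with `#` comments.
#'
#' @param path File path.
#' @return A `genetic_conditions`.
#' @export
read_conditions_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t| +")
  sets <- list(KO = character(), OVER = character(), UNDER = character())
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 2 || !p[2] %in% names(sets)) {
      stop_parse(sprintf("conditions file line %d is not 'reaction_id<TAB>KO|OVER|UNDER'", i))
    }
    sets[[p[2]]] <- c(sets[[p[2]]], p[1])
  }
  genetic_conditions(sets$KO, sets$OVER, sets$UNDER)
}

new_overlay <- function(edge_style = NULL, node_glyph = NULL, label_suffix = NULL,
                        filters = list(), diagnostics = character()) {
  structure(
    list(
      edge_style = edge_style %||% tibble(reaction_id = character(),
                                          metabolite_id = character(), role = character(),
                                          width = double(), color = character(),
                                          marker_color = character()),
      node_glyph = node_glyph %||% tibble(reaction_id = character(), glyph = character(),
                                          color = character()),
      label_suffix = label_suffix %||% tibble(reaction_id = character(), suffix = character()),
      filters = filters,
      diagnostics = diagnostics
    ),
    class = "fluxmapr_overlay"
  )
}

#' @export
print.fluxmapr_overlay <- function(x, ...) {
  cat(sprintf(
    "<overlay: %d styled edge(s), %d glyph(s), %d label suffix(es), %d filter(s)>\n",
    nrow(x$edge_style), nrow(x$node_glyph), nrow(x$label_suffix), length(x$filters)
  ))
  invisible(x)
}

# Widths from per-node magnitudes by linear max-normalization:
# min + (max - min) * m / M, all min when M == 0. Nodes absent from `mags`
# get the default (minimum) width.
normalized_widths <- function(layout, mags, style) {
  e <- layout$edges
  w <- rep(style$min_width, nrow(e))
  if (nrow(mags)) {
    M <- max(mags$m)
    i <- match(e$reaction_id, mags$node_id)
    hit <- !is.na(i)
    if (M > 0) {
      w[hit] <- style$min_width +
        (style$max_width - style$min_width) * mags$m[i[hit]] / M
    }
  }
  tibble(reaction_id = e$reaction_id, metabolite_id = e$metabolite_id,
         role = e$role, width = w,
         color = NA_character_, marker_color = NA_character_)
}

# Hide reactions with zero or absent flux, together with metabolite
# neighbours left without any visible reaction.
zero_flux_filter <- function(layout, node_flux, name) {
  active <- node_flux$node_id[abs(node_flux$flux) > 0]
  hidden_rx <- setdiff(layout$reactions$id, active)
  e <- layout$edges
  mets <- unique(e$metabolite_id)
  orphan <- mets[map_lgl(mets, function(m) {
    all(e$reaction_id[e$metabolite_id == m] %in% hidden_rx)
  })]
  visibility_filter(name, c(hidden_rx, orphan))
}

#' Paint a flux distribution onto a layout
#'
#' Aggregates model fluxes per reaction node ([fluxes_per_reaction_node()]),
#' normalizes the absolute values against the per-layout maximum `F`, and
#' sets the width of every edge incident to a node with aggregated flux `f`
#' to `min_width + (max_width - min_width) * |f| / F` (all widths collapse to
#' `min_width` when `F = 0`). Edges of unmapped reactions keep the default
#' width. Each mapped reaction's label gains the signed flux value, formatted
#' with `style$flux_label_decimals` decimals.
#'
#' @param layout A `metabolic_layout`.
#' @param mapping A `model_mapping` targeting `layout`.
#' @param flux A `flux_distribution`.
#' @param style A [style_config()].
#' @return A `fluxmapr_overlay`.
#' @export
flux_overlay <- function(layout, mapping, flux, style = style_config()) {
  nf <- fluxes_per_reaction_node(layout, mapping, flux)
  edge_style <- normalized_widths(
    layout, tibble(node_id = nf$node_id, m = abs(nf$flux)), style)
  suffix <- tibble(reaction_id = nf$node_id,
                   suffix = format_flux(nf$flux, style$flux_label_decimals))
  new_overlay(edge_style = edge_style, label_suffix = suffix)
}

#' Paint genetic conditions onto a layout
#'
#' Knocked-out reactions get a red cross glyph and red incident edges;
#' over-expressed reactions an upward green arrow and green edges;
#' under-expressed reactions a downward orange arrow and orange edges (all
#' colours from the style). Condition ids that map to no layout node are
#' collected in the overlay's diagnostics, never fatal.
#'
#' @param layout A `metabolic_layout`.
#' @param mapping A `model_mapping` targeting `layout`.
#' @param conditions A [genetic_conditions()].
#' @param style A [style_config()].
#' @return A `fluxmapr_overlay`.
#' @export
genetic_overlay <- function(layout, mapping, conditions, style = style_config()) {
  stopifnot(inherits(conditions, "genetic_conditions"))
  spec <- list(
    list(ids = conditions$knockouts, glyph = "knockout_cross", color = style$knockout_color),
    list(ids = conditions$over_expressed, glyph = "up_arrow", color = style$over_color),
    list(ids = conditions$under_expressed, glyph = "down_arrow", color = style$under_color)
  )
  glyphs <- list(); edge_rows <- list(); unmapped <- character()
  for (s in spec) {
    for (mid in s$ids) {
      nodes <- mapping$reaction_map$node_id[mapping$reaction_map$model_id == mid]
      nodes <- intersect(nodes, layout$reactions$id)
      if (!length(nodes)) {
        unmapped <- c(unmapped, mid)
        next
      }
      glyphs[[length(glyphs) + 1]] <- tibble(reaction_id = nodes, glyph = s$glyph,
                                             color = s$color)
      inc <- layout$edges[layout$edges$reaction_id %in% nodes, ]
      if (nrow(inc)) {
        inc$width <- NA_real_
        inc$color <- s$color
        inc$marker_color <- NA_character_
        edge_rows[[length(edge_rows) + 1]] <- inc
      }
    }
  }
  new_overlay(
    edge_style = if (length(edge_rows)) distinct(bind_rows(edge_rows)) else NULL,
    node_glyph = if (length(glyphs)) distinct(bind_rows(glyphs)) else NULL,
    diagnostics = unmapped
  )
}

#' Compare two simulations on one layout
#'
#' Per reaction node, let `a = |f_A|` and `b = |f_B|` be the absolute
#' aggregated fluxes of the two simulations (absent treated as zero) and
#' `d = |a - b| / max(a, b)` the relative difference (0 when both are zero).
#' Edge colours blend linearly from the neutral colour (black: no difference)
#' toward the colour of the simulation with the larger flux, with weight `d`;
#' both-zero edges keep the default style. Widths are computed as in
#' [flux_overlay()] from the per-node mean `(a + b) / 2`. For reversible
#' reactions whose two fluxes run in opposite directions, arrowheads are
#' coloured by the simulation flowing their way: product-end heads take the
#' forward simulation's colour, substrate-end heads the backward one's.
#' Genetic conditions of either simulation contribute their glyphs (edge
#' colours stay with the gradient). Two hide filters are generated, one per
#' simulation, hiding its zero-flux reactions.
#'
#' @param layout A `metabolic_layout`.
#' @param mapping A `model_mapping` targeting `layout`.
#' @param flux_a,flux_b The two simulations' `flux_distribution`s.
#' @param style A [style_config()]; `sim1_color` belongs to `flux_a`,
#'   `sim2_color` to `flux_b`.
#' @param conditions_a,conditions_b Optional [genetic_conditions()] for each
#'   simulation.
#' @return A `fluxmapr_overlay`.
#' @export
comparison_overlay <- function(layout, mapping, flux_a, flux_b,
                               style = style_config(),
                               conditions_a = NULL, conditions_b = NULL) {
  fa <- fluxes_per_reaction_node(layout, mapping, flux_a)
  fb <- fluxes_per_reaction_node(layout, mapping, flux_b)
  nodes <- union(fa$node_id, fb$node_id)
  sa <- fa$flux[match(nodes, fa$node_id)]; sa[is.na(sa)] <- 0
  sb <- fb$flux[match(nodes, fb$node_id)]; sb[is.na(sb)] <- 0
  a <- abs(sa); b <- abs(sb)

  edge_style <- normalized_widths(
    layout, tibble(node_id = nodes, m = (a + b) / 2), style)

  mx <- pmax(a, b)
  d <- ifelse(mx > 0, abs(a - b) / mx, 0)
  col <- rep(NA_character_, length(nodes))
  nz <- mx > 0
  toward <- ifelse(a >= b, style$sim1_color, style$sim2_color)
  col[nz] <- blend_color(style$neutral_color, toward[nz], d[nz])

  i <- match(edge_style$reaction_id, nodes)
  hit <- !is.na(i)
  edge_style$color[hit] <- col[i[hit]]

  # direction colouring on reversible reactions with opposing fluxes
  rev_ids <- layout$reactions$id[layout$reactions$reversible]
  opp <- nodes[sign(sa) * sign(sb) < 0]
  opp <- intersect(opp, rev_ids)
  if (length(opp)) {
    for (nid in opp) {
      fwd <- if (sa[nodes == nid] > 0) style$sim1_color else style$sim2_color
      bwd <- if (sa[nodes == nid] > 0) style$sim2_color else style$sim1_color
      sel_p <- edge_style$reaction_id == nid & edge_style$role == "product"
      sel_s <- edge_style$reaction_id == nid & edge_style$role == "substrate"
      edge_style$marker_color[sel_p] <- fwd
      edge_style$marker_color[sel_s] <- bwd
    }
  }

  glyphs <- NULL; diag <- character()
  for (cond in list(conditions_a, conditions_b)) {
    if (!is.null(cond)) {
      g <- genetic_overlay(layout, mapping, cond, style)
      glyphs <- bind_rows(glyphs, g$node_glyph)
      diag <- c(diag, g$diagnostics)
    }
  }

  filters <- list(
    zero_flux_filter(layout, tibble(node_id = nodes, flux = sa), "hide_zero_in_A"),
    zero_flux_filter(layout, tibble(node_id = nodes, flux = sb), "hide_zero_in_B")
  )
  new_overlay(edge_style = edge_style,
              node_glyph = if (!is.null(glyphs)) distinct(glyphs) else NULL,
              filters = filters, diagnostics = diag)
}

#' Paint an elementary flux mode onto a layout
#'
#' An EFM is supplied as a flux distribution over its member reactions.
#' Widths and label suffixes are computed exactly as in [flux_overlay()]; no
#' glyphs or recolouring. A single visibility filter is generated hiding the
#' reactions with zero or absent flux (and the metabolite neighbours those
#' hides orphan), so activating it shows the mode alone.
#'
#' @param layout A `metabolic_layout`.
#' @param mapping A `model_mapping` targeting `layout`.
#' @param efm_flux A `flux_distribution` holding the mode's flux vector.
#' @param style A [style_config()].
#' @return A `fluxmapr_overlay`.
#' @export
efm_overlay <- function(layout, mapping, efm_flux, style = style_config()) {
  ov <- flux_overlay(layout, mapping, efm_flux, style)
  nf <- fluxes_per_reaction_node(layout, mapping, efm_flux)
  ov$filters <- list(zero_flux_filter(layout, nf, "hide_zero_flux"))
  ov
}
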