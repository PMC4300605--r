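#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_segment geom_point geom_text
#'   scale_shape_manual coord_equal theme_void labs scale_size_identity
#'   scale_color_identity
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a metabolic layout into a node table
#'
#' One row per reaction/metabolite node with a `node_type` column, the
#' comma-joined model ids, position and fixed flag — convenient for dplyr
#' pipelines and plotting.
#'
#' @param x A `metabolic_layout`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy metabolic_layout
#' @export
tidy.metabolic_layout <- function(x, ...) {
  bind_rows(
    mutate(select(x$reactions, "id", "label", "model_ids", "x", "y", "fixed"),
           node_type = "reaction", kind = NA_character_,
           reversible = x$reactions$reversible),
    mutate(select(x$metabolites, "id", "label", "model_ids", "kind", "x", "y", "fixed"),
           node_type = "metabolite", reversible = NA)
  ) |>
    mutate(model_ids = map_chr(.data$model_ids, paste, collapse = ",")) |>
    select("id", "node_type", "kind", "label", "model_ids", "reversible",
           "x", "y", "fixed")
}

#' One-row summary of a layout
#'
#' @param x A `metabolic_layout`.
#' @param ... Unused.
#' @return A one-row tibble with node/edge counts and a validity flag.
#' @method glance metabolic_layout
#' @export
glance.metabolic_layout <- function(x, ...) {
  tibble(
    name = x$name,
    n_reactions = nrow(x$reactions),
    n_metabolites = nrow(x$metabolites),
    n_currency = sum(x$metabolites$kind == "currency"),
    n_edges = nrow(x$edges),
    n_info = nrow(x$info_nodes),
    valid = nrow(validate_layout(x)) == 0
  )
}

#' Tidy an overlay into its edge-style table
#'
#' @param x A `fluxmapr_overlay`.
#' @param ... Unused.
#' @return The per-edge style tibble.
#' @method tidy fluxmapr_overlay
#' @export
tidy.fluxmapr_overlay <- function(x, ...) x$edge_style

#' One-row summary of an overlay
#'
#' @param x A `fluxmapr_overlay`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance fluxmapr_overlay
#' @export
glance.fluxmapr_overlay <- function(x, ...) {
  tibble(
    n_styled_edges = nrow(x$edge_style),
    n_glyphs = nrow(x$node_glyph),
    n_label_suffixes = nrow(x$label_suffix),
    n_filters = length(x$filters),
    n_unmapped = length(x$diagnostics),
    max_width = if (nrow(x$edge_style)) max(x$edge_style$width, na.rm = TRUE) else NA_real_
  )
}

#' Plot a layout (optionally with an overlay) as a ggplot
#'
#' A quick-look companion to [render_svg()]: edges as segments (width and
#' colour from the overlay when given), reactions as squares, metabolites as
#' circles, labels as text. All nodes must be positioned.
#'
#' @param object A `metabolic_layout`.
#' @param overlay Optional `fluxmapr_overlay`.
#' @param label Draw node labels?
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metabolic_layout
#' @export
autoplot.metabolic_layout <- function(object, overlay = NULL, label = TRUE, ...) {
  nodes <- tidy(object)
  if (any(is.na(nodes$x))) {
    stop_fluxmapr("cannot plot: unpositioned nodes (run run_fdl first)", "render")
  }
  e <- object$edges
  pos <- nodes[, c("id", "x", "y")]
  e <- left_join(e, rename(pos, xr = "x", yr = "y"), by = c(reaction_id = "id"))
  e <- left_join(e, rename(pos, xm = "x", ym = "y"), by = c(metabolite_id = "id"))
  e$width <- 0.5
  e$color <- "grey40"
  if (!is.null(overlay) && nrow(overlay$edge_style)) {
    es <- overlay$edge_style
    key_e <- edge_key(e$reaction_id, e$metabolite_id, e$role)
    key_s <- edge_key(es$reaction_id, es$metabolite_id, es$role)
    i <- match(key_e, key_s)
    hit <- !is.na(i)
    w <- es$width[i[hit]]
    e$width[hit] <- ifelse(is.na(w), e$width[hit], w / 4)
    cl <- es$color[i[hit]]
    e$color[hit] <- ifelse(is.na(cl), e$color[hit], cl)
  }
  p <- ggplot() +
    geom_segment(data = e,
                 aes(x = .data$xr, y = .data$yr, xend = .data$xm, yend = .data$ym,
                     linewidth = .data$width, color = .data$color)) +
    ggplot2::scale_linewidth_identity() +
    scale_color_identity() +
    geom_point(data = nodes,
               aes(x = .data$x, y = .data$y, shape = .data$node_type),
               size = 3, fill = "white") +
    scale_shape_manual(values = c(reaction = 22, metabolite = 21)) +
    ggplot2::scale_y_reverse() +
    coord_equal() +
    theme_void() +
    labs(shape = NULL)
  if (label) {
    p <- p + geom_text(data = nodes,
                       aes(x = .data$x, y = .data$y, label = .data$label),
                       nudge_y = 12, size = 2.8)
  }
  p
}
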