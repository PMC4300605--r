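#' Split a metabolite node into per-reaction replicas
#'
#' A metabolite connected to several reactions is replaced by one replica per
#' distinct incident reaction; each replica inherits the label, model ids,
#' kind, position and fixed flag of the original and carries exactly the edges
#' linking it to its one reaction. Replica ids are `"<id>__k"` with `k`
#' assigned in lexicographic order of the neighbouring reaction ids, so the
#' operation is deterministic. Degree-1 (and degree-0) metabolites are
#' returned unchanged, which makes batch scripting idempotent. This is the
#' standard de-cluttering move for currency metabolites.
#'
#' @param layout A `metabolic_layout`.
#' @param node_id Id of the metabolite node to split.
#' @return A new `metabolic_layout`.
#' @export
split_metabolite_node <- function(layout, node_id) {
  cls <- node_class(layout, node_id)
  if (is.na(cls)) stop_not_found(node_id)
  if (cls != "metabolite") stop_wrong_kind(node_id, "metabolite")

  incident <- layout$edges[layout$edges$metabolite_id == node_id, ]
  rx <- sort(unique(incident$reaction_id))
  if (length(rx) <= 1) return(layout)

  orig <- layout$metabolites[layout$metabolites$id == node_id, ]
  replicas <- orig[rep(1, length(rx)), ]
  replicas$id <- paste0(node_id, "__", seq_along(rx))

  keep_m <- layout$metabolites[layout$metabolites$id != node_id, ]
  layout$metabolites <- bind_rows(keep_m, replicas)

  other <- layout$edges[layout$edges$metabolite_id != node_id, ]
  moved <- incident
  moved$metabolite_id <- replicas$id[match(moved$reaction_id, rx)]
  layout$edges <- bind_rows(other, moved)
  layout
}

#' Merge metabolite nodes representing the same compound
#'
#' The inverse of [split_metabolite_node()]. Nodes may only be merged when
#' they depict the same compound, operationally: identical model-id sets and
#' identical kind. The survivor is the lexicographically lowest id; it takes
#' the union of incident edges (duplicates collapsed), the centroid of the
#' merged nodes' positions (positionless nodes ignored) and stays fixed if any
#' merged node was fixed.
#'
#' @param layout A `metabolic_layout`.
#' @param node_ids Character vector of at least two metabolite node ids.
#' @return A new `metabolic_layout`.
#' @export
merge_metabolite_nodes <- function(layout, node_ids) {
  node_ids <- unique(as.character(node_ids))
  if (length(node_ids) < 2) stop_argument("merge needs at least two distinct node ids")
  for (id in node_ids) {
    cls <- node_class(layout, id)
    if (is.na(cls)) stop_not_found(id)
    if (cls != "metabolite") stop_wrong_kind(id, "metabolite")
  }
  nodes <- layout$metabolites[match(node_ids, layout$metabolites$id), ]
  ref_ids <- nodes$model_ids[[1]]
  for (i in seq_len(nrow(nodes))) {
    if (!setequal_chr(nodes$model_ids[[i]], ref_ids) || nodes$kind[i] != nodes$kind[1]) {
      stop_fluxmapr(
        sprintf("nodes '%s' and '%s' do not represent the same compound (model ids or kind differ)",
                nodes$id[1], nodes$id[i]),
        "same_compound")
    }
  }
  survivor <- min(node_ids)
  xs <- nodes$x[!is.na(nodes$x)]; ys <- nodes$y[!is.na(nodes$y)]
  srow <- which(layout$metabolites$id == survivor)
  layout$metabolites$x[srow] <- if (length(xs)) mean(xs) else NA_real_
  layout$metabolites$y[srow] <- if (length(ys)) mean(ys) else NA_real_
  layout$metabolites$fixed[srow] <- any(nodes$fixed) &&
    !is.na(layout$metabolites$x[srow])
  layout$metabolites <- layout$metabolites[
    !(layout$metabolites$id %in% setdiff(node_ids, survivor)), ]

  e <- layout$edges
  e$metabolite_id[e$metabolite_id %in% node_ids] <- survivor
  layout$edges <- distinct(e)
  layout
}

#' Replicate a reaction node
#'
#' Produces `n` copies in total (the original plus `n - 1` fresh ids
#' `"<id>__k"`), each connected to the same metabolite neighbours with the
#' same roles and sharing reversibility, label and model ids.
#'
#' @param layout A `metabolic_layout`.
#' @param node_id Reaction node id.
#' @param n Total number of copies, at least 2.
#' @return A new `metabolic_layout`.
#' @export
replicate_reaction_node <- function(layout, node_id, n) {
  cls <- node_class(layout, node_id)
  if (is.na(cls)) stop_not_found(node_id)
  if (cls != "reaction") stop_wrong_kind(node_id, "reaction")
  if (!is.numeric(n) || n < 2 || n != as.integer(n)) {
    stop_argument("n must be an integer >= 2")
  }
  n <- as.integer(n)
  orig <- layout$reactions[layout$reactions$id == node_id, ]
  copies <- orig[rep(1, n - 1L), ]
  copies$id <- paste0(node_id, "__", seq_len(n - 1L))
  layout$reactions <- bind_rows(layout$reactions, copies)

  base_edges <- layout$edges[layout$edges$reaction_id == node_id, ]
  for (cid in copies$id) {
    ne <- base_edges
    ne$reaction_id <- cid
    layout$edges <- bind_rows(layout$edges, ne)
  }
  layout
}

# Brute-force mergeability predicate: identical sorted (metabolite, role)
# incidence lists and the same reversibility flag.
reactions_mergeable <- function(layout, id_a, id_b) {
  ea <- layout$edges[layout$edges$reaction_id == id_a, c("metabolite_id", "role")]
  eb <- layout$edges[layout$edges$reaction_id == id_b, c("metabolite_id", "role")]
  ka <- sort(paste(ea$metabolite_id, ea$role))
  kb <- sort(paste(eb$metabolite_id, eb$role))
  ra <- layout$reactions$reversible[layout$reactions$id == id_a]
  rb <- layout$reactions$reversible[layout$reactions$id == id_b]
  identical(ka, kb) && identical(ra, rb)
}

#' Merge reaction nodes
#'
#' Reactions can only be merged when they are exactly the same: connected to
#' the same metabolite nodes with the same substrate/product roles, and with
#' equal reversibility. The survivor (lowest id) keeps a deduplicated edge set
#' and the union of model ids.
#'
#' @param layout A `metabolic_layout`.
#' @param node_ids Character vector of at least two reaction node ids.
#' @return A new `metabolic_layout`.
#' @export
merge_reaction_nodes <- function(layout, node_ids) {
  node_ids <- unique(as.character(node_ids))
  if (length(node_ids) < 2) stop_argument("merge needs at least two distinct node ids")
  for (id in node_ids) {
    cls <- node_class(layout, id)
    if (is.na(cls)) stop_not_found(id)
    if (cls != "reaction") stop_wrong_kind(id, "reaction")
  }
  ref <- node_ids[1]
  for (id in node_ids[-1]) {
    ea <- layout$edges[layout$edges$reaction_id == ref, ]
    eb <- layout$edges[layout$edges$reaction_id == id, ]
    ka <- sort(paste(ea$metabolite_id, ea$role))
    kb <- sort(paste(eb$metabolite_id, eb$role))
    if (!identical(ka, kb)) {
      first_diff <- c(setdiff(kb, ka), setdiff(ka, kb))[1]
      stop_fluxmapr(
        sprintf("reactions '%s' and '%s' differ in neighbourhood at '%s'", ref, id, first_diff),
        "merge_illegal")
    }
    ra <- layout$reactions$reversible[layout$reactions$id == ref]
    rb <- layout$reactions$reversible[layout$reactions$id == id]
    if (!identical(ra, rb)) {
      stop_fluxmapr(
        sprintf("reactions '%s' and '%s' differ in reversibility", ref, id),
        "merge_illegal")
    }
  }
  survivor <- min(node_ids)
  rows <- layout$reactions$id %in% node_ids
  union_ids <- unique(unlist(layout$reactions$model_ids[rows]))
  srow <- which(layout$reactions$id == survivor)
  layout$reactions$model_ids[[srow]] <- union_ids
  layout$reactions <- layout$reactions[
    !(layout$reactions$id %in% setdiff(node_ids, survivor)), ]
  e <- layout$edges
  e$reaction_id[e$reaction_id %in% node_ids] <- survivor
  layout$edges <- distinct(e)
  # info nodes follow their reaction into the survivor
  layout$info_nodes$reaction_id[layout$info_nodes$reaction_id %in% node_ids] <- survivor
  layout
}

#' Change the type of a metabolite node
#'
#' @param layout A `metabolic_layout`.
#' @param node_id Metabolite node id.
#' @param kind `"regular"` or `"currency"`.
#' @return A new `metabolic_layout`.
#' @export
set_metabolite_kind <- function(layout, node_id, kind) {
  cls <- node_class(layout, node_id)
  if (is.na(cls)) stop_not_found(node_id)
  if (cls != "metabolite") stop_wrong_kind(node_id, "metabolite")
  if (!kind %in% c("regular", "currency")) stop_argument("kind must be 'regular' or 'currency'")
  layout$metabolites$kind[layout$metabolites$id == node_id] <- kind
  layout
}

#' Pin or release nodes for the force-directed layout
#'
#' Fixing a node pins it to its current position (a positionless node is
#' placed at the origin first); unfixing clears the flag but keeps the stored
#' coordinates as the starting point for the next force-directed run, so the
#' node becomes movable without the run turning nondeterministic.
#'
#' @param layout A `metabolic_layout`.
#' @param node_id Node id (reaction or metabolite).
#' @param fixed Logical.
#' @return A new `metabolic_layout`.
#' @export
set_fixed <- function(layout, node_id, fixed) {
  cls <- node_class(layout, node_id)
  if (is.na(cls) || cls == "info") stop_not_found(node_id)
  tab <- if (cls == "reaction") "reactions" else "metabolites"
  i <- which(layout[[tab]]$id == node_id)
  if (fixed && (is.na(layout[[tab]]$x[i]) || is.na(layout[[tab]]$y[i]))) {
    layout[[tab]]$x[i] <- 0
    layout[[tab]]$y[i] <- 0
  }
  layout[[tab]]$fixed[i] <- as.logical(fixed)
  layout
}

#' @rdname set_fixed
#' @param node_kind `"reaction"` or `"metabolite"`: which node class to pin or
#'   release wholesale.
#' @export
fix_by_kind <- function(layout, node_kind, fixed) {
  if (!node_kind %in% c("reaction", "metabolite")) {
    stop_argument("node_kind must be 'reaction' or 'metabolite'")
  }
  tab <- if (node_kind == "reaction") "reactions" else "metabolites"
  if (fixed && nrow(layout[[tab]])) {
    no_pos <- is.na(layout[[tab]]$x) | is.na(layout[[tab]]$y)
    layout[[tab]]$x[no_pos] <- 0
    layout[[tab]]$y[no_pos] <- 0
  }
  layout[[tab]]$fixed <- rep(as.logical(fixed), nrow(layout[[tab]]))
  layout
}

#' Visibility filters
#'
#' A visibility filter names a set of nodes to hide; hiding a node also hides
#' its incident edges and attached info nodes at render time.
#' `filter_by_kind()` builds one from a node-type selector (e.g. hide all
#' currency metabolites); `filter_by_reaction_ids()` from reaction
#' identifiers, matching both layout node ids and model ids. Unknown ids are
#' ignored but recorded in the filter's `unknown` field. Neither function
#' mutates the layout.
#'
#' @param layout A `metabolic_layout`.
#' @param selector One of `"currency_metabolites"`, `"all_metabolites"`,
#'   `"reactions"`.
#' @param name Filter name (defaults to the selector).
#' @return A `visibility_filter`: list with `name`, `hidden` (node ids) and
#'   `unknown` (ids that matched nothing).
#' @export
filter_by_kind <- function(layout, selector, name = selector) {
  hidden <- switch(selector,
    currency_metabolites = layout$metabolites$id[layout$metabolites$kind == "currency"],
    all_metabolites = layout$metabolites$id,
    reactions = layout$reactions$id,
    stop_argument(sprintf("unknown selector '%s'", selector))
  )
  visibility_filter(name, hidden)
}

#' @rdname filter_by_kind
#' @param ids Character vector of reaction node ids or model reaction ids.
#' @export
filter_by_reaction_ids <- function(layout, ids, name = "by_reaction_id") {
  ids <- as.character(ids)
  hit <- map_lgl(seq_len(nrow(layout$reactions)), function(i) {
    layout$reactions$id[i] %in% ids ||
      length(intersect(layout$reactions$model_ids[[i]], ids)) > 0
  })
  hidden <- layout$reactions$id[hit]
  known <- unique(c(layout$reactions$id[hit], unlist(layout$reactions$model_ids[hit])))
  visibility_filter(name, hidden, unknown = setdiff(ids, known))
}

#' @rdname filter_by_kind
#' @param hidden Character vector of node ids to hide.
#' @param unknown Ids that were requested but matched nothing (diagnostics).
#' @export
visibility_filter <- function(name, hidden, unknown = character()) {
  structure(
    list(name = as.character(name), hidden = unique(as.character(hidden)),
         unknown = as.character(unknown)),
    class = "visibility_filter"
  )
}

#' @export
print.visibility_filter <- function(x, ...) {
  cat(sprintf("<visibility_filter '%s': %d hidden node(s)>\n", x$name, length(x$hidden)))
  invisible(x)
}

# Resolve the visible part of a layout under a set of filters: hidden nodes
# drop out together with incident edges, attached info nodes, and (optionally
# already included in the filters) nothing else.
visible_subgraph <- function(layout, filters = list()) {
  hidden <- unique(unlist(lapply(filters, function(f) f$hidden)))
  mets <- layout$metabolites[!layout$metabolites$id %in% hidden, ]
  rxns <- layout$reactions[!layout$reactions$id %in% hidden, ]
  edges <- layout$edges[layout$edges$reaction_id %in% rxns$id &
                          layout$edges$metabolite_id %in% mets$id, ]
  info <- layout$info_nodes[layout$info_nodes$reaction_id %in% rxns$id &
                              !layout$info_nodes$id %in% hidden, ]
  list(metabolites = mets, reactions = rxns, edges = edges, info_nodes = info)
}
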