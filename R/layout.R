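#' Construct a metabolic layout
#'
#' A metabolic layout is the bipartite reaction-compound graph at the heart of
#' the package: reaction nodes on one side, metabolite nodes on the other,
#' edges only between the two classes. Each node carries a list of model
#' identifiers linking it to one or more genome-scale metabolic models, an
#' optional position on an abstract canvas (origin top-left, y increasing
#' downward, as in SVG) and a `fixed` flag that pins it against the
#' force-directed layout. Metabolites are typed `"regular"` or `"currency"`
#' (highly connected hub compounds such as water or ATP, usually replicated or
#' hidden). Reversibility is a property of the reaction node; arrowheads are
#' derived from it at render time, never stored.
#'
#' @param name Layout name.
#' @param metabolites Data frame with columns `id` and optionally `label`,
#'   `model_ids` (list column of character vectors), `kind` (`"regular"` or
#'   `"currency"`), `x`, `y`, `fixed`.
#' @param reactions Data frame with columns `id` and optionally `label`,
#'   `model_ids`, `reversible`, `x`, `y`, `fixed`.
#' @param edges Data frame with columns `reaction_id`, `metabolite_id`, `role`
#'   (`"substrate"` or `"product"`).
#' @param info_nodes Data frame with columns `id`, `text`, `reaction_id`:
#'   free-text annotations attached to a reaction node.
#'
#' @return An object of class `metabolic_layout`: a list of tibbles
#'   (`$metabolites`, `$reactions`, `$edges`, `$info_nodes`) plus `$name`.
#' @export
#' @examples
#' lay <- metabolic_layout(
#'   name = "toy",
#'   metabolites = data.frame(id = c("glc", "g6p")),
#'   reactions = data.frame(id = "HEX1", reversible = FALSE),
#'   edges = data.frame(
#'     reaction_id = "HEX1",
#'     metabolite_id = c("glc", "g6p"),
#'     role = c("substrate", "product")
#'   )
#' )
#' validate_layout(lay)
metabolic_layout <- function(name = "", metabolites = NULL, reactions = NULL,
                             edges = NULL, info_nodes = NULL) {
  structure(
    list(
      name = as.character(name),
      metabolites = normalize_metabolites(metabolites),
      reactions = normalize_reactions(reactions),
      edges = normalize_edges(edges),
      info_nodes = normalize_info_nodes(info_nodes)
    ),
    class = "metabolic_layout"
  )
}

empty_metabolites <- function() {
  tibble(id = character(), label = character(), model_ids = list(),
         kind = character(), x = double(), y = double(), fixed = logical())
}

empty_reactions <- function() {
  tibble(id = character(), label = character(), model_ids = list(),
         reversible = logical(), x = double(), y = double(), fixed = logical())
}

empty_edges <- function() {
  tibble(reaction_id = character(), metabolite_id = character(), role = character())
}

empty_info_nodes <- function() {
  tibble(id = character(), text = character(), reaction_id = character())
}

col_or <- function(df, name, default) {
  if (name %in% names(df)) df[[name]] else default
}

as_model_ids <- function(x, n) {
  if (is.null(x)) return(replicate(n, character(), simplify = FALSE))
  if (!is.list(x)) x <- as.list(as.character(x))
  lapply(x, function(v) if (length(v) == 1 && is.na(v)) character() else as.character(v))
}

normalize_metabolites <- function(df) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0) return(empty_metabolites())
  df <- as_tibble(df)
  n <- nrow(df)
  tibble(
    id = as.character(df$id),
    label = as.character(col_or(df, "label", df$id)),
    model_ids = as_model_ids(col_or(df, "model_ids", NULL), n),
    kind = as.character(col_or(df, "kind", rep("regular", n))),
    x = as.double(col_or(df, "x", rep(NA_real_, n))),
    y = as.double(col_or(df, "y", rep(NA_real_, n))),
    fixed = as.logical(col_or(df, "fixed", rep(FALSE, n)))
  )
}

normalize_reactions <- function(df) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0) return(empty_reactions())
  df <- as_tibble(df)
  n <- nrow(df)
  tibble(
    id = as.character(df$id),
    label = as.character(col_or(df, "label", df$id)),
    model_ids = as_model_ids(col_or(df, "model_ids", NULL), n),
    reversible = as.logical(col_or(df, "reversible", rep(FALSE, n))),
    x = as.double(col_or(df, "x", rep(NA_real_, n))),
    y = as.double(col_or(df, "y", rep(NA_real_, n))),
    fixed = as.logical(col_or(df, "fixed", rep(FALSE, n)))
  )
}

normalize_edges <- function(df) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0) return(empty_edges())
  df <- as_tibble(df)
  tibble(
    reaction_id = as.character(df$reaction_id),
    metabolite_id = as.character(df$metabolite_id),
    role = as.character(df$role)
  )
}

normalize_info_nodes <- function(df) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0) return(empty_info_nodes())
  df <- as_tibble(df)
  tibble(
    id = as.character(df$id),
    text = as.character(col_or(df, "text", rep("", nrow(df)))),
    reaction_id = as.character(df$reaction_id)
  )
}

#' @export
print.metabolic_layout <- function(x, ...) {
  cat(sprintf(
    "<metabolic_layout '%s': %d reactions, %d metabolites (%d currency), %d edges, %d info nodes>\n",
    x$name, nrow(x$reactions), nrow(x$metabolites),
    sum(x$metabolites$kind == "currency"), nrow(x$edges), nrow(x$info_nodes)
  ))
  invisible(x)
}

#' Add a reaction (with its metabolites) to a layout
#'
#' Convenience builder: appends one reaction node, creates any metabolite
#' nodes not yet present, and wires substrate/product edges. Used heavily to
#' assemble small layouts programmatically.
#'
#' @param layout A `metabolic_layout`.
#' @param id Reaction node id.
#' @param substrates,products Character vectors of metabolite node ids.
#' @param reversible Reaction reversibility.
#' @param label Display label (defaults to `id`).
#' @param model_ids Model reaction identifiers (defaults to `id`).
#' @return The extended layout.
#' @export
add_reaction <- function(layout, id, substrates = character(), products = character(),
                         reversible = FALSE, label = id, model_ids = id) {
  stopifnot(inherits(layout, "metabolic_layout"))
  layout$reactions <- bind_rows(layout$reactions, tibble(
    id = id, label = label, model_ids = list(as.character(model_ids)),
    reversible = reversible, x = NA_real_, y = NA_real_, fixed = FALSE
  ))
  mets <- unique(c(substrates, products))
  new_mets <- setdiff(mets, layout$metabolites$id)
  if (length(new_mets)) {
    layout$metabolites <- bind_rows(layout$metabolites, tibble(
      id = new_mets, label = new_mets, model_ids = as.list(new_mets),
      kind = "regular", x = NA_real_, y = NA_real_, fixed = FALSE
    ))
  }
  layout$edges <- bind_rows(
    layout$edges,
    tibble(reaction_id = id, metabolite_id = substrates, role = "substrate"),
    tibble(reaction_id = id, metabolite_id = products, role = "product")
  )
  layout
}

#' Validate the structural invariants of a layout
#'
#' Checks the bipartite contract and referential integrity: unique node ids,
#' edges whose endpoints exist and connect a reaction to a metabolite (never
#' reaction-reaction or metabolite-metabolite), no duplicate
#' (reaction, metabolite, role) triples, info nodes attached to existing
#' reactions, legal `kind`/`role` values, and `fixed` nodes carrying a
#' position. Validation reports, it never throws.
#'
#' @param layout A `metabolic_layout`.
#' @return A tibble of violation records with columns `rule`, `ref`,
#'   `message`; zero rows iff the layout is valid.
#' @export
validate_layout <- function(layout) {
  v <- list()
  add <- function(rule, ref, message) {
    v[[length(v) + 1]] <<- tibble(rule = rule, ref = ref, message = message)
  }
  rx_ids <- layout$reactions$id
  mb_ids <- layout$metabolites$id
  all_ids <- c(rx_ids, mb_ids, layout$info_nodes$id)
  for (id in unique(all_ids[duplicated(all_ids)])) {
    add("duplicate_node_id", id, sprintf("node id '%s' occurs more than once", id))
  }
  for (id in all_ids[!nzchar(all_ids)]) {
    add("empty_node_id", id, "node id is empty")
  }
  e <- layout$edges
  if (nrow(e)) {
    for (i in seq_len(nrow(e))) {
      r <- e$reaction_id[i]; m <- e$metabolite_id[i]
      if (r %in% mb_ids) {
        add("bipartiteness", r, sprintf("edge reaction end '%s' is a metabolite node", r))
      } else if (!(r %in% rx_ids)) {
        add("dangling_endpoint", r, sprintf("edge references missing reaction node '%s'", r))
      }
      if (m %in% rx_ids) {
        add("bipartiteness", m, sprintf("edge metabolite end '%s' is a reaction node", m))
      } else if (!(m %in% mb_ids)) {
        add("dangling_endpoint", m, sprintf("edge references missing metabolite node '%s'", m))
      }
      if (!e$role[i] %in% c("substrate", "product")) {
        add("bad_role", e$role[i], sprintf("edge role '%s' is not substrate/product", e$role[i]))
      }
    }
    keys <- edge_key(e$reaction_id, e$metabolite_id, e$role)
    for (k in unique(keys[duplicated(keys)])) {
      parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
      add("duplicate_edge", parts[1],
          sprintf("duplicate edge (%s, %s, %s)", parts[1], parts[2], parts[3]))
    }
  }
  bad_kind <- layout$metabolites$id[!layout$metabolites$kind %in% c("regular", "currency")]
  for (id in bad_kind) add("bad_kind", id, sprintf("metabolite '%s' has unknown kind", id))
  dangling_info <- layout$info_nodes$id[!layout$info_nodes$reaction_id %in% rx_ids]
  for (id in dangling_info) {
    add("dangling_info_node", id, sprintf("info node '%s' references a missing reaction", id))
  }
  for (tab in list(layout$metabolites, layout$reactions)) {
    if (nrow(tab)) {
      bad <- tab$id[tab$fixed & (is.na(tab$x) | is.na(tab$y))]
      for (id in bad) add("fixed_without_position", id,
                          sprintf("node '%s' is fixed but has no position", id))
    }
  }
  if (length(v)) bind_rows(v) else tibble(rule = character(), ref = character(), message = character())
}

# Degree table: edges per metabolite node.
metabolite_degree <- function(layout, id) {
  sum(layout$edges$metabolite_id == id)
}

node_class <- function(layout, id) {
  if (id %in% layout$reactions$id) return("reaction")
  if (id %in% layout$metabolites$id) return("metabolite")
  if (id %in% layout$info_nodes$id) return("info")
  NA_character_
}
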