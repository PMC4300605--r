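#' Default currency metabolite identifiers
#'
#' Hub compounds (protons, water, energy and redox carriers) that clutter
#' drawings; matched case-insensitively after stripping a leading `M_` prefix
#' and a trailing compartment suffix (`_c`, `_e`, `[c]`, ...).
#'
#' @return Character vector of canonical currency ids.
#' @export
default_currency_ids <- function() {
  c("h", "h2o", "atp", "adp", "pi", "nad", "nadh", "nadp", "nadph", "co2", "coa")
}

strip_compartment <- function(id) {
  x <- sub("^M_", "", id)
  x <- sub("\\[[A-Za-z0-9]+\\]$", "", x)
  x <- sub("_[A-Za-z0-9]{1,2}$", "", x)
  tolower(x)
}

#' Generate a layout from a model's reactions or pathways
#'
#' Builds a bipartite layout de novo from a model digest: one reaction node
#' per selected reaction (model ids set to the reaction id, reversibility
#' taken from the model) and metabolite nodes for every participant.
#' Metabolites named in `currency_ids` (after compartment stripping), or
#' whose degree within the selection exceeds `currency_degree_threshold`, are
#' typed currency and instantiated as one degree-limited replica per
#' reaction; regular metabolites are shared nodes. A metabolite appearing on
#' both sides of a reaction yields two edges with different roles;
#' stoichiometric coefficients are not stored — the layout is qualitative.
#'
#' With `basis` given, the basis layout is extended: reactions already
#' present (matched by model id) are reused, only new reactions are appended,
#' and regular metabolites are resolved against the basis's model ids. All
#' newly created nodes are unfixed so a force-directed run can place them.
#'
#' @param model A `model_digest` (see [read_sbml_model()]).
#' @param reactions Character vector of model reaction ids to include.
#' @param pathways Character vector of pathway names (requires pathway
#'   information in the model); union of their reactions is used. Give
#'   either `reactions` or `pathways` (or both, unioned).
#' @param basis Optional `metabolic_layout` to extend.
#' @param currency_ids Currency metabolite list (canonical, lowercase).
#' @param currency_degree_threshold Degree above which a metabolite is
#'   treated as currency regardless of its name.
#' @return A `metabolic_layout`.
#' @export
generate_pathway_layout <- function(model, reactions = NULL, pathways = NULL,
                                    basis = NULL,
                                    currency_ids = default_currency_ids(),
                                    currency_degree_threshold = 8) {
  stopifnot(inherits(model, "model_digest"))
  sel <- character()
  if (!is.null(pathways)) {
    known <- unique(model$pathways$pathway)
    bad <- setdiff(pathways, known)
    if (length(bad)) {
      stop_fluxmapr(sprintf("unknown pathway(s): %s", paste(bad, collapse = ", ")),
                    "selection")
    }
    sel <- c(sel, model$pathways$reaction_id[model$pathways$pathway %in% pathways])
  }
  if (!is.null(reactions)) {
    bad <- setdiff(reactions, model$reactions$id)
    if (length(bad)) {
      stop_fluxmapr(sprintf("unknown reaction(s): %s", paste(bad, collapse = ", ")),
                    "selection")
    }
    sel <- c(sel, reactions)
  }
  sel <- unique(sel)
  if (!length(sel)) stop_argument("empty selection: give reactions and/or pathways")

  layout <- basis %||% metabolic_layout(name = "generated")
  stopifnot(inherits(layout, "metabolic_layout"))

  has_model_id <- function(tab, mid) {
    which(map_lgl(tab$model_ids, function(v) mid %in% v))
  }
  existing_rx <- map_lgl(sel, function(r) length(has_model_id(layout$reactions, r)) > 0)
  new_sel <- sel[!existing_rx]

  # participation degree within the selection (distinct reactions)
  parts <- list()
  for (r in new_sel) {
    row <- model$reactions[model$reactions$id == r, ]
    subs <- row$substrates[[1]]
    prods <- row$products[[1]]
    parts[[r]] <- list(substrates = subs, products = prods)
  }
  all_sel_rows <- model$reactions[model$reactions$id %in% sel, ]
  degree <- table(unlist(lapply(seq_len(nrow(all_sel_rows)), function(i) {
    unique(c(all_sel_rows$substrates[[i]], all_sel_rows$products[[i]]))
  })))
  is_currency <- function(mid) {
    strip_compartment(mid) %in% currency_ids ||
      (!is.na(degree[mid]) && degree[mid] > currency_degree_threshold)
  }

  fresh_id <- function(base) {
    taken <- c(layout$reactions$id, layout$metabolites$id, layout$info_nodes$id)
    if (!base %in% taken) return(base)
    k <- 1
    while (paste0(base, "__", k) %in% taken) k <- k + 1
    paste0(base, "__", k)
  }

  met_label <- function(mid) {
    nm <- model$metabolites$name[model$metabolites$id == mid]
    if (length(nm) && nzchar(nm[1])) nm[1] else mid
  }

  resolve_regular <- function(mid) {
    hit <- has_model_id(layout$metabolites, mid)
    hit <- hit[layout$metabolites$kind[hit] == "regular"]
    if (length(hit)) return(layout$metabolites$id[hit[1]])
    nid <- fresh_id(mid)
    layout$metabolites <<- bind_rows(layout$metabolites, tibble(
      id = nid, label = met_label(mid), model_ids = list(mid), kind = "regular",
      x = NA_real_, y = NA_real_, fixed = FALSE
    ))
    nid
  }

  for (r in new_sel) {
    row <- model$reactions[model$reactions$id == r, ]
    rid <- fresh_id(r)
    layout$reactions <- bind_rows(layout$reactions, tibble(
      id = rid, label = if (nzchar(row$name)) row$name else r,
      model_ids = list(r), reversible = row$reversible,
      x = NA_real_, y = NA_real_, fixed = FALSE
    ))
    part <- bind_rows(
      tibble(mid = unique(parts[[r]]$substrates), role = "substrate"),
      tibble(mid = unique(parts[[r]]$products), role = "product")
    )
    for (mid in unique(part$mid)) {
      if (is_currency(mid)) {
        # one currency replica per reaction, even when on both sides
        nid <- fresh_id(mid)
        layout$metabolites <- bind_rows(layout$metabolites, tibble(
          id = nid, label = met_label(mid), model_ids = list(mid),
          kind = "currency", x = NA_real_, y = NA_real_, fixed = FALSE
        ))
      } else {
        nid <- resolve_regular(mid)
      }
      for (role in part$role[part$mid == mid]) {
        layout$edges <- bind_rows(layout$edges, tibble(
          reaction_id = rid, metabolite_id = nid, role = role
        ))
      }
    }
  }
  layout
}
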