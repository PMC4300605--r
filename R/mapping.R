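#' Read a two-column layout/model mapping table
#'
#' Parses the explicit-mapping file format: whitespace- or tab-delimited
#' two-column text, first column the layout node id, second the model id.
#' Lines starting with `#` (and blank lines) are ignored; duplicate pairs are
#' collapsed.
#'
#' @param path Path to the file, or a character vector of lines.
#' @return A tibble with columns `layout_id`, `model_id`.
#' @export
load_mapping_table <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path, warn = FALSE) else path
  keep <- which(!grepl("^\\s*(#|$)", lines))
  out <- list()
  for (i in keep) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) {
      stop_parse(sprintf("mapping table line %d has %d columns, expected 2", i, length(parts)))
    }
    out[[length(out) + 1]] <- tibble(layout_id = parts[1], model_id = parts[2])
  }
  if (!length(out)) return(tibble(layout_id = character(), model_id = character()))
  distinct(bind_rows(out))
}

#' Build a model-to-layout identifier mapping
#'
#' Resolves model reaction and metabolite identifiers to layout nodes. Two
#' exclusive modes:
#'
#' * **pairs mode** (`pairs` given): exactly the listed
#'   (layout id, model id) pairs are mapped; nothing is inferred.
#' * **regex mode** (default): each side's identifiers are canonicalized by a
#'   regex substitution (`layout_regex` applied to layout node ids,
#'   `model_regex` to model ids; both optional and defaulting to the identity)
#'   and matched on equal canonical strings. Independently of the regexes, a
#'   model id listed verbatim in a node's `model_ids` also matches — this is
#'   how curated layouts carry their model links.
#'
#' A model id may resolve to several nodes (replicas) and several model ids
#' may resolve to one node. Unmatched identifiers on either side are never
#' fatal; they are collected for diagnostics. Matching is case-sensitive, as
#' SBML identifiers are.
#'
#' @param layout A `metabolic_layout`.
#' @param model_reaction_ids,model_metabolite_ids Character vectors of model
#'   identifiers to resolve.
#' @param pairs Optional tibble from [load_mapping_table()] (columns
#'   `layout_id`, `model_id`).
#' @param layout_regex,model_regex Optional length-2 character vectors
#'   `c(pattern, replacement)` canonicalizing the respective side.
#' @return A `model_mapping`: list with tibbles `reaction_map` and
#'   `metabolite_map` (columns `model_id`, `node_id`) plus
#'   `unmatched_model_ids` and `unmatched_layout_ids`.
#' @export
build_mapping <- function(layout, model_reaction_ids, model_metabolite_ids = character(),
                          pairs = NULL, layout_regex = NULL, model_regex = NULL) {
  model_reaction_ids <- unique(as.character(model_reaction_ids))
  model_metabolite_ids <- unique(as.character(model_metabolite_ids))
  if (!is.null(pairs) && (!is.null(layout_regex) || !is.null(model_regex))) {
    stop_argument("use either explicit pairs or regex canonicalization, not both")
  }
  subst <- function(ids, rx) {
    if (is.null(rx)) return(ids)
    if (length(rx) != 2) stop_fluxmapr("regex must be c(pattern, replacement)", "configuration")
    res <- tryCatch(suppressWarnings(gsub(rx[1], rx[2], ids)), error = function(e) NULL)
    if (is.null(res)) stop_fluxmapr(sprintf("invalid regular expression '%s'", rx[1]), "configuration")
    res
  }

  match_side <- function(nodes, model_ids) {
    if (!nrow(nodes) || !length(model_ids)) {
      return(tibble(model_id = character(), node_id = character()))
    }
    if (!is.null(pairs)) {
      p <- pairs[pairs$layout_id %in% nodes$id & pairs$model_id %in% model_ids, ]
      return(tibble(model_id = p$model_id, node_id = p$layout_id))
    }
    canon_layout <- subst(nodes$id, layout_regex)
    canon_model <- subst(model_ids, model_regex)
    hits <- list()
    for (j in seq_along(model_ids)) {
      by_canon <- nodes$id[canon_layout == canon_model[j]]
      by_list <- nodes$id[map_lgl(nodes$model_ids, function(v) model_ids[j] %in% v)]
      nd <- unique(c(by_canon, by_list))
      if (length(nd)) {
        hits[[length(hits) + 1]] <- tibble(model_id = model_ids[j], node_id = nd)
      }
    }
    if (!length(hits)) return(tibble(model_id = character(), node_id = character()))
    bind_rows(hits)
  }

  rmap <- arrange(match_side(layout$reactions, model_reaction_ids), .data$model_id, .data$node_id)
  mmap <- arrange(match_side(layout$metabolites, model_metabolite_ids), .data$model_id, .data$node_id)

  structure(
    list(
      reaction_map = rmap,
      metabolite_map = mmap,
      unmatched_model_ids = c(setdiff(model_reaction_ids, rmap$model_id),
                              setdiff(model_metabolite_ids, mmap$model_id)),
      unmatched_layout_ids = c(setdiff(layout$reactions$id, rmap$node_id),
                               setdiff(layout$metabolites$id, mmap$node_id))
    ),
    class = "model_mapping"
  )
}

#' @export
print.model_mapping <- function(x, ...) {
  cat(sprintf(
    "<model_mapping: %d reaction pairs, %d metabolite pairs, %d unmatched model id(s)>\n",
    nrow(x$reaction_map), nrow(x$metabolite_map), length(x$unmatched_model_ids)
  ))
  invisible(x)
}

#' Construct a flux distribution
#'
#' A flux distribution assigns a rate (conventionally mmol gDW^-1 h^-1, sign
#' relative to the reaction's declared orientation) to model reaction ids.
#' Non-finite values are rejected.
#'
#' @param values Named numeric vector (names are model reaction ids) or a
#'   two-column data frame (`reaction_id`, `value`).
#' @return A `flux_distribution`: tibble with columns `reaction_id`, `value`.
#' @export
flux_distribution <- function(values) {
  if (is.data.frame(values)) {
    df <- tibble(reaction_id = as.character(values[[1]]), value = as.double(values[[2]]))
  } else {
    df <- tibble(reaction_id = names(values) %||% character(), value = as.double(values))
  }
  if (nrow(df) && any(!is.finite(df$value))) {
    stop_argument("flux distributions must contain finite values only")
  }
  structure(distinct(df), class = c("flux_distribution", class(df)))
}

#' Read a flux distribution from a TSV file
#'
#' Expects `reaction_id<TAB>value` lines, an optional non-numeric header line,
#' and `#` comments.
#'
#' @param path File path.
#' @return A `flux_distribution`.
#' @export
read_flux_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t| +")
  rows <- list()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2) stop_parse(sprintf("flux file line %d has fewer than 2 columns", i))
    val <- suppressWarnings(as.double(p[2]))
    if (is.na(val)) {
      if (i == 1) next  # header line
      stop_parse(sprintf("flux file line %d has non-numeric value '%s'", i, p[2]))
    }
    rows[[length(rows) + 1]] <- tibble(reaction_id = p[1], value = val)
  }
  if (!length(rows)) return(flux_distribution(tibble(reaction_id = character(), value = double())))
  flux_distribution(bind_rows(rows))
}

#' Aggregate model-level fluxes onto layout reaction nodes
#'
#' Each reaction node receives the sum of the flux values over all model
#' reaction ids mapped to it (several model reactions collapsed into one node
#' are summed; a model id mapped to several replica nodes contributes its full
#' value to each, since replicas depict the same reaction). Nodes with no
#' mapped flux are absent from the result.
#'
#' @param layout A `metabolic_layout`.
#' @param mapping A `model_mapping` targeting `layout`.
#' @param flux A `flux_distribution`.
#' @return A tibble with columns `node_id`, `flux`.
#' @export
fluxes_per_reaction_node <- function(layout, mapping, flux) {
  fl <- flux_distribution(flux)
  joined <- dplyr::inner_join(mapping$reaction_map, fl,
                              by = c(model_id = "reaction_id"))
  joined <- joined[joined$node_id %in% layout$reactions$id, ]
  out <- summarise(group_by(joined, node_id = .data$node_id), flux = sum(.data$value))
  arrange(ungroup(out), .data$node_id)
}
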