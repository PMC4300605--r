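#' Read and write XGMML layouts
#'
#' XGMML is a generic XML graph format (used e.g. by Cytoscape) with no
#' metabolic vocabulary, so the package uses a documented dialect for a
#' lossless round trip: each `<node>` carries `att` elements `nodetype`
#' (`reaction`, `metabolite`, `currency` or `info`), `model_ids`
#' (comma-joined), `reversible`/`fixed` flags, and a `<graphics>` element
#' with `x`/`y` when the node is positioned; each `<edge>` carries an `att`
#' `role` (`substrate`/`product`). Reading tolerates foreign attributes and
#' namespaces; a node without a `nodetype` att is taken as a regular
#' metabolite with a warning.
#'
#' @param stream File path or literal XML text.
#' @return For `read_xgmml()`, a list with `$layout` (a `metabolic_layout`)
#'   and `$report` (a `format_report`). For `write_xgmml()`, the path (or,
#'   with `path = NULL`, the XML text) invisibly.
#' @export
read_xgmml <- function(stream) {
  doc <- read_xml_input(stream)
  xml_ns_strip(doc)
  warnings <- character()

  get_att <- function(node, name) {
    att <- xml_find_first(node, sprintf("./att[@name='%s']", name))
    if (inherits(att, "xml_missing")) NA_character_ else xml_attr(att, "value")
  }

  mets <- list(); rxns <- list(); infos <- list()
  for (node in xml_find_all(doc, "//node")) {
    id <- xml_attr(node, "id")
    label <- xml_attr(node, "label") %||% id
    if (is.na(label)) label <- id
    ntype <- get_att(node, "nodetype")
    if (is.na(ntype)) {
      warnings <- c(warnings, sprintf("node '%s' has no nodetype att; assuming regular metabolite", id))
      ntype <- "metabolite"
    }
    g <- xml_find_first(node, "./graphics")
    x <- if (inherits(g, "xml_missing")) NA_real_ else num_or_na(xml_attr(g, "x"))
    y <- if (inherits(g, "xml_missing")) NA_real_ else num_or_na(xml_attr(g, "y"))
    mids <- get_att(node, "model_ids")
    mids <- if (is.na(mids) || !nzchar(mids)) character() else strsplit(mids, ",", fixed = TRUE)[[1]]
    fixed <- identical(get_att(node, "fixed"), "true")
    if (ntype %in% c("metabolite", "currency")) {
      mets[[length(mets) + 1]] <- tibble(
        id = id, label = label, model_ids = list(mids),
        kind = if (ntype == "currency") "currency" else "regular",
        x = x, y = y, fixed = fixed)
    } else if (ntype == "reaction") {
      rxns[[length(rxns) + 1]] <- tibble(
        id = id, label = label, model_ids = list(mids),
        reversible = identical(get_att(node, "reversible"), "true"),
        x = x, y = y, fixed = fixed)
    } else if (ntype == "info") {
      infos[[length(infos) + 1]] <- tibble(
        id = id, text = get_att(node, "text") %||% "",
        reaction_id = get_att(node, "reaction_id"))
    } else {
      warnings <- c(warnings, sprintf("node '%s' has unknown nodetype '%s'; skipped", id, ntype))
    }
  }

  edges <- list()
  for (edge in xml_find_all(doc, "//edge")) {
    role <- xml_find_first(edge, "./att[@name='role']")
    role <- if (inherits(role, "xml_missing")) "substrate" else xml_attr(role, "value")
    edges[[length(edges) + 1]] <- tibble(
      reaction_id = xml_attr(edge, "source"),
      metabolite_id = xml_attr(edge, "target"),
      role = role)
  }

  layout <- metabolic_layout(
    name = xml_attr(xml_find_first(doc, "/graph"), "label") %||% "",
    metabolites = if (length(mets)) bind_rows(mets) else NULL,
    reactions = if (length(rxns)) bind_rows(rxns) else NULL,
    edges = if (length(edges)) bind_rows(edges) else NULL,
    info_nodes = if (length(infos)) bind_rows(infos) else NULL
  )
  if (is.na(layout$name)) layout$name <- ""
  list(layout = layout, report = layout_report("xgmml", layout, warnings))
}

#' @rdname read_xgmml
#' @param layout A `metabolic_layout`.
#' @param path Output file path, or `NULL` to return the XML text.
#' @export
write_xgmml <- function(layout, path = NULL) {
  doc <- xml_new_root("graph",
                      xmlns = "http://www.cs.rpi.edu/XGMML",
                      label = layout$name, directed = "1")
  add_att <- function(node, name, value) {
    xml_add_child(node, "att", name = name, value = value)
  }
  add_graphics <- function(node, x, y) {
    if (!is.na(x) && !is.na(y)) {
      xml_add_child(node, "graphics", x = fmt_num(x), y = fmt_num(y))
    }
  }
  m <- layout$metabolites
  for (i in seq_len(nrow(m))) {
    node <- xml_add_child(doc, "node", id = m$id[i], label = m$label[i])
    add_att(node, "nodetype", if (m$kind[i] == "currency") "currency" else "metabolite")
    add_att(node, "model_ids", paste(m$model_ids[[i]], collapse = ","))
    add_att(node, "fixed", if (isTRUE(m$fixed[i])) "true" else "false")
    add_graphics(node, m$x[i], m$y[i])
  }
  r <- layout$reactions
  for (i in seq_len(nrow(r))) {
    node <- xml_add_child(doc, "node", id = r$id[i], label = r$label[i])
    add_att(node, "nodetype", "reaction")
    add_att(node, "model_ids", paste(r$model_ids[[i]], collapse = ","))
    add_att(node, "reversible", if (isTRUE(r$reversible[i])) "true" else "false")
    add_att(node, "fixed", if (isTRUE(r$fixed[i])) "true" else "false")
    add_graphics(node, r$x[i], r$y[i])
  }
  n <- layout$info_nodes
  for (i in seq_len(nrow(n))) {
    node <- xml_add_child(doc, "node", id = n$id[i], label = n$text[i])
    add_att(node, "nodetype", "info")
    add_att(node, "text", n$text[i])
    add_att(node, "reaction_id", n$reaction_id[i])
  }
  e <- layout$edges
  for (i in seq_len(nrow(e))) {
    edge <- xml_add_child(doc, "edge",
                          source = e$reaction_id[i], target = e$metabolite_id[i],
                          label = paste0(e$reaction_id[i], "-", e$metabolite_id[i]))
    add_att(edge, "role", e$role[i])
  }
  if (is.null(path)) return(invisible(as.character(doc)))
  write_xml(doc, path)
  invisible(path)
}
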