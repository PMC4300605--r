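#' Read a KGML (KEGG Markup Language) pathway
#'
#' Each `<reaction>` element becomes a reaction node (model ids are the
#' whitespace-separated KEGG reaction names, reversibility from the `type`
#' attribute); its substrates and products are resolved through the
#' `<entry>` elements of type compound and become metabolite nodes. KEGG
#' graphics coordinates are used as-is (pixels, y down) and nodes that carry
#' them are created fixed. A reaction participant referencing a missing
#' entry is skipped with a warning; a file with no `<reaction>` elements
#' yields an empty layout plus a warning.
#'
#' @param stream File path or literal XML text.
#' @return A list with `$layout` and `$report`.
#' @export
read_kgml <- function(stream) {
  doc <- read_xml_input(stream)
  xml_ns_strip(doc)
  warnings <- character()

  entries <- list()
  for (entry in xml_find_all(doc, "//entry")) {
    id <- xml_attr(entry, "id")
    g <- xml_find_first(entry, "./graphics")
    entries[[id]] <- list(
      name = xml_attr(entry, "name"),
      type = xml_attr(entry, "type"),
      label = {
        nm <- if (inherits(g, "xml_missing")) NA_character_ else xml_attr(g, "name")
        if (is.na(nm)) xml_attr(entry, "name") else sub(",.*$", "", nm)
      },
      x = if (inherits(g, "xml_missing")) NA_real_ else num_or_na(xml_attr(g, "x")),
      y = if (inherits(g, "xml_missing")) NA_real_ else num_or_na(xml_attr(g, "y"))
    )
  }

  mets <- list(); rxns <- list(); edges <- list()
  seen_met <- character()
  reactions <- xml_find_all(doc, "//reaction")
  if (!length(reactions)) {
    warnings <- c(warnings, "KGML input contains no <reaction> elements; layout is empty")
  }
  for (rxn in reactions) {
    rid <- xml_attr(rxn, "id")
    if (is.na(rid)) rid <- xml_attr(rxn, "name")
    name <- xml_attr(rxn, "name")
    ent <- entries[[rid]]
    rxns[[length(rxns) + 1]] <- tibble(
      id = rid, label = name,
      model_ids = list(strsplit(name, "\\s+")[[1]]),
      reversible = identical(xml_attr(rxn, "type"), "reversible"),
      x = if (is.null(ent)) NA_real_ else ent$x,
      y = if (is.null(ent)) NA_real_ else ent$y,
      fixed = !is.null(ent) && !is.na(ent$x) && !is.na(ent$y))
    for (role in c("substrate", "product")) {
      for (part in xml_find_all(rxn, paste0("./", role))) {
        pid <- xml_attr(part, "id")
        pent <- entries[[pid]]
        if (is.null(pent)) {
          warnings <- c(warnings, sprintf(
            "reaction '%s' %s '%s' references a missing entry; skipped", rid, role, pid))
          next
        }
        if (!pid %in% seen_met) {
          seen_met <- c(seen_met, pid)
          mets[[length(mets) + 1]] <- tibble(
            id = pid, label = pent$label %||% xml_attr(part, "name"),
            model_ids = list(strsplit(xml_attr(part, "name") %||% pent$name, "\\s+")[[1]]),
            kind = "regular",
            x = pent$x, y = pent$y,
            fixed = !is.na(pent$x) && !is.na(pent$y))
        }
        edges[[length(edges) + 1]] <- tibble(
          reaction_id = rid, metabolite_id = pid, role = role)
      }
    }
  }

  layout <- metabolic_layout(
    name = xml_attr(xml_find_first(doc, "/pathway"), "name") %||% "",
    metabolites = if (length(mets)) bind_rows(mets) else NULL,
    reactions = if (length(rxns)) bind_rows(rxns) else NULL,
    edges = if (length(edges)) distinct(bind_rows(edges)) else NULL
  )
  if (is.na(layout$name)) layout$name <- ""
  list(layout = layout, report = layout_report("kgml", layout, warnings))
}
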