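#' Read an SBML model into a model digest
#'
#' Supports SBML Level 2 and 3. The digest keeps what layout generation and
#' mapping need: reactions with reversibility and stoichiometric participant
#' lists, metabolites with compartments, pathway groupings, and a gene
#' count. Pathways are harvested from the SBML groups package when present,
#' otherwise from `SUBSYSTEM:` lines in reaction notes. Genes are counted
#' from `fbc` gene products or, failing that, from `GENE_ASSOCIATION` note
#' lines.
#'
#' @param stream File path or literal XML text.
#' @return A list with `$model` (a `model_digest`) and `$report`.
#' @export
read_sbml_model <- function(stream) {
  doc <- read_xml_input(stream)
  level <- xml_attr(xml_find_first(doc, "/*"), "level")
  xml_ns_strip(doc)
  model_node <- xml_find_first(doc, "//model")
  if (inherits(model_node, "xml_missing")) stop_parse("no <model> element in SBML input")
  warnings <- character()
  rev_default <- !identical(level, "3")  # L2 reactions default to reversible

  species <- xml_find_all(doc, "//listOfSpecies/species")
  metabolites <- tibble(
    id = map_chr(species, ~ xml_attr(.x, "id")),
    name = map_chr(species, ~ xml_attr(.x, "name") %||% NA_character_),
    compartment = map_chr(species, ~ xml_attr(.x, "compartment") %||% NA_character_)
  )
  metabolites$name[is.na(metabolites$name)] <- metabolites$id[is.na(metabolites$name)]

  # each text node of a reaction's <notes> as its own line
  note_lines <- function(rxn) {
    n <- xml_find_first(rxn, "./notes")
    if (inherits(n, "xml_missing")) return(character())
    xml_text(xml_find_all(n, ".//text()"))
  }

  participants <- function(rxn, which) {
    refs <- xml_find_all(rxn, sprintf("./%s/speciesReference", which))
    sp <- map_chr(refs, ~ xml_attr(.x, "species"))
    st <- map_dbl(refs, ~ {
      s <- num_or_na(xml_attr(.x, "stoichiometry"))
      if (is.na(s)) 1 else s
    })
    list(species = sp, stoich = st)
  }

  rxn_nodes <- xml_find_all(doc, "//listOfReactions/reaction")
  rows <- list(); path_rows <- list()
  for (rxn in rxn_nodes) {
    id <- xml_attr(rxn, "id")
    subs <- participants(rxn, "listOfReactants")
    prods <- participants(rxn, "listOfProducts")
    bad <- setdiff(c(subs$species, prods$species), metabolites$id)
    if (length(bad)) {
      warnings <- c(warnings, sprintf(
        "reaction '%s' references undeclared species %s", id, paste(bad, collapse = ", ")))
    }
    rev_attr <- xml_attr(rxn, "reversible")
    rows[[length(rows) + 1]] <- tibble(
      id = id,
      name = xml_attr(rxn, "name") %||% id,
      reversible = if (is.na(rev_attr)) rev_default else identical(rev_attr, "true"),
      substrates = list(subs$species), sub_stoich = list(subs$stoich),
      products = list(prods$species), prod_stoich = list(prods$stoich)
    )
    for (txt in note_lines(rxn)) {
      m <- regmatches(txt, regexpr("SUBSYSTEM:\\s*\\S[^\n]*", txt))
      if (length(m)) {
        path_rows[[length(path_rows) + 1]] <- tibble(
          pathway = trimws(sub("SUBSYSTEM:\\s*", "", m)), reaction_id = id)
      }
    }
  }
  reactions <- if (length(rows)) bind_rows(rows) else tibble(
    id = character(), name = character(), reversible = logical(),
    substrates = list(), sub_stoich = list(), products = list(), prod_stoich = list())
  reactions$name[is.na(reactions$name)] <- reactions$id[is.na(reactions$name)]

  # groups package (element names survive namespace stripping)
  for (grp in xml_find_all(doc, "//group")) {
    gname <- xml_attr(grp, "name") %||% xml_attr(grp, "id")
    members <- map_chr(xml_find_all(grp, ".//member"), ~ xml_attr(.x, "idRef"))
    members <- members[members %in% reactions$id]
    if (length(members)) {
      path_rows[[length(path_rows) + 1]] <- tibble(pathway = gname, reaction_id = members)
    }
  }
  pathways <- if (length(path_rows)) distinct(bind_rows(path_rows)) else
    tibble(pathway = character(), reaction_id = character())

  gene_ids <- map_chr(xml_find_all(doc, "//listOfGeneProducts/geneProduct"),
                      ~ xml_attr(.x, "id"))
  if (!length(gene_ids)) {
    notes_txt <- unlist(lapply(rxn_nodes, note_lines))
    ga <- regmatches(notes_txt, regexpr("GENE[_ ]ASSOCIATION:\\s*[^\n]+", notes_txt))
    toks <- unlist(strsplit(gsub("GENE[_ ]ASSOCIATION:\\s*", "", ga), "[()[:space:]]+"))
    gene_ids <- setdiff(unique(toks[nzchar(toks)]), c("and", "or", "AND", "OR"))
  }

  model <- model_digest(
    id = xml_attr(model_node, "id") %||% "",
    name = xml_attr(model_node, "name") %||% "",
    reactions = reactions, metabolites = metabolites, pathways = pathways,
    n_genes = length(unique(gene_ids))
  )
  report <- format_report("sbml_model", warnings,
                          nodes = nrow(metabolites), edges = 0,
                          reactions = nrow(reactions))
  list(model = model, report = report)
}

#' Construct a model digest
#'
#' The in-memory summary of a genome-scale metabolic model used by layout
#' generation and mapping. Normally produced by [read_sbml_model()]; exposed
#' so toy models can be built programmatically.
#'
#' @param id,name Model identifier and display name.
#' @param reactions Tibble with columns `id`, `name`, `reversible`,
#'   `substrates`, `sub_stoich`, `products`, `prod_stoich` (the last four are
#'   list columns).
#' @param metabolites Tibble with columns `id`, `name`, `compartment`.
#' @param pathways Tibble with columns `pathway`, `reaction_id`.
#' @param n_genes Number of distinct genes in the model.
#' @return A `model_digest`.
#' @export
model_digest <- function(id = "", name = "", reactions, metabolites,
                         pathways = NULL, n_genes = 0) {
  pathways <- pathways %||% tibble(pathway = character(), reaction_id = character())
  structure(
    list(id = id, name = name, reactions = as_tibble(reactions),
         metabolites = as_tibble(metabolites), pathways = as_tibble(pathways),
         n_genes = as.integer(n_genes)),
    class = "model_digest"
  )
}

#' @export
print.model_digest <- function(x, ...) {
  cat(sprintf("<model_digest '%s': %d reactions, %d metabolites, %d genes, %d pathway(s)>\n",
              if (nzchar(x$id)) x$id else x$name, nrow(x$reactions),
              nrow(x$metabolites), x$n_genes, length(unique(x$pathways$pathway))))
  invisible(x)
}

#' Read a CellDesigner-annotated SBML layout
#'
#' Read-only. CellDesigner stores drawing information in `celldesigner`
#' extension annotations: each species alias becomes one metabolite node at
#' the alias bounds centre (so duplicated aliases of one species become
#' replicas sharing model ids), reactions become reaction nodes with
#' reversibility from the SBML flag, and participant edges are resolved
#' through the reaction's base reactant/product alias references when
#' present, falling back to the species' first alias. Plain SBML without a
#' CellDesigner annotation falls back to [read_sbml_model()] +
#' [generate_pathway_layout()] with a warning.
#'
#' @param stream File path or literal XML text.
#' @return A list with `$layout` and `$report`.
#' @export
read_cd_sbml <- function(stream) {
  raw <- if (length(stream) == 1 && file.exists(stream))
    paste(readLines(stream, warn = FALSE), collapse = "\n") else stream
  doc <- read_xml_input(raw)
  has_cd <- grepl("celldesigner", paste(unlist(xml2::xml_ns(doc)), collapse = " "),
                  fixed = TRUE)
  if (!has_cd) {
    sb <- read_sbml_model(raw)
    layout <- generate_pathway_layout(sb$model, reactions = sb$model$reactions$id)
    layout$name <- if (nzchar(sb$model$id)) sb$model$id else "cd_sbml"
    rep <- layout_report("cd_sbml", layout, c(
      sb$report$warnings,
      "no CellDesigner annotation found; fell back to plain SBML + layout generation"))
    return(list(layout = layout, report = rep))
  }
  xml_ns_strip(doc)
  warnings <- character()

  sp_nodes <- xml_find_all(doc, "//listOfSpecies/species")
  sp_name <- stats::setNames(
    map_chr(sp_nodes, ~ xml_attr(.x, "name") %||% xml_attr(.x, "id")),
    map_chr(sp_nodes, ~ xml_attr(.x, "id")))
  sp_name[is.na(sp_name)] <- names(sp_name)[is.na(sp_name)]

  mets <- list()
  alias_species <- character()
  for (al in xml_find_all(doc, "//*[local-name()='speciesAlias']")) {
    aid <- xml_attr(al, "id")
    sid <- xml_attr(al, "species")
    b <- xml_find_first(al, "./*[local-name()='bounds']")
    x <- num_or_na(xml_attr(b, "x")); y <- num_or_na(xml_attr(b, "y"))
    w <- num_or_na(xml_attr(b, "w")); h <- num_or_na(xml_attr(b, "h"))
    alias_species[aid] <- sid
    lbl <- unname(sp_name[sid])
    if (length(lbl) != 1 || is.na(lbl)) lbl <- sid
    mets[[length(mets) + 1]] <- tibble(
      id = aid, label = lbl, model_ids = list(sid),
      kind = "regular",
      x = if (is.na(x)) NA_real_ else x + (if (is.na(w)) 0 else w / 2),
      y = if (is.na(y)) NA_real_ else y + (if (is.na(h)) 0 else h / 2),
      fixed = !is.na(x) && !is.na(y))
  }

  rxns <- list(); edges <- list()
  for (rxn in xml_find_all(doc, "//listOfReactions/reaction")) {
    rid <- xml_attr(rxn, "id")
    rev_attr <- xml_attr(rxn, "reversible")
    rxns[[length(rxns) + 1]] <- tibble(
      id = rid, label = xml_attr(rxn, "name") %||% rid, model_ids = list(rid),
      reversible = if (is.na(rev_attr)) TRUE else identical(rev_attr, "true"),
      x = NA_real_, y = NA_real_, fixed = FALSE)
    base_alias <- function(which) {
      refs <- xml_find_all(rxn, sprintf(".//*[local-name()='%s']", which))
      stats::setNames(map_chr(refs, ~ xml_attr(.x, "alias") %||% NA_character_),
                      map_chr(refs, ~ xml_attr(.x, "species")))
    }
    pref <- list(substrate = base_alias("baseReactant"),
                 product = base_alias("baseProduct"))
    for (spec in list(c("listOfReactants", "substrate"), c("listOfProducts", "product"))) {
      for (ref in xml_find_all(rxn, sprintf("./%s/speciesReference", spec[1]))) {
        sid <- xml_attr(ref, "species")
        aid <- pref[[spec[2]]][sid]
        if (is.null(aid) || is.na(aid)) {
          cand <- names(alias_species)[alias_species == sid]
          aid <- if (length(cand)) cand[1] else NA_character_
        }
        if (is.na(aid)) {
          warnings <- c(warnings, sprintf(
            "species '%s' in reaction '%s' has no alias; participant skipped", sid, rid))
          next
        }
        edges[[length(edges) + 1]] <- tibble(
          reaction_id = rid, metabolite_id = aid, role = spec[2])
      }
    }
  }

  layout <- metabolic_layout(
    name = xml_attr(xml_find_first(doc, "//model"), "id") %||% "cd_sbml",
    metabolites = if (length(mets)) bind_rows(mets) else NULL,
    reactions = if (length(rxns)) bind_rows(rxns) else NULL,
    edges = if (length(edges)) distinct(bind_rows(edges)) else NULL
  )
  if (is.na(layout$name)) layout$name <- "cd_sbml"
  list(layout = layout, report = layout_report("cd_sbml", layout, warnings))
}
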