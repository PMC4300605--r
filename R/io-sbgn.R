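#' Read and write SBGN-ML Process Description maps
#'
#' Only the Process Description (PD) language is supported — the
#' state-transition notation that fits metabolism. The mapping is: process
#' glyphs become reaction nodes; simple chemical glyphs become metabolite
#' nodes (a clone marker means currency); consumption arcs become substrate
#' edges and production arcs product edges. Reversible reactions are written
#' in the PD convention of production arcs on both sides, attached to the
#' process's two ports; on read, the port an arc touches decides the side
#' (port 1 substrates, port 2 products). Glyph bounding-box centres become
#' positions and positioned nodes are created fixed. Model identifier lists
#' — which plain SBGN does not model — travel in an `<extension>` element so
#' the round trip is lossless; info annotations are written as `annotation`
#' glyphs. Unsupported glyph classes (e.g. macromolecules) are skipped with
#' a warning; ER/AF maps raise an unsupported-language error.
#'
#' @param stream File path or literal XML text.
#' @return For `read_sbgnml_pd()`, a list with `$layout` and `$report`; for
#'   `write_sbgnml_pd()`, the path (or XML text when `path = NULL`)
#'   invisibly.
#' @export
read_sbgnml_pd <- function(stream) {
  doc <- read_xml_input(stream)
  xml_ns_strip(doc)
  map <- xml_find_first(doc, "//map")
  if (inherits(map, "xml_missing")) stop_parse("no <map> element in SBGN-ML input")
  lang <- xml_attr(map, "language")
  if (!is.na(lang) && !identical(lang, "process description")) {
    stop_unsupported(sprintf("SBGN language '%s' is not supported (only process description)", lang))
  }
  warnings <- character()

  glyph_ext <- function(glyph, name) {
    e <- xml_find_first(glyph, sprintf("./extension/%s", name))
    if (inherits(e, "xml_missing")) NA_character_ else xml_text(e)
  }
  bbox_center <- function(glyph) {
    b <- xml_find_first(glyph, "./bbox")
    if (inherits(b, "xml_missing")) return(c(NA_real_, NA_real_))
    x <- num_or_na(xml_attr(b, "x")); y <- num_or_na(xml_attr(b, "y"))
    w <- num_or_na(xml_attr(b, "w")); h <- num_or_na(xml_attr(b, "h"))
    c(x + w / 2, y + h / 2)
  }
  glyph_label <- function(glyph, default) {
    l <- xml_find_first(glyph, "./label")
    if (inherits(l, "xml_missing")) default else (xml_attr(l, "text") %||% default)
  }
  split_ids <- function(s) {
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, ",", fixed = TRUE)[[1]]
  }

  mets <- list(); rxns <- list(); infos <- list()
  port_owner <- character()  # port id -> glyph id
  port_rank <- integer()     # port id -> 1 (substrate side) or 2 (product side)
  for (glyph in xml_find_all(map, "./glyph")) {
    cls <- xml_attr(glyph, "class")
    id <- xml_attr(glyph, "id")
    ctr <- bbox_center(glyph)
    if (identical(cls, "process")) {
      ports <- xml_find_all(glyph, "./port")
      for (k in seq_along(ports)) {
        pid <- xml_attr(ports[[k]], "id")
        port_owner[pid] <- id
        port_rank[pid] <- k
      }
      rxns[[length(rxns) + 1]] <- tibble(
        id = id, label = glyph_label(glyph, id),
        model_ids = list(split_ids(glyph_ext(glyph, "modelIds"))),
        reversible = identical(glyph_ext(glyph, "reversible"), "true"),
        x = ctr[1], y = ctr[2], fixed = !is.na(ctr[1]))
    } else if (identical(cls, "simple chemical")) {
      currency <- !inherits(xml_find_first(glyph, "./clone"), "xml_missing")
      mets[[length(mets) + 1]] <- tibble(
        id = id, label = glyph_label(glyph, id),
        model_ids = list(split_ids(glyph_ext(glyph, "modelIds"))),
        kind = if (currency) "currency" else "regular",
        x = ctr[1], y = ctr[2], fixed = !is.na(ctr[1]))
    } else if (identical(cls, "annotation")) {
      infos[[length(infos) + 1]] <- tibble(
        id = id, text = glyph_label(glyph, ""),
        reaction_id = glyph_ext(glyph, "infoFor"))
    } else {
      warnings <- c(warnings, sprintf("glyph '%s' of class '%s' skipped", id, cls))
    }
  }
  rxn_ids <- if (length(rxns)) map_chr(rxns, ~ .x$id) else character()

  resolve <- function(ref) {
    # an arc endpoint is either a glyph id or a port id
    if (ref %in% names(port_owner)) {
      list(glyph = port_owner[[ref]], rank = port_rank[[ref]])
    } else {
      list(glyph = ref, rank = NA_integer_)
    }
  }
  edges <- list()
  for (arc in xml_find_all(map, "./arc")) {
    cls <- xml_attr(arc, "class")
    if (!cls %in% c("consumption", "production")) {
      warnings <- c(warnings, sprintf("arc of class '%s' skipped", cls))
      next
    }
    s <- resolve(xml_attr(arc, "source"))
    t <- resolve(xml_attr(arc, "target"))
    if (s$glyph %in% rxn_ids) { proc <- s; met <- t } else { proc <- t; met <- s }
    role <- if (!is.na(proc$rank)) {
      if (proc$rank == 1) "substrate" else "product"
    } else if (cls == "consumption") "substrate" else "product"
    edges[[length(edges) + 1]] <- tibble(
      reaction_id = proc$glyph, metabolite_id = met$glyph, role = role)
  }

  layout <- metabolic_layout(
    name = xml_attr(map, "id") %||% "",
    metabolites = if (length(mets)) bind_rows(mets) else NULL,
    reactions = if (length(rxns)) bind_rows(rxns) else NULL,
    edges = if (length(edges)) bind_rows(edges) else NULL,
    info_nodes = if (length(infos)) bind_rows(infos) else NULL
  )
  if (is.na(layout$name)) layout$name <- ""
  list(layout = layout, report = layout_report("sbgnml_pd", layout, warnings))
}

#' @rdname read_sbgnml_pd
#' @param layout A `metabolic_layout`. Positionless nodes are written with a
#'   bounding box at the origin.
#' @param path Output file path, or `NULL` to return the XML text.
#' @export
write_sbgnml_pd <- function(layout, path = NULL) {
  doc <- xml_new_root("sbgn", xmlns = "http://sbgn.org/libsbgn/0.2")
  map <- xml_add_child(doc, "map", language = "process description",
                       id = if (nzchar(layout$name)) layout$name else "map1")
  add_bbox <- function(node, x, y, w, h) {
    if (is.na(x) || is.na(y)) { x <- 0; y <- 0 }
    xml_add_child(node, "bbox", x = fmt_num(x - w / 2), y = fmt_num(y - h / 2),
                  w = fmt_num(w), h = fmt_num(h))
  }
  add_ext <- function(node, ...) {
    vals <- list(...)
    ext <- xml_add_child(node, "extension")
    for (nm in names(vals)) {
      child <- xml_add_child(ext, nm)
      xml2::xml_set_text(child, vals[[nm]])
    }
  }
  m <- layout$metabolites
  for (i in seq_len(nrow(m))) {
    g <- xml_add_child(map, "glyph", id = m$id[i], class = "simple chemical")
    xml_add_child(g, "label", text = m$label[i])
    if (m$kind[i] == "currency") xml_add_child(g, "clone")
    add_bbox(g, m$x[i], m$y[i], 40, 20)
    add_ext(g, modelIds = paste(m$model_ids[[i]], collapse = ","))
  }
  r <- layout$reactions
  for (i in seq_len(nrow(r))) {
    g <- xml_add_child(map, "glyph", id = r$id[i], class = "process")
    xml_add_child(g, "label", text = r$label[i])
    add_bbox(g, r$x[i], r$y[i], 20, 20)
    x <- if (is.na(r$x[i])) 0 else r$x[i]
    y <- if (is.na(r$y[i])) 0 else r$y[i]
    xml_add_child(g, "port", id = paste0(r$id[i], ".1"), x = fmt_num(x - 15), y = fmt_num(y))
    xml_add_child(g, "port", id = paste0(r$id[i], ".2"), x = fmt_num(x + 15), y = fmt_num(y))
    add_ext(g, modelIds = paste(r$model_ids[[i]], collapse = ","),
            reversible = if (isTRUE(r$reversible[i])) "true" else "false")
  }
  n <- layout$info_nodes
  for (i in seq_len(nrow(n))) {
    g <- xml_add_child(map, "glyph", id = n$id[i], class = "annotation")
    xml_add_child(g, "label", text = n$text[i])
    add_bbox(g, NA, NA, 30, 12)
    add_ext(g, infoFor = n$reaction_id[i])
  }
  e <- layout$edges
  rev_lookup <- stats::setNames(layout$reactions$reversible, layout$reactions$id)
  for (i in seq_len(nrow(e))) {
    reversible <- isTRUE(rev_lookup[[e$reaction_id[i]]])
    port <- paste0(e$reaction_id[i], ".", if (e$role[i] == "substrate") 1 else 2)
    if (e$role[i] == "substrate" && !reversible) {
      arc <- xml_add_child(map, "arc", id = sprintf("arc%d", i), class = "consumption",
                           source = e$metabolite_id[i], target = port)
    } else {
      # product arcs always, and substrate-side production arcs when reversible
      arc <- xml_add_child(map, "arc", id = sprintf("arc%d", i), class = "production",
                           source = port, target = e$metabolite_id[i])
    }
    xml_add_child(arc, "start", x = "0", y = "0")
    xml_add_child(arc, "end", x = "0", y = "0")
  }
  if (is.null(path)) return(invisible(as.character(doc)))
  write_xml(doc, path)
  invisible(path)
}
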