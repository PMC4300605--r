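#' Read a COBRA/BiGG map file
#'
#' Best-effort, read-only support for tab-delimited pathway map text in the
#' style of the maps distributed with the COBRA Toolbox for BiGG models.
#' Because that family of files comes in several undocumented dialect
#' versions, the reader targets a documented record layout (`v1`) and
#' degrades gracefully: the first non-comment line must be the header
#' `type<TAB>id<TAB>name<TAB>x<TAB>y<TAB>attr`, then one record per line:
#'
#' * `metabolite<TAB>id<TAB>name<TAB>x<TAB>y<TAB>[regular|currency]`
#' * `reaction<TAB>id<TAB>name<TAB>x<TAB>y<TAB>[true|false]` (reversibility)
#' * `edge<TAB>reaction_id<TAB>metabolite_id<TAB>substrate|product` (x/y unused)
#'
#' All positioned nodes are created fixed. A record with a non-numeric
#' coordinate yields a warning and an unfixed node; unparseable records are
#' collected as warnings; an unrecognizable header (or an empty file) is a
#' format error.
#'
#' @param path Path to the map file, or a character vector of lines.
#' @return A list with `$layout` and `$report`.
#' @export
read_cobra_map <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop_format("empty COBRA map file")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 5 || tolower(header[1]) != "type" || tolower(header[2]) != "id") {
    stop_format("unrecognizable COBRA map header; expected 'type\tid\tname\tx\ty\tattr'")
  }
  warnings <- character()
  mets <- list(); rxns <- list(); edges <- list()
  for (i in seq_along(lines)[-1]) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    kind <- tolower(f[1])
    if (kind == "edge") {
      if (length(f) < 4 || !tolower(f[4]) %in% c("substrate", "product")) {
        warnings <- c(warnings, sprintf("line %d: unparseable edge record", i))
        next
      }
      edges[[length(edges) + 1]] <- tibble(
        reaction_id = f[2], metabolite_id = f[3], role = tolower(f[4]))
      next
    }
    if (!kind %in% c("metabolite", "reaction") || length(f) < 5) {
      warnings <- c(warnings, sprintf("line %d: unparseable record '%s'", i, lines[i]))
      next
    }
    x <- num_or_na(f[4]); y <- num_or_na(f[5])
    fixed <- !is.na(x) && !is.na(y)
    if (!fixed) {
      warnings <- c(warnings, sprintf("line %d: non-numeric coordinate; node '%s' left unfixed", i, f[2]))
      x <- NA_real_; y <- NA_real_
    }
    attr6 <- if (length(f) >= 6) tolower(f[6]) else ""
    if (kind == "metabolite") {
      mets[[length(mets) + 1]] <- tibble(
        id = f[2], label = f[3], model_ids = list(f[2]),
        kind = if (identical(attr6, "currency")) "currency" else "regular",
        x = x, y = y, fixed = fixed)
    } else {
      rxns[[length(rxns) + 1]] <- tibble(
        id = f[2], label = f[3], model_ids = list(f[2]),
        reversible = identical(attr6, "true"),
        x = x, y = y, fixed = fixed)
    }
  }
  layout <- metabolic_layout(
    name = "cobra_map",
    metabolites = if (length(mets)) bind_rows(mets) else NULL,
    reactions = if (length(rxns)) bind_rows(rxns) else NULL,
    edges = if (length(edges)) distinct(bind_rows(edges)) else NULL
  )
  list(layout = layout, report = layout_report("cobra_map", layout, warnings))
}
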