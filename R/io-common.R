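#' @importFrom xml2 read_xml xml_find_all xml_find_first xml_attr xml_text
#'   xml_name xml_ns_strip xml_add_child xml_new_root xml_set_attr write_xml
NULL

# A format report accompanies every reader/writer call: which dialect was
# used, non-fatal warnings, and the object counts actually constructed.
format_report <- function(format, warnings = character(), nodes = 0, edges = 0,
                          reactions = 0) {
  structure(
    list(format = format, warnings = as.character(warnings),
         counts = list(nodes = nodes, edges = edges, reactions = reactions)),
    class = "format_report"
  )
}

#' @export
print.format_report <- function(x, ...) {
  cat(sprintf("<format_report %s: %d nodes, %d edges, %d reactions, %d warning(s)>\n",
              x$format, x$counts$nodes, x$counts$edges, x$counts$reactions,
              length(x$warnings)))
  for (w in x$warnings) cat(" - ", w, "\n", sep = "")
  invisible(x)
}

layout_report <- function(format, layout, warnings = character()) {
  format_report(format, warnings,
                nodes = nrow(layout$metabolites) + nrow(layout$reactions) +
                  nrow(layout$info_nodes),
                edges = nrow(layout$edges),
                reactions = nrow(layout$reactions))
}

# Accept a file path or literal XML text.
read_xml_input <- function(stream) {
  doc <- tryCatch(read_xml(stream), error = function(e) {
    stop_parse(sprintf("malformed XML: %s", conditionMessage(e)))
  })
  doc
}

num_or_na <- function(x) suppressWarnings(as.double(x))

# Serialize a double so that reading it back is value-exact.
fmt_num <- function(x) sprintf("%.17g", x)
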