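positioned_toy <- function(reversible_r2 = TRUE) {
  lay <- metabolic_layout(
    name = "render_toy",
    reactions = data.frame(id = c("R1", "R2"),
                           reversible = c(FALSE, reversible_r2),
                           x = c(100, 200), y = c(50, 50), fixed = TRUE),
    metabolites = data.frame(id = c("M0", "M1", "M2"),
                             x = c(50, 150, 250), y = c(50, 50, 50), fixed = TRUE),
    edges = data.frame(reaction_id = c("R1", "R1", "R2", "R2"),
                       metabolite_id = c("M0", "M1", "M1", "M2"),
                       role = c("substrate", "product", "substrate", "product")))
  lay
}

count_matches <- function(pattern, text) {
  m <- gregexpr(pattern, text)[[1]]
  if (m[1] == -1) 0L else length(m)
}

test_that("SVG output is well-formed XML with one shape per node and line per edge", {
  lay <- positioned_toy()
  svg <- render_svg(lay)
  doc <- xml2::read_xml(svg)  # parses or dies
  expect_identical(xml2::xml_name(doc), "svg")
  expect_identical(count_matches("<rect class=\"reaction\"", svg), 2L)
  expect_identical(count_matches("<circle class=\"metabolite\"", svg), 3L)
  expect_identical(count_matches("<line class=\"edge\"", svg), 4L)
})

test_that("arrowheads follow reversibility: products only, or both metabolite ends", {
  # irreversible 1-substrate/1-product reaction: exactly one arrowed edge end
  lay1 <- metabolic_layout(
    reactions = data.frame(id = "R", reversible = FALSE, x = 0, y = 0, fixed = TRUE),
    metabolites = data.frame(id = c("S", "P"), x = c(-50, 50), y = 0, fixed = TRUE),
    edges = data.frame(reaction_id = "R", metabolite_id = c("S", "P"),
                       role = c("substrate", "product")))
  expect_identical(count_matches("marker-end", render_svg(lay1)), 1L)
  lay1$reactions$reversible <- TRUE
  expect_identical(count_matches("marker-end", render_svg(lay1)), 2L)
  # mixed layout: product edges of irreversible + all edges of reversible
  lay <- positioned_toy(reversible_r2 = TRUE)
  expect_identical(count_matches("marker-end", render_svg(lay)), 3L)
})

test_that("filters hide nodes, their edges and their ids from the output", {
  lay <- positioned_toy()
  ov <- new_overlay(filters = list(visibility_filter("hide_R2", "R2")))
  svg <- render_svg(lay, ov, active_filters = list("hide_R2"))
  expect_false(grepl("R2", svg))
  expect_identical(count_matches("<line class=\"edge\"", svg), 2L)
  # orphaned metabolite M2 still drawn (only named filters hide nodes)
  expect_true(grepl("\"M2\"", svg))
  # unknown filter names are an error
  expect_error(render_svg(lay, ov, active_filters = list("nope")),
               class = "fluxmapr_not_found_error")
})

test_that("overlay widths, colours, glyphs and label suffixes reach the SVG", {
  lay <- positioned_toy()
  mp <- build_mapping(lay, c("R1", "R2"))
  ov <- flux_overlay(lay, mp, flux_distribution(c(R1 = 5, R2 = 2.5)))
  svg <- render_svg(lay, ov)
  expect_true(grepl('stroke-width="8.000"', svg))
  expect_true(grepl('stroke-width="4.500"', svg))
  expect_true(grepl("R1 5.000", svg))
  gov <- genetic_overlay(lay, mp, genetic_conditions(knockouts = "R1",
                                                     over_expressed = "R2"))
  svg2 <- render_svg(lay, gov)
  expect_identical(count_matches("knockout_cross", svg2), 1L)
  expect_identical(count_matches("up_arrow", svg2), 1L)
  expect_true(grepl("#CC0000", svg2))
})

test_that("rendering demands positions and names the offending node", {
  lay <- positioned_toy()
  lay$metabolites$x[2] <- NA
  err <- tryCatch(render_svg(lay), condition = identity)
  expect_s3_class(err, "fluxmapr_render_error")
  expect_match(conditionMessage(err), "M1")
})

test_that("rendered output is deterministic", {
  sc <- make_toy_scenario(6, seed = 4)
  lay <- run_fdl(sc$layout, fdl_params(iterations = 120))
  ov <- flux_overlay(lay, sc$mapping, sc$wild_flux)
  expect_identical(render_svg(lay, ov), render_svg(lay, ov))
})

test_that("PDF conversion works when a converter exists, else raises the classed error", {
  svg <- render_svg(positioned_toy())
  if (is.na(fluxmapr:::pdf_converter())) {
    expect_error(svg_to_pdf(svg), class = "fluxmapr_unsupported_error")
  } else {
    bytes <- svg_to_pdf(svg)
    expect_identical(rawToChar(bytes[1:4]), "%PDF")
  }
  expect_error(svg_to_pdf("<svg><unclosed"), class = "fluxmapr_parse_error")
})
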