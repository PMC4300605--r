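style <- style_config()

flux_fixture <- function(values) {
  lay <- mapped_layout_for(names(values))
  mp <- build_mapping(lay, names(values))
  list(layout = lay, mapping = mp, flux = flux_distribution(values))
}

test_that("edge widths follow the linear max-normalization exactly", {
  fx <- flux_fixture(c(N1 = 10, N2 = 5, N3 = 0))
  ov <- flux_overlay(fx$layout, fx$mapping, fx$flux, style)
  w <- function(node) {
    rid <- fx$layout$reactions$id[vapply(fx$layout$reactions$model_ids,
                                         function(v) node %in% v, logical(1))]
    unique(ov$edge_style$width[ov$edge_style$reaction_id == rid])
  }
  expect_equal(w("N1"), 8, tolerance = 1e-12)
  expect_equal(w("N2"), 4.5, tolerance = 1e-12)
  expect_equal(w("N3"), 1, tolerance = 1e-12)
})

test_that("an empty flux distribution leaves default widths and no labels", {
  fx <- flux_fixture(c(N1 = 1))
  ov <- flux_overlay(fx$layout, fx$mapping,
                     flux_distribution(stats::setNames(numeric(), character())), style)
  expect_true(all(ov$edge_style$width == style$min_width))
  expect_identical(nrow(ov$label_suffix), 0L)
})

test_that("negative fluxes rank by magnitude and keep their sign in labels", {
  fx <- flux_fixture(c(N1 = -6, N2 = 3))
  ov <- flux_overlay(fx$layout, fx$mapping, fx$flux, style)
  n1 <- fx$layout$reactions$id[vapply(fx$layout$reactions$model_ids,
                                      function(v) "N1" %in% v, logical(1))]
  expect_equal(max(ov$edge_style$width), 8)
  expect_true(all(ov$edge_style$width[ov$edge_style$reaction_id == n1] == 8))
  expect_identical(ov$label_suffix$suffix[ov$label_suffix$reaction_id == n1], "-6.000")
})

test_that("width bounds and max attainment hold for random fluxes; scaling is invariant", {
  for (seed in 1:6) {
    set.seed(seed)
    vals <- stats::setNames(stats::rnorm(5) * 10^seed, paste0("N", 1:5))
    fx <- flux_fixture(vals)
    ov <- flux_overlay(fx$layout, fx$mapping, fx$flux, style)
    expect_true(all(ov$edge_style$width >= style$min_width - 1e-12))
    expect_true(all(ov$edge_style$width <= style$max_width + 1e-12))
    expect_equal(max(ov$edge_style$width), style$max_width, tolerance = 1e-12)
    ov2 <- flux_overlay(fx$layout, fx$mapping, flux_distribution(vals * 3.7), style)
    expect_equal(ov$edge_style$width, ov2$edge_style$width, tolerance = 1e-12)
  }
})

test_that("genetic conditions draw the right glyphs and recolour incident edges", {
  lay <- mapped_layout_for(c("R1", "R2", "R3"))
  mp <- build_mapping(lay, c("R1", "R2", "R3"))
  ov <- genetic_overlay(lay, mp,
                        genetic_conditions(knockouts = "R3", over_expressed = "R1",
                                           under_expressed = "R2"),
                        style)
  g <- ov$node_glyph
  expect_identical(g$glyph[g$reaction_id == "N1"], "up_arrow")
  expect_identical(g$color[g$reaction_id == "N1"], style$over_color)
  expect_identical(g$glyph[g$reaction_id == "N2"], "down_arrow")
  expect_identical(g$color[g$reaction_id == "N2"], style$under_color)
  expect_identical(g$glyph[g$reaction_id == "N3"], "knockout_cross")
  expect_true(all(ov$edge_style$color[ov$edge_style$reaction_id == "N3"] ==
                    style$knockout_color))
  # only mapped condition nodes are touched
  expect_identical(nrow(g), 3L)
  empty <- genetic_overlay(lay, mp, genetic_conditions(), style)
  expect_identical(nrow(empty$node_glyph), 0L)
  expect_identical(nrow(empty$edge_style), 0L)
})

test_that("unmapped condition ids go to diagnostics and sets must be disjoint", {
  lay <- mapped_layout_for("R1")
  mp <- build_mapping(lay, "R1")
  ov <- genetic_overlay(lay, mp, genetic_conditions(knockouts = c("R1", "R_missing")), style)
  expect_identical(ov$diagnostics, "R_missing")
  expect_identical(nrow(ov$node_glyph), 1L)
  expect_error(genetic_conditions(knockouts = "R1", over_expressed = "R1"),
               class = "fluxmapr_argument_error")
})

comparison_fixture <- function(va, vb, reversible = FALSE) {
  ids <- union(names(va), names(vb))
  lay <- mapped_layout_for(ids)
  lay$reactions$reversible <- reversible
  mp <- build_mapping(lay, ids)
  list(layout = lay, mapping = mp,
       fa = flux_distribution(va), fb = flux_distribution(vb))
}

test_that("the comparison gradient is black iff fluxes are equal and nonzero, pure at exclusives", {
  fx <- comparison_fixture(c(E = 3, A = 5, H = 6), c(E = 3, B = 4, H = 3))
  ov <- comparison_overlay(fx$layout, fx$mapping, fx$fa, fx$fb, style)
  col <- function(model_id) {
    nid <- fx$layout$reactions$id[vapply(fx$layout$reactions$model_ids,
                                         function(v) model_id %in% v, logical(1))]
    unique(ov$edge_style$color[ov$edge_style$reaction_id == nid])
  }
  expect_identical(col("E"), style$neutral_color)      # equal, nonzero -> black
  expect_identical(col("A"), style$sim1_color)         # only in A -> pure sim1
  expect_identical(col("B"), style$sim2_color)         # only in B -> pure sim2
  # d = 0.5 toward sim1: halfway blend of black and red
  expect_identical(col("H"), blend_color(style$neutral_color, style$sim1_color, 0.5))
})

test_that("comparison widths use the mean flux and the zero filters name each side", {
  fx <- comparison_fixture(c(X = 6, Y = 4), c(X = 3, Y = 4))
  ov <- comparison_overlay(fx$layout, fx$mapping, fx$fa, fx$fb, style)
  # means: X 4.5 (max), Y 4 -> widths 8 and 1 + 7*4/4.5
  wX <- unique(ov$edge_style$width[ov$edge_style$reaction_id == "N1"])
  wY <- unique(ov$edge_style$width[ov$edge_style$reaction_id == "N2"])
  expect_equal(wX, 8, tolerance = 1e-12)
  expect_equal(wY, 1 + 7 * 4 / 4.5, tolerance = 1e-12)
  fx2 <- comparison_fixture(c(P = 5, Q = 0), c(P = 0, Q = 2))
  ov2 <- comparison_overlay(fx2$layout, fx2$mapping, fx2$fa, fx2$fb, style)
  fa_hidden <- ov2$filters[[which(vapply(ov2$filters, function(f) f$name, "") == "hide_zero_in_A")]]
  fb_hidden <- ov2$filters[[which(vapply(ov2$filters, function(f) f$name, "") == "hide_zero_in_B")]]
  expect_true("N2" %in% fa_hidden$hidden)  # Q is zero in A
  expect_true("N1" %in% fb_hidden$hidden)  # P is zero in B
})

test_that("swapping simulations together with their colours leaves edge colours unchanged", {
  for (seed in 1:5) {
    set.seed(seed)
    ids <- paste0("R", 1:6)
    va <- stats::setNames(round(stats::rnorm(6), 2), ids)
    vb <- stats::setNames(round(stats::rnorm(6), 2), ids)
    vb[2] <- va[2]  # ensure an equal pair too
    fx <- comparison_fixture(va, vb)
    ov1 <- comparison_overlay(fx$layout, fx$mapping, fx$fa, fx$fb, style)
    swapped <- style_config(sim1_color = style$sim2_color, sim2_color = style$sim1_color)
    ov2 <- comparison_overlay(fx$layout, fx$mapping, fx$fb, fx$fa, swapped)
    expect_identical(ov1$edge_style$color, ov2$edge_style$color)
    expect_equal(ov1$edge_style$width, ov2$edge_style$width, tolerance = 1e-12)
  }
})

test_that("opposing directions on reversible reactions colour the arrowheads per simulation", {
  fx <- comparison_fixture(c(R = 4), c(R = -2), reversible = TRUE)
  ov <- comparison_overlay(fx$layout, fx$mapping, fx$fa, fx$fb, style)
  es <- ov$edge_style
  expect_identical(es$marker_color[es$role == "product"], style$sim1_color)
  expect_identical(es$marker_color[es$role == "substrate"], style$sim2_color)
  # irreversible: no direction colouring even with opposite signs
  fx2 <- comparison_fixture(c(R = 4), c(R = -2), reversible = FALSE)
  ov2 <- comparison_overlay(fx2$layout, fx2$mapping, fx2$fa, fx2$fb, style)
  expect_true(all(is.na(ov2$edge_style$marker_color)))
})

test_that("EFM overlays change widths and labels only, and hide the zero-flux remainder", {
  lay <- mapped_layout_for(paste0("R", 1:5))
  mp <- build_mapping(lay, paste0("R", 1:5))
  efm <- flux_distribution(c(R1 = 1, R3 = 2, R5 = 1))
  ov <- efm_overlay(lay, mp, efm, style)
  expect_identical(nrow(ov$node_glyph), 0L)
  expect_true(all(is.na(ov$edge_style$color)))
  expect_identical(length(ov$filters), 1L)
  hidden <- ov$filters[[1]]$hidden
  expect_true(all(c("N2", "N4") %in% hidden))             # zero-flux reactions
  expect_true(all(c("A2", "B2", "A4", "B4") %in% hidden)) # orphaned neighbours
  expect_false(any(c("N1", "N3", "N5") %in% hidden))
  # all-zero EFM hides every reaction
  ov0 <- efm_overlay(lay, mp, flux_distribution(c(R1 = 0)), style)
  expect_true(all(lay$reactions$id %in% ov0$filters[[1]]$hidden))
  # single active reaction attains max width
  ov1 <- efm_overlay(lay, mp, flux_distribution(c(R2 = 1)), style)
  expect_equal(max(ov1$edge_style$width[ov1$edge_style$reaction_id == "N2"]), 8)
})
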