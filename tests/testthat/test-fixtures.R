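test_that("toy scenarios are pure functions of their arguments", {
  a <- make_toy_scenario(5, 0.4, 0.4, seed = 1)
  b <- make_toy_scenario(5, 0.4, 0.4, seed = 1)
  expect_identical(a, b)
  c <- make_toy_scenario(5, 0.4, 0.4, seed = 2)
  expect_false(identical(a$layout, c$layout))
})

test_that("rate parameters act as documented at their extremes", {
  none <- make_toy_scenario(6, branching = 0, currency_rate = 0, seed = 3)
  expect_identical(sum(none$layout$metabolites$kind == "currency"), 0L)
  expect_identical(nrow(none$layout$reactions), 6L + 2L)  # chain + bypass
  all_cur <- make_toy_scenario(6, branching = 0, currency_rate = 1, seed = 3)
  expect_identical(sum(all_cur$layout$metabolites$kind == "currency"), 6L)
  expect_error(make_toy_scenario(0), class = "fluxmapr_argument_error")
  expect_error(make_toy_scenario(5, branching = 2), class = "fluxmapr_argument_error")
})

test_that("the truth record matches independent recomputation across seeds", {
  for (seed in 1:25) {
    sc <- make_toy_scenario(sample(3:10, 1), stats::runif(1), stats::runif(1),
                            seed = seed)
    expect_identical(nrow(validate_layout(sc$layout)), 0L)
    expect_identical(sc$truth$nodes,
                     nrow(sc$layout$metabolites) + nrow(sc$layout$reactions))
    expect_identical(sc$truth$edges, nrow(sc$layout$edges))
    expect_identical(sc$truth$currency_replicas,
                     sum(sc$layout$metabolites$kind == "currency"))
    expect_identical(sc$truth$nonzero_wild_fluxes,
                     sum(sc$wild_flux$value != 0))
    # mapping resolves every model id with nothing left over
    expect_identical(length(sc$mapping$unmatched_model_ids), 0L)
  }
})

test_that("toy fluxes are conserved along the active path", {
  for (seed in c(2, 5, 8)) {
    sc <- make_toy_scenario(7, 0.5, 0.5, seed = seed)
    for (flux in list(sc$wild_flux, sc$mutant_flux)) {
      vals <- stats::setNames(flux$value, flux$reaction_id)
      # each internal chain metabolite: production equals consumption
      for (m in paste0("M", 1:6)) {
        prod_rx <- sc$layout$edges$reaction_id[
          sc$layout$edges$metabolite_id == m & sc$layout$edges$role == "product"]
        cons_rx <- sc$layout$edges$reaction_id[
          sc$layout$edges$metabolite_id == m & sc$layout$edges$role == "substrate"]
        expect_equal(sum(vals[prod_rx]), sum(vals[cons_rx]), info = paste(seed, m))
      }
    }
  }
})

test_that("the mutant reroutes through the bypass under knockout conditions", {
  sc <- make_toy_scenario(5, 0, 0, seed = 1)
  v <- stats::setNames(sc$mutant_flux$value, sc$mutant_flux$reaction_id)
  expect_identical(sc$conditions$knockouts, c("R1", "R2"))
  expect_equal(unname(v[c("R1", "R2")]), c(0, 0))
  expect_true(all(v[c("RB1", "RB2")] > 0))
})

test_that("the two case-study knockout sets are shipped verbatim and disjoint", {
  fx <- paper_case_fixtures()
  expect_setequal(fx$succinate$knockouts, c("R_GHMT2", "R_THD2", "R_SUCD1i", "R_TKT1"))
  expect_setequal(fx$glycine$knockouts, c("R_ICL", "R_GLYCL", "R_PPC", "R_GART"))
  expect_identical(length(fx$succinate$knockouts), 4L)
  expect_identical(length(fx$glycine$knockouts), 4L)
  expect_identical(intersect(fx$succinate$knockouts, fx$glycine$knockouts), character())
})

test_that("scenario export writes readable plain-text artifacts", {
  sc <- make_toy_scenario(4, 0.5, 0.5, seed = 6)
  dir <- withr::local_tempdir()
  write_toy_scenario(sc, dir)
  expect_layout_equal(sc$layout, read_xgmml(file.path(dir, "layout.xgmml"))$layout)
  rt_model <- read_sbml_model(file.path(dir, "model.xml"))$model
  expect_identical(rt_model$reactions$id, sc$model$reactions$id)
  wf <- read_flux_tsv(file.path(dir, "wild.tsv"))
  expect_equal(stats::setNames(wf$value, wf$reaction_id),
               stats::setNames(sc$wild_flux$value, sc$wild_flux$reaction_id))
  sbgn <- read_sbgnml_pd(file.path(dir, "layout.sbgn"))$layout
  expect_identical(nrow(sbgn$reactions), nrow(sc$layout$reactions))
})
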