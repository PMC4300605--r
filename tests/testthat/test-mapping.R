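test_that("mapping tables parse, deduplicate and report bad lines", {
  expect_identical(load_mapping_table("N1 R_PGI"),
                   tibble::tibble(layout_id = "N1", model_id = "R_PGI"))
  dup <- load_mapping_table(c("# comment", "N1\tR_PGI", "N1 R_PGI", ""))
  expect_identical(nrow(dup), 1L)
  err <- tryCatch(load_mapping_table("N1 R_PGI extra"), condition = identity)
  expect_s3_class(err, "fluxmapr_parse_error")
  expect_match(conditionMessage(err), "line 1")
})

test_that("regex canonicalization and verbatim model-id lists both resolve nodes", {
  lay <- metabolic_layout(
    reactions = data.frame(id = "R_PGI"),
    metabolites = data.frame(id = "glc"),
    edges = data.frame(reaction_id = "R_PGI", metabolite_id = "glc", role = "substrate"))
  m <- build_mapping(lay, model_reaction_ids = "PGI", model_metabolite_ids = character(),
                     model_regex = c("^", "R_"))
  expect_identical(m$reaction_map,
                   tibble::tibble(model_id = "PGI", node_id = "R_PGI"))
  # empty pairs mode maps nothing
  m0 <- build_mapping(lay, "PGI", pairs = tibble::tibble(layout_id = character(),
                                                         model_id = character()))
  expect_identical(nrow(m0$reaction_map), 0L)
  expect_identical(m0$unmatched_model_ids, "PGI")
  # replicas: one model id to several nodes
  lay2 <- metabolic_layout(reactions = data.frame(id = c("n1", "n2")))
  lay2$reactions$model_ids <- list("TKT1", "TKT1")
  m2 <- build_mapping(lay2, "TKT1")
  expect_identical(nrow(m2$reaction_map), 2L)
  expect_error(build_mapping(lay, "PGI", model_regex = c("([", "x")),
               class = "fluxmapr_configuration_error")
  expect_error(build_mapping(lay, "PGI", pairs = tibble::tibble(layout_id = "a", model_id = "b"),
                             model_regex = c("a", "b")),
               class = "fluxmapr_argument_error")
})

test_that("mapping is independent of input iteration order", {
  lay <- mapped_layout_for(c("Ra", "Rb", "Rc"))
  m1 <- build_mapping(lay, c("Ra", "Rb", "Rc"))
  m2 <- build_mapping(lay, c("Rc", "Ra", "Rb"))
  expect_identical(m1$reaction_map, m2$reaction_map)
})

test_that("fluxes are summed per reaction node; replicas each get the full value", {
  lay <- metabolic_layout(reactions = data.frame(id = c("N", "P", "Q")))
  lay$reactions$model_ids <- list(c("R1", "R2"), "R3", "R9")
  mp <- build_mapping(lay, c("R1", "R2", "R3", "R9"))
  fl <- flux_distribution(c(R1 = 2, R2 = 3, R3 = -4))
  nf <- fluxes_per_reaction_node(lay, mp, fl)
  expect_equal(nf$flux[nf$node_id == "N"], 5)
  expect_equal(nf$flux[nf$node_id == "P"], -4)
  expect_false("Q" %in% nf$node_id)  # no mapped flux -> absent
})

test_that("node flux aggregation matches a brute-force double loop", {
  set.seed(7)
  lay <- metabolic_layout(reactions = data.frame(id = paste0("n", 1:6)))
  model_ids <- paste0("R", 1:10)
  lay$reactions$model_ids <- split(model_ids, sample(rep(1:6, length.out = 10)))
  mp <- build_mapping(lay, model_ids)
  fl <- flux_distribution(stats::setNames(round(stats::rnorm(10), 3), model_ids))
  nf <- fluxes_per_reaction_node(lay, mp, fl)
  for (i in seq_len(nrow(lay$reactions))) {
    want <- 0
    for (j in seq_along(model_ids)) {
      if (model_ids[j] %in% lay$reactions$model_ids[[i]]) {
        want <- want + fl$value[fl$reaction_id == model_ids[j]]
      }
    }
    got <- nf$flux[nf$node_id == lay$reactions$id[i]]
    if (length(got) == 0) got <- 0
    expect_equal(got, want, info = lay$reactions$id[i])
  }
})

test_that("flux distributions reject non-finite values and read from TSV", {
  expect_error(flux_distribution(c(R1 = Inf)), class = "fluxmapr_argument_error")
  tf <- withr::local_tempfile(lines = c("reaction\tvalue", "# note", "R1\t2.5", "R2\t-1"))
  fl <- read_flux_tsv(tf)
  expect_equal(fl$value, c(2.5, -1))
})
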