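test_that("splitting a metabolite yields one replica per incident reaction, conserving edges", {
  lay <- toy_layout()  # M1 touches R1 (product) and R2 (substrate)
  before <- incidence_multiset(lay)
  out <- split_metabolite_node(lay, "M1")
  replicas <- out$metabolites[grepl("^M1__", out$metabolites$id), ]
  expect_identical(nrow(replicas), 2L)
  expect_true(all(replicas$label == "M1"))
  expect_identical(incidence_multiset(out), before)
  # each replica carries exactly the edges to its one reaction
  for (rid in replicas$id) {
    inc <- out$edges[out$edges$metabolite_id == rid, ]
    expect_identical(length(unique(inc$reaction_id)), 1L)
  }
})

test_that("replica ids and ordering are deterministic (suffix by reaction id)", {
  lay <- metabolic_layout(name = "t")
  lay <- add_reaction(lay, "Rb", substrates = "M", products = "P1")
  lay <- add_reaction(lay, "Ra", substrates = "Q1", products = "M")
  lay <- add_reaction(lay, "Rc", substrates = "M", products = "P2")
  out <- split_metabolite_node(lay, "M")
  # M__1 -> Ra, M__2 -> Rb, M__3 -> Rc (lexicographic neighbour order)
  expect_identical(out$edges$reaction_id[out$edges$metabolite_id == "M__1"], "Ra")
  expect_identical(out$edges$reaction_id[out$edges$metabolite_id == "M__2"], "Rb")
  expect_identical(out$edges$reaction_id[out$edges$metabolite_id == "M__3"], "Rc")
})

test_that("degree-1 split is a no-op and error cases are classed", {
  lay <- toy_layout()
  expect_identical(split_metabolite_node(lay, "M0"), lay)
  expect_error(split_metabolite_node(lay, "nope"), class = "fluxmapr_not_found_error")
  expect_error(split_metabolite_node(lay, "R1"), class = "fluxmapr_wrong_kind_error")
})

test_that("split then merge restores the layout up to node renaming", {
  for (seed in 1:8) {
    lay <- random_layout(seed)
    deg <- table(lay$edges$metabolite_id)
    hub <- names(deg)[which.max(deg)]
    split <- split_metabolite_node(lay, hub)
    replicas <- split$metabolites$id[grepl(paste0("^", hub, "__"), split$metabolites$id)]
    if (length(replicas) < 2) next
    merged <- merge_metabolite_nodes(split, replicas)
    expect_identical(nrow(validate_layout(merged)), 0L)
    expect_isomorphic_mets(lay, merged)
    expect_identical(incidence_multiset(lay), incidence_multiset(merged))
  }
})

test_that("metabolite merge demands the same compound and averages positions", {
  lay <- metabolic_layout(
    metabolites = data.frame(id = c("a", "b", "z"), x = c(0, 10, NA), y = c(0, 20, NA),
                             kind = "regular"),
    reactions = data.frame(id = c("r1", "r2")),
    edges = data.frame(reaction_id = c("r1", "r2", "r1"),
                       metabolite_id = c("a", "b", "z"),
                       role = c("product", "substrate", "substrate")))
  lay$metabolites$model_ids <- list("pyr", "pyr", "glc")
  out <- merge_metabolite_nodes(lay, c("a", "b"))
  expect_false("b" %in% out$metabolites$id)
  srow <- out$metabolites[out$metabolites$id == "a", ]
  expect_equal(c(srow$x, srow$y), c(5, 10))
  expect_identical(sum(out$edges$metabolite_id == "a"), 2L)
  expect_error(merge_metabolite_nodes(lay, c("a", "z")),
               class = "fluxmapr_same_compound_error")
})

test_that("reaction replication copies edges, attributes and reversibility", {
  lay <- metabolic_layout(
    metabolites = data.frame(id = c("s1", "s2", "p")),
    reactions = data.frame(id = "R1", reversible = FALSE),
    edges = data.frame(reaction_id = "R1", metabolite_id = c("s1", "s2", "p"),
                       role = c("substrate", "substrate", "product")))
  out <- replicate_reaction_node(lay, "R1", 2)
  expect_identical(nrow(out$reactions), 2L)
  expect_false(any(out$reactions$reversible))
  for (rid in out$reactions$id) {
    expect_identical(sum(out$edges$reaction_id == rid), 3L)
  }
  # metabolite degrees doubled
  expect_true(all(table(out$edges$metabolite_id) == 2))
  expect_error(replicate_reaction_node(lay, "R1", 1), class = "fluxmapr_argument_error")
})

test_that("replicate then merge is the identity", {
  for (seed in 1:8) {
    lay <- random_layout(seed)
    rid <- lay$reactions$id[1]
    rep3 <- replicate_reaction_node(lay, rid, 3)
    copies <- c(rid, paste0(rid, "__", 1:2))
    back <- merge_reaction_nodes(rep3, copies)
    expect_layout_equal(lay, back)
  }
})

test_that("reaction merge rejects any neighbourhood or reversibility mismatch", {
  lay <- metabolic_layout(
    metabolites = data.frame(id = c("A", "B", "C")),
    reactions = data.frame(id = c("R1", "R1b", "R2"),
                           reversible = c(TRUE, FALSE, TRUE)),
    edges = data.frame(
      reaction_id = c("R1", "R1", "R1b", "R1b", "R2", "R2"),
      metabolite_id = c("A", "B", "A", "B", "A", "C"),
      role = c("substrate", "product", "substrate", "product",
               "substrate", "product")))
  expect_error(merge_reaction_nodes(lay, c("R1", "R1b")),
               class = "fluxmapr_merge_illegal_error", regexp = "reversibility")
  expect_error(merge_reaction_nodes(lay, c("R1", "R2")),
               class = "fluxmapr_merge_illegal_error")
})

test_that("merge acceptance agrees with the brute-force sameness predicate", {
  n_checked <- 0
  for (seed in 1:25) {
    lay <- random_layout(seed, n_reactions = 5)
    ids <- lay$reactions$id
    pairs <- t(utils::combn(ids, 2))
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      # independent brute-force oracle, recomputed here from raw tables
      ea <- lay$edges[lay$edges$reaction_id == a, ]
      eb <- lay$edges[lay$edges$reaction_id == b, ]
      oracle <- identical(sort(paste(ea$metabolite_id, ea$role)),
                          sort(paste(eb$metabolite_id, eb$role))) &&
        lay$reactions$reversible[lay$reactions$id == a] ==
        lay$reactions$reversible[lay$reactions$id == b]
      got <- tryCatch({ merge_reaction_nodes(lay, c(a, b)); TRUE },
                      fluxmapr_merge_illegal_error = function(e) FALSE)
      expect_identical(got, oracle, info = sprintf("seed %d pair %s/%s", seed, a, b))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 200)
})

test_that("metabolite kind changes are reflected in kind filters and are idempotent", {
  lay <- toy_layout()
  lay2 <- set_metabolite_kind(lay, "M0", "currency")
  expect_true("M0" %in% filter_by_kind(lay2, "currency_metabolites")$hidden)
  lay3 <- set_metabolite_kind(lay2, "M0", "regular")
  expect_false("M0" %in% filter_by_kind(lay3, "currency_metabolites")$hidden)
  expect_identical(set_metabolite_kind(lay, "M0", "regular"), lay)
})

test_that("fixing honours positions; unfixing keeps coordinates", {
  lay <- toy_layout()
  lay <- set_fixed(lay, "M0", TRUE)   # positionless: placed at origin
  m0 <- lay$metabolites[lay$metabolites$id == "M0", ]
  expect_true(m0$fixed); expect_equal(c(m0$x, m0$y), c(0, 0))
  lay <- set_fixed(lay, "M0", FALSE)
  m0 <- lay$metabolites[lay$metabolites$id == "M0", ]
  expect_false(m0$fixed); expect_equal(c(m0$x, m0$y), c(0, 0))
  lay <- fix_by_kind(lay, "reaction", TRUE)
  expect_true(all(lay$reactions$fixed))
  expect_false(any(lay$metabolites$fixed))
})

test_that("visibility filters select by kind and by reaction identifier", {
  lay <- toy_layout()
  lay <- set_metabolite_kind(lay, "M2", "currency")
  f <- filter_by_kind(lay, "currency_metabolites")
  expect_setequal(f$hidden, c("h2o", "M2"))
  expect_identical(length(filter_by_kind(metabolic_layout(), "reactions")$hidden), 0L)
  # matches model ids as well as layout ids; unknown ids reported, not fatal
  lay$reactions$model_ids[[1]] <- "R_TKT1"
  f2 <- filter_by_reaction_ids(lay, c("R_TKT1", "R_NOPE"))
  expect_identical(f2$hidden, "R1")
  expect_identical(f2$unknown, "R_NOPE")
})
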