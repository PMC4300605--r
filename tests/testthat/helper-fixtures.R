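# Programmatic fixtures: every layout/model used by the tests is built in
# code, at toy scale, under explicit seeds.

# Two-reaction toy: M0 -R1-> M1 -R2-> M2, R2 reversible, one currency water.
toy_layout <- function() {
  lay <- metabolic_layout(name = "toy2")
  lay <- add_reaction(lay, "R1", substrates = "M0", products = "M1", reversible = FALSE)
  lay <- add_reaction(lay, "R2", substrates = "M1", products = "M2", reversible = TRUE)
  lay$metabolites <- dplyr::bind_rows(lay$metabolites, tibble::tibble(
    id = "h2o", label = "water", model_ids = list("h2o"), kind = "currency",
    x = NA_real_, y = NA_real_, fixed = FALSE))
  lay$edges <- dplyr::bind_rows(lay$edges, tibble::tibble(
    reaction_id = "R1", metabolite_id = "h2o", role = "product"))
  lay
}

# Random small bipartite layout with optional positions, currency nodes and
# info nodes; always valid by construction.
random_layout <- function(seed, n_reactions = 4, positioned = FALSE) {
  set.seed(seed)
  n_mets <- n_reactions + sample(1:3, 1)
  met_ids <- paste0("m", seq_len(n_mets))
  lay <- metabolic_layout(name = paste0("rand", seed))
  kinds <- ifelse(stats::runif(n_mets) < 0.25, "currency", "regular")
  lay$metabolites <- tibble::tibble(
    id = met_ids, label = paste0("Met ", met_ids),
    model_ids = lapply(met_ids, function(m) c(paste0("M_", m), paste0("alt_", m))),
    kind = kinds,
    x = if (positioned) stats::runif(n_mets, 0, 400) else NA_real_,
    y = if (positioned) stats::runif(n_mets, 0, 400) else NA_real_,
    fixed = positioned)
  rx_ids <- paste0("r", seq_len(n_reactions))
  lay$reactions <- tibble::tibble(
    id = rx_ids, label = paste0("Reaction ", rx_ids),
    model_ids = lapply(rx_ids, function(r) paste0("R_", r)),
    reversible = stats::runif(n_reactions) < 0.5,
    x = if (positioned) stats::runif(n_reactions, 0, 400) else NA_real_,
    y = if (positioned) stats::runif(n_reactions, 0, 400) else NA_real_,
    fixed = positioned)
  edges <- list()
  for (r in rx_ids) {
    k <- sample(2:3, 1)
    mets <- sample(met_ids, k)
    roles <- c("substrate", sample(c("substrate", "product"), k - 1, replace = TRUE))
    roles[k] <- "product"  # every reaction has at least one product
    for (j in seq_len(k)) {
      edges[[length(edges) + 1]] <- tibble::tibble(
        reaction_id = r, metabolite_id = mets[j], role = roles[j])
    }
  }
  lay$edges <- dplyr::distinct(dplyr::bind_rows(edges))
  if (stats::runif(1) < 0.5) {
    lay$info_nodes <- tibble::tibble(
      id = "note1", text = "EC 1.1.1.1", reaction_id = rx_ids[1])
  }
  lay
}

# Field-by-field layout equality (model_ids as ordered vectors), with rows
# sorted by id so table order does not matter.
expect_layout_equal <- function(a, b, ignore_fixed = FALSE, tol = 1e-9) {
  sort_tab <- function(t) t[order(t$id), , drop = FALSE]
  am <- sort_tab(a$metabolites); bm <- sort_tab(b$metabolites)
  ar <- sort_tab(a$reactions); br <- sort_tab(b$reactions)
  if (ignore_fixed) {
    am$fixed <- bm$fixed <- NULL
    ar$fixed <- br$fixed <- NULL
  }
  testthat::expect_equal(as.data.frame(am), as.data.frame(bm),
                         tolerance = tol, ignore_attr = TRUE)
  testthat::expect_equal(as.data.frame(ar), as.data.frame(br),
                         tolerance = tol, ignore_attr = TRUE)
  sort_edges <- function(t) t[order(t$reaction_id, t$metabolite_id, t$role), , drop = FALSE]
  testthat::expect_equal(as.data.frame(sort_edges(a$edges)),
                         as.data.frame(sort_edges(b$edges)), ignore_attr = TRUE)
  sort_info <- function(t) t[order(t$id), , drop = FALSE]
  testthat::expect_equal(as.data.frame(sort_info(a$info_nodes)),
                         as.data.frame(sort_info(b$info_nodes)), ignore_attr = TRUE)
}

# Canonical structural signature for isomorphism checks (identity up to
# node-id renaming): metabolites are identified by label/kind/model-id set
# and their sorted incidence over reaction ids; reactions by their sorted
# incidence over metabolite signatures.
met_signatures <- function(lay) {
  sig <- vapply(seq_len(nrow(lay$metabolites)), function(i) {
    id <- lay$metabolites$id[i]
    inc <- lay$edges[lay$edges$metabolite_id == id, ]
    paste(lay$metabolites$label[i], lay$metabolites$kind[i],
          paste(sort(lay$metabolites$model_ids[[i]]), collapse = ","),
          paste(sort(paste(inc$reaction_id, inc$role)), collapse = ";"),
          sep = "|")
  }, character(1))
  sort(sig)
}

expect_isomorphic_mets <- function(a, b) {
  testthat::expect_equal(met_signatures(a), met_signatures(b))
}

# Multiset of (reaction model ids, metabolite model ids, role) incidences —
# the edge-conservation oracle for split/merge/replicate.
incidence_multiset <- function(lay) {
  if (!nrow(lay$edges)) return(character())
  out <- vapply(seq_len(nrow(lay$edges)), function(i) {
    r <- lay$edges$reaction_id[i]; m <- lay$edges$metabolite_id[i]
    rm <- lay$reactions$model_ids[[match(r, lay$reactions$id)]]
    mm <- lay$metabolites$model_ids[[match(m, lay$metabolites$id)]]
    paste(paste(sort(rm), collapse = ","), paste(sort(mm), collapse = ","),
          lay$edges$role[i], sep = "|")
  }, character(1))
  sort(out)
}

# Minimal 3-reaction linear SBML model text (M0 -R1-> M1 -R2-> M2 -R3-> M3).
linear_sbml <- function(reversible_r2 = TRUE, with_groups = FALSE) {
  groups <- if (with_groups) paste0(
    '<listOfGroups xmlns:groups="http://www.sbml.org/sbml/level3/version1/groups/version1">',
    '<group id="g1" name="upper chain" kind="partonomy">',
    '<listOfMembers><member idRef="R1"/><member idRef="R2"/></listOfMembers>',
    '</group></listOfGroups>') else ""
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="linear3" name="linear toy">',
    '<listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="M0" name="alpha" compartment="c"/>',
    '<species id="M1" name="beta" compartment="c"/>',
    '<species id="M2" name="gamma" compartment="c"/>',
    '<species id="M3" name="delta" compartment="c"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="R1" reversible="false">',
    '<listOfReactants><speciesReference species="M0" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M1" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    sprintf('<reaction id="R2" reversible="%s">', tolower(reversible_r2)),
    '<listOfReactants><speciesReference species="M1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M2"/></listOfProducts>',
    '</reaction>',
    '<reaction id="R3" reversible="false">',
    '<listOfReactants><speciesReference species="M2"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M3"/></listOfProducts>',
    '</reaction>',
    '</listOfReactions>',
    groups,
    '</model></sbml>')
}

# Fully mapped toy layout carrying a set of model reaction ids one-to-one.
mapped_layout_for <- function(model_ids) {
  lay <- metabolic_layout(name = "mapped")
  for (i in seq_along(model_ids)) {
    lay <- add_reaction(lay, paste0("N", i),
                        substrates = paste0("A", i), products = paste0("B", i),
                        model_ids = model_ids[i])
  }
  lay
}

# Toy KGML: one reversible reaction (entry 10) between compounds 1 and 2,
# one irreversible reaction (entry 11) consuming compound 2 into compound 3
# (which has no graphics and no entry for one participant test variant).
toy_kgml <- function(missing_participant = FALSE) {
  extra <- if (missing_participant) '<product id="99" name="cpd:C99999"/>' else ""
  paste0(
    '<?xml version="1.0"?>',
    '<pathway name="path:toy00010" org="eco" number="00010">',
    '<entry id="1" name="cpd:C00022" type="compound">',
    '<graphics name="Pyruvate" x="10" y="20" type="circle"/></entry>',
    '<entry id="2" name="cpd:C00036" type="compound">',
    '<graphics name="Oxaloacetate" x="30" y="40" type="circle"/></entry>',
    '<entry id="3" name="cpd:C00149" type="compound">',
    '<graphics name="Malate" x="50" y="60" type="circle"/></entry>',
    '<entry id="10" name="rn:R00199" type="gene" reaction="rn:R00199">',
    '<graphics name="ppsA" x="20" y="30" type="rectangle"/></entry>',
    '<entry id="11" name="rn:R00342 rn:R00343" type="ortholog" reaction="rn:R00342"/>',
    '<reaction id="10" name="rn:R00199" type="reversible">',
    '<substrate id="1" name="cpd:C00022"/><product id="2" name="cpd:C00036"/>',
    '</reaction>',
    '<reaction id="11" name="rn:R00342 rn:R00343" type="irreversible">',
    '<substrate id="2" name="cpd:C00036"/><product id="3" name="cpd:C00149"/>',
    extra,
    '</reaction>',
    '</pathway>')
}

# CellDesigner-annotated SBML with two aliases of one species.
toy_cd_sbml <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" ',
    'xmlns:celldesigner="http://www.sbml.org/2001/ns/celldesigner" level="2" version="4">',
    '<model id="cdtoy">',
    '<annotation><celldesigner:extension>',
    '<celldesigner:listOfSpeciesAliases>',
    '<celldesigner:speciesAlias id="sa1" species="s1">',
    '<celldesigner:bounds x="0" y="0" w="40" h="20"/></celldesigner:speciesAlias>',
    '<celldesigner:speciesAlias id="sa2" species="s1">',
    '<celldesigner:bounds x="100" y="100" w="40" h="20"/></celldesigner:speciesAlias>',
    '<celldesigner:speciesAlias id="sa3" species="s2">',
    '<celldesigner:bounds x="200" y="0" w="40" h="20"/></celldesigner:speciesAlias>',
    '</celldesigner:listOfSpeciesAliases>',
    '</celldesigner:extension></annotation>',
    '<listOfSpecies>',
    '<species id="s1" name="glucose" compartment="c"/>',
    '<species id="s2" name="G6P" compartment="c"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="r1" reversible="false">',
    '<annotation><celldesigner:extension>',
    '<celldesigner:baseReactants><celldesigner:baseReactant species="s1" alias="sa2"/>',
    '</celldesigner:baseReactants>',
    '<celldesigner:baseProducts><celldesigner:baseProduct species="s2" alias="sa3"/>',
    '</celldesigner:baseProducts>',
    '</celldesigner:extension></annotation>',
    '<listOfReactants><speciesReference species="s1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="s2"/></listOfProducts>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>')
}

# Minimal COBRA-style map in the documented v1 dialect.
toy_cobra_map <- function(bad_coord = FALSE) {
  c("# toy map",
    "type\tid\tname\tx\ty\tattr",
    "metabolite\tglc\tGlucose\t10\t20\tregular",
    if (bad_coord) "metabolite\tg6p\tG6P\toops\t40\tregular"
    else "metabolite\tg6p\tG6P\t30\t40\tregular",
    "reaction\tHEX1\tHexokinase\t20\t30\tfalse",
    "edge\tHEX1\tglc\tsubstrate",
    "edge\tHEX1\tg6p\tproduct")
}
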