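#' Generate a toy scenario with known ground truth
#'
#' Builds a deterministic, fully consistent bundle for testing and
#' demonstration: a small model digest, its layout, an identifier mapping
#' with no unmatched ids, a steady "wild-type" flux vector, a "mutant"
#' vector with one path rerouted, and the knockout conditions that force the
#' reroute. The network is a linear reaction chain `R1..Rn` over metabolites
#' `M0..Mn`; when `n_reactions >= 3` a two-reaction bypass (`RB1`, `RB2` via
#' metabolite `X`) shortcuts the first two chain steps, the mutant carries
#' all flux through it, and `R1`, `R2` are the knockouts. Each chain
#' reaction sprouts, with probability `branching`, an inactive side-drain
#' reaction (`S<i>` producing a dead-end metabolite), and with probability
#' `currency_rate` a degree-1 currency replica (water). Fluxes are
#' flux-conserving along the active path (every internal chain metabolite is
#' produced and consumed at the same rate), mimicking a steady-state FBA
#' solution without solving one.
#'
#' The returned `truth` record (node, edge, currency-replica and
#' nonzero-flux counts) is kept by construction, so tests can compare it
#' against independent recomputation.
#'
#' @param n_reactions Number of chain reactions (>= 1).
#' @param branching Probability of a side-drain branch per chain reaction,
#'   in `[0, 1]`.
#' @param currency_rate Probability of a currency attachment per chain
#'   reaction, in `[0, 1]`.
#' @param seed Integer seed; the scenario is a pure function of the
#'   arguments.
#' @return A `toy_scenario`: list with `model`, `layout`, `mapping`,
#'   `wild_flux`, `mutant_flux`, `conditions`, `truth`.
#' @export
make_toy_scenario <- function(n_reactions, branching = 0.3, currency_rate = 0.3,
                              seed = 1) {
  if (!is.numeric(n_reactions) || n_reactions < 1 ||
      n_reactions != as.integer(n_reactions)) {
    stop_argument("n_reactions must be an integer >= 1")
  }
  if (branching < 0 || branching > 1) stop_argument("branching must be in [0, 1]")
  if (currency_rate < 0 || currency_rate > 1) stop_argument("currency_rate must be in [0, 1]")
  n <- as.integer(n_reactions)
  set.seed(as.integer(seed))

  rxn <- list(); met_ids <- paste0("M", 0:n)
  chain_rev <- stats::runif(n) < 0.3
  add_rxn <- function(id, subs, prods, reversible) {
    rxn[[length(rxn) + 1]] <<- tibble(
      id = id, name = id, reversible = reversible,
      substrates = list(subs), sub_stoich = list(rep(1, length(subs))),
      products = list(prods), prod_stoich = list(rep(1, length(prods))))
  }
  for (i in seq_len(n)) {
    add_rxn(paste0("R", i), paste0("M", i - 1), paste0("M", i), chain_rev[i])
  }
  has_branch <- stats::runif(n) < branching
  for (i in which(has_branch)) {
    met_ids <- c(met_ids, paste0("D", i))
    add_rxn(paste0("S", i), paste0("M", i), paste0("D", i), FALSE)
  }
  has_currency <- stats::runif(n) < currency_rate
  if (any(has_currency)) met_ids <- c(met_ids, "h2o")
  bypass <- n >= 3
  if (bypass) {
    met_ids <- c(met_ids, "X")
    add_rxn("RB1", "M0", "X", FALSE)
    add_rxn("RB2", "X", "M2", FALSE)
  }
  reactions <- bind_rows(rxn)
  # currency participation recorded on the model too (as a product of the
  # chain reaction), so layout generation and the hand-built layout agree
  for (i in which(has_currency)) {
    j <- which(reactions$id == paste0("R", i))
    reactions$products[[j]] <- c(reactions$products[[j]], "h2o")
    reactions$prod_stoich[[j]] <- c(reactions$prod_stoich[[j]], 1)
  }
  model <- model_digest(
    id = sprintf("toy_%d_%d", n, as.integer(seed)), name = "toy model",
    reactions = reactions,
    metabolites = tibble(id = met_ids, name = met_ids, compartment = "c"),
    pathways = tibble(pathway = "chain", reaction_id = paste0("R", seq_len(n))),
    n_genes = 0
  )

  layout <- metabolic_layout(name = model$id)
  for (j in seq_len(nrow(reactions))) {
    non_currency <- function(v) setdiff(v, "h2o")
    layout <- add_reaction(layout, reactions$id[j],
                           substrates = non_currency(reactions$substrates[[j]]),
                           products = non_currency(reactions$products[[j]]),
                           reversible = reactions$reversible[j])
  }
  n_currency <- 0L
  for (i in which(has_currency)) {
    nid <- paste0("h2o__R", i)
    layout$metabolites <- bind_rows(layout$metabolites, tibble(
      id = nid, label = "h2o", model_ids = list("h2o"), kind = "currency",
      x = NA_real_, y = NA_real_, fixed = FALSE))
    layout$edges <- bind_rows(layout$edges, tibble(
      reaction_id = paste0("R", i), metabolite_id = nid, role = "product"))
    n_currency <- n_currency + 1L
  }

  mapping <- build_mapping(layout,
                           model_reaction_ids = model$reactions$id,
                           model_metabolite_ids = model$metabolites$id)

  base <- 10
  wild <- stats::setNames(rep(base, n), paste0("R", seq_len(n)))
  if (any(has_branch)) {
    wild <- c(wild, stats::setNames(rep(0, sum(has_branch)),
                                    paste0("S", which(has_branch))))
  }
  if (bypass) wild <- c(wild, RB1 = 0, RB2 = 0)
  mutant <- wild
  if (bypass) {
    mutant[c("R1", "R2")] <- 0
    mutant[c("RB1", "RB2")] <- base
    conditions <- genetic_conditions(knockouts = c("R1", "R2"))
  } else {
    conditions <- genetic_conditions()
  }

  structure(
    list(
      model = model, layout = layout, mapping = mapping,
      wild_flux = flux_distribution(wild),
      mutant_flux = flux_distribution(mutant),
      conditions = conditions,
      truth = list(
        nodes = nrow(layout$metabolites) + nrow(layout$reactions),
        reactions = nrow(layout$reactions),
        metabolites = nrow(layout$metabolites),
        edges = nrow(layout$edges),
        currency_replicas = n_currency,
        nonzero_wild_fluxes = sum(wild != 0)
      )
    ),
    class = "toy_scenario"
  )
}

#' @export
print.toy_scenario <- function(x, ...) {
  cat(sprintf("<toy_scenario '%s': %d reactions, %d metabolites, %d edges>\n",
              x$model$id, x$truth$reactions, x$truth$metabolites, x$truth$edges))
  invisible(x)
}

#' Knockout sets of the two E. coli production case studies
#'
#' The two published knockout designs used as demonstration conditions: a
#' succinic-acid production mutant of the iJR904 model (deleting serine
#' hydroxymethyltransferase `R_GHMT2`, transhydrogenase `R_THD2`, succinate
#' dehydrogenase `R_SUCD1i` and transketolase I `R_TKT1`) and a glycine
#' production mutant of the iAF1260 model (deleting isocitrate lyase
#' `R_ICL`, glycine cleavage `R_GLYCL`, PEP carboxylase `R_PPC` and GAR
#' formyltransferase 2 `R_GART`).
#'
#' @return A named list of two [genetic_conditions()]: `succinate` and
#'   `glycine`.
#' @export
paper_case_fixtures <- function() {
  list(
    succinate = genetic_conditions(
      knockouts = c("R_GHMT2", "R_THD2", "R_SUCD1i", "R_TKT1")),
    glycine = genetic_conditions(
      knockouts = c("R_ICL", "R_GLYCL", "R_PPC", "R_GART"))
  )
}

#' Write a toy scenario to disk
#'
#' Exports a [make_toy_scenario()] bundle as plain-text files: the layout as
#' XGMML and SBGN-ML, the model as SBML, the two flux vectors and the
#' conditions as TSV.
#'
#' @param scenario A `toy_scenario`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_toy_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_xgmml(scenario$layout, file.path(dir, "layout.xgmml"))
  positioned <- run_fdl(scenario$layout, fdl_params(iterations = 150))
  positioned <- fix_by_kind(fix_by_kind(positioned, "reaction", TRUE), "metabolite", TRUE)
  write_sbgnml_pd(positioned, file.path(dir, "layout.sbgn"))
  write_sbml_model(scenario$model, file.path(dir, "model.xml"))
  wf <- scenario$wild_flux
  writeLines(c("# wild-type flux distribution",
               paste(wf$reaction_id, wf$value, sep = "\t")),
             file.path(dir, "wild.tsv"))
  mf <- scenario$mutant_flux
  writeLines(c("# mutant flux distribution",
               paste(mf$reaction_id, mf$value, sep = "\t")),
             file.path(dir, "mutant.tsv"))
  ko <- scenario$conditions$knockouts
  writeLines(if (length(ko)) paste(ko, "KO", sep = "\t") else character(),
             file.path(dir, "conditions.tsv"))
  invisible(dir)
}

#' Write a model digest as SBML Level 3
#'
#' Minimal SBML writer used to export generated toy models; emits species,
#' reactions with stoichiometric participants and reversibility, and
#' pathway groups.
#'
#' @param model A `model_digest`.
#' @param path Output file path, or `NULL` to return the XML text.
#' @return The path (or XML text) invisibly.
#' @export
write_sbml_model <- function(model, path = NULL) {
  doc <- xml_new_root("sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
                      level = "3", version = "1")
  mn <- xml_add_child(doc, "model", id = if (nzchar(model$id)) model$id else "model")
  comps <- unique(model$metabolites$compartment)
  comps <- comps[!is.na(comps)]
  if (length(comps)) {
    lc <- xml_add_child(mn, "listOfCompartments")
    for (cmp in comps) xml_add_child(lc, "compartment", id = cmp, constant = "true")
  }
  ls <- xml_add_child(mn, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    xml_add_child(ls, "species", id = m$id, name = m$name,
                  compartment = if (is.na(m$compartment)) "c" else m$compartment,
                  hasOnlySubstanceUnits = "false", boundaryCondition = "false",
                  constant = "false")
  }
  lr <- xml_add_child(mn, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rn <- xml_add_child(lr, "reaction", id = r$id, name = r$name,
                        reversible = if (isTRUE(r$reversible)) "true" else "false",
                        fast = "false")
    if (length(r$substrates[[1]])) {
      l1 <- xml_add_child(rn, "listOfReactants")
      for (k in seq_along(r$substrates[[1]])) {
        xml_add_child(l1, "speciesReference", species = r$substrates[[1]][k],
                      stoichiometry = fmt_num(r$sub_stoich[[1]][k]), constant = "true")
      }
    }
    if (length(r$products[[1]])) {
      l2 <- xml_add_child(rn, "listOfProducts")
      for (k in seq_along(r$products[[1]])) {
        xml_add_child(l2, "speciesReference", species = r$products[[1]][k],
                      stoichiometry = fmt_num(r$prod_stoich[[1]][k]), constant = "true")
      }
    }
  }
  if (nrow(model$pathways)) {
    lg <- xml_add_child(mn, "listOfGroups")
    for (pw in unique(model$pathways$pathway)) {
      grp <- xml_add_child(lg, "group", id = gsub("[^A-Za-z0-9_]", "_", pw),
                           name = pw, kind = "partonomy")
      lm <- xml_add_child(grp, "listOfMembers")
      for (rid in model$pathways$reaction_id[model$pathways$pathway == pw]) {
        xml_add_child(lm, "member", idRef = rid)
      }
    }
  }
  if (is.null(path)) return(invisible(as.character(doc)))
  write_xml(doc, path)
  invisible(path)
}
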