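---
title: "Metabolic layouts and flux overlays: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic layouts and flux overlays: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmapr)
```

## The layout model

fluxmapr draws metabolism as a *reaction-compound network*: a bipartite graph
with reaction nodes on one side, metabolite nodes on the other, and edges only
between the two classes. This representation is descriptive (every reaction is
an explicit node that can be labelled, styled and annotated) and it maps
naturally onto the stoichiometric structure of genome-scale metabolic models
(GSMMs).

A `metabolic_layout` holds four tibbles: metabolite nodes, reaction nodes,
edges (with a `substrate`/`product` role) and free-text info annotations
attached to reactions. Two modelling decisions shape everything else:

* **Model-identifier lists, not foreign keys.** Every node carries a *list* of
  model identifiers. One layout can serve several models (different strains or
  model versions), a partial layout can cover a slice of a model, a node can
  stand for several model reactions (e.g. a lumped pathway), and one model
  metabolite can appear as many replica nodes. The `model_mapping` layer
  resolves these lists at analysis time; the layout itself stays independent
  of any particular model.
* **Arrowheads are derived, never stored.** An irreversible reaction's edges
  carry arrows toward its products only; a reversible reaction's edges carry
  arrows at both metabolite ends. Since this follows entirely from the
  reversibility flag, the renderer computes it and no file format needs to
  persist it.

Metabolites are typed `regular` or `currency`. Currency metabolites (water,
protons, ATP/ADP, redox carriers) are hubs that would otherwise dominate the
drawing; they are usually replicated per reaction or hidden with a filter.
The default currency list (`default_currency_ids()`) contains the eleven
classic hub compounds, matched case-insensitively after stripping a leading
`M_` prefix and one trailing compartment suffix; the degree threshold (default
8 within the selected reaction set) additionally promotes unnamed hubs. Both
are heuristics: compartment conventions vary across models, and users mapping
unusual models should pass their own list.

Coordinates live on an abstract unitless canvas with the origin at the top
left and y increasing downward, matching SVG; all format readers convert into
this convention (KGML pixel coordinates are already y-down and are used
as-is).

## Editing algebra

The editing operations are designed to be closed over validity (every
operation's output passes `validate_layout()`) and, where meaningful, to be
mutually inverse:

* `split_metabolite_node()` replaces a shared metabolite with one replica per
  incident reaction. Replica ids are `<id>__k` with `k` ordered by the
  neighbouring reaction id, so scripted edits are reproducible. A degree-1
  node splits to itself (a no-op rather than an error) so batch scripts are
  idempotent.
* `merge_metabolite_nodes()` is its inverse. "Same compound" is interpreted
  strictly: identical model-id sets and identical kind. Overlapping but
  unequal id lists are rejected — a deliberate conservative choice, since
  merging nodes that map different reactions would silently change analysis
  results. The survivor is the lexicographically lowest id; its position is
  the centroid of the positioned participants.
* `replicate_reaction_node()` / `merge_reaction_nodes()` do the same for
  reactions. Reactions may only merge when *exactly* the same: identical
  (metabolite, role) neighbourhoods and equal reversibility. The package's
  acceptance of a merge is property-tested against the brute-force predicate.
* Unfixing a node keeps its stored coordinates and only clears the pinned
  flag. Discarding coordinates would make every subsequent force-directed run
  depend on the seed alone; caching them keeps restarts deterministic while
  still letting the embedder move the node. Fixing a positionless node places
  it at the origin first — a documented, trivially predictable default.

## Force-directed layout

`run_fdl()` is a spring embedder with pinned-node support: edges pull their
endpoints toward a rest length `spring_length` (default 80 canvas units) with
stiffness `spring_coefficient` (0.05 per unit extension); all node pairs repel
with `repulsion_constant / d^2` (default 5000); movable nodes feel a weak
centroid gravity (0.001) so disconnected fragments stay on canvas. Updates are
capped by a linearly cooling step (from one rest length down to ~0), which
gives geometric convergence near equilibria. With repulsion and gravity
disabled, a single movable node attached to one pinned node settles at the
spring rest length — the 1-D force-balance oracle used in the tests.

Defaults are tuned for the scale the tool targets: partial layouts of roughly
30–50 nodes (up to ~15 reactions), where the defaults produce no overlapping
nodes. Layouts far larger than that are better drawn as several partial
layouts.

Determinism is part of the contract: positionless nodes are initialized on a
seeded uniform disc around the centroid of the positioned nodes, and nothing
else draws random numbers, so a run is a pure function of
`(layout, params)`. Initial placement is assigned in row order, not id order,
so renaming node ids (keeping row order) does not change the result. Fixed
nodes are never touched — their coordinates are bit-identical in the output.
Info annotations take no part in the simulation; they are placed beside their
reaction at render time: annotations should follow their reaction, not
distort its neighbourhood's geometry.

## Identifier mapping and flux aggregation

`build_mapping()` has two modes. *Pairs mode* maps exactly the rows of a
two-column table — nothing inferred, including an empty table mapping
nothing. *Regex mode* canonicalizes each side's identifiers with a
substitution (`pattern`, `replacement`; identity when omitted) and matches on
equal canonical strings; independently, a model id listed verbatim in a
node's `model_ids` always matches. Substitution-then-equality was chosen over
"search" semantics because it is a single well-defined rule that covers the
common cases (prefix/suffix conventions like `R_` or compartment tags).
Matching is case-sensitive because SBML identifiers are.

When several model reactions map to one node, `fluxes_per_reaction_node()`
**sums** their fluxes — the natural reading for lumped reactions. When one
model reaction maps to several replica nodes, each replica receives the full
value: replicas depict the same reaction, and scaling the value down would
make visually identical copies of one reaction look different. Both rules are
deliberate and tested; users who need a different aggregation can aggregate
before building the distribution.

## Overlays

Overlays are the only channel from analysis results to rendering: a bundle of
per-edge widths and colours, per-node glyphs and label suffixes, and named
hide-filters. The renderer applies them without knowing where they came from.

**Flux overlays.** Per-node fluxes are normalized linearly against the
per-layout maximum absolute value `F`: every edge incident to a node with
flux `f` gets width `min_width + (max_width − min_width)·|f|/F`. Linear
max-scaling is monotone, attains both bounds exactly, and is scale-free
(multiplying all fluxes by a constant changes nothing but the labels). When
`F = 0` every width collapses to the minimum. Signed values appear in the
label suffix (fixed-point, 3 decimals by default, appended after the reaction
name); thickness uses magnitudes, since edge direction is already encoded by
the arrowheads.

**Genetic conditions.** Knockouts draw a red cross over the reaction node and
colour its edges red; over-expression an upward green arrow; under-expression
a downward orange arrow. Condition ids that resolve to no node are collected
as diagnostics rather than failing — a partial layout legitimately omits most
of a genome-scale condition set.

**Simulation comparisons.** Per node, with `a = |f_A|` and `b = |f_B|`, the
relative difference `d = |a − b| / max(a, b)` drives a linear RGB blend from
black (no difference) toward the colour of the simulation with more flux
(pure colour when the other simulation is silent). The relative form makes
`d` scale-free; the endpoints (black for equal, pure colour for exclusive)
fix the gradient's meaning, the curve between them is this package's choice. Edges where both simulations are
zero keep the default style rather than black, distinguishing "no flux
anywhere" from "equal nonzero flux". Widths use the per-node mean
`(a + b)/2`, normalized after averaging (mean-then-normalize keeps the width
of an edge interpretable as its average activity). On reversible reactions
whose two fluxes run opposite ways, arrowheads are coloured per direction:
product-end heads take the forward simulation's colour, substrate-end heads
the backward one's. Two filters (`hide_zero_in_A`/`_B`) hide each
simulation's silent reactions; like the EFM filter, they also hide metabolite
neighbours left without any visible reaction, since a floating compound
carries no information.

**Elementary flux modes.** An EFM arrives as a flux vector over its member
reactions; the overlay reuses the flux-overlay width/label rules, adds no
glyphs or colours, and generates one filter hiding the zero-flux remainder —
activating it shows the mode alone.

## File formats

* **XGMML** is the lossless interchange format. XGMML has no metabolic
  vocabulary, so the package writes a documented dialect (`att` elements
  `nodetype`, `model_ids`, `reversible`, `fixed`, plus `graphics` for
  coordinates); Cytoscape still opens the files. Reading tolerates foreign
  attributes; an untyped node is taken as a regular metabolite with a
  warning.
* **SBGN-ML PD** is supported read/write; only the Process Description
  language fits metabolism (ER/AF maps are rejected). Processes carry two
  ports; arcs through port 1 are the substrate side, port 2 the product side,
  which lets reversible reactions follow the PD convention of production arcs
  on both sides and still round-trip. Clone markers map to currency
  metabolites. Model-id lists travel in an `extension` element. SBGN has no
  notion of an unpositioned glyph, so every node is written with a bounding
  box (origin when unknown) and read back fixed; lossless round trips are
  therefore defined over positioned layouts.
* **KGML**, **CellDesigner SBML** and **COBRA/BiGG map text** are read-only:
  they are sources of curated drawings, and XGMML/SBGN-ML are the export
  targets. The COBRA map family has several undocumented dialect versions, so
  the reader targets a documented v1 record layout and degrades gracefully
  (bad coordinates unfix the node, unparseable records become warnings).
  KGML files are supplied by the user; the package does not download from
  KEGG.
* **SBML models** (Level 2/3) are digested to what layout generation needs:
  reactions, stoichiometric participants, reversibility, compartments,
  pathway groups (SBML `groups` package or `SUBSYSTEM:` notes) and a gene
  count (`fbc` gene products or `GENE_ASSOCIATION` notes).
* **PDF export** is a conversion of the rendered SVG, delegated to an
  available converter at runtime; without one, a classed unsupported-feature
  error is raised and the SVG path is unaffected.

## Rendering

The SVG vocabulary is deliberately small — squares for reactions, circles for
metabolites, small grey circles for currency, straight edges — matching the
drawings this style of tool produces and keeping output dependency-free.
Glyph geometry (cross and triangles beside the node) is a documented
approximation of the usual pictorial symbols. Elements are emitted sorted by
node id, so output is byte-stable and golden-file testable. Hidden nodes are
omitted entirely: their ids appear nowhere in the output text, which the
tests assert literally.

## The toy-scenario generator

`make_toy_scenario()` builds the bundle every integration test runs on: a
linear reaction chain with a two-reaction bypass, optional inactive
side-drain branches, optional per-reaction currency replicas, a wild-type
flux vector running the chain at 10 mmol gDW⁻¹ h⁻¹, and a mutant vector
rerouted through the bypass with the bypassed chain steps as knockouts.
Fluxes are constructed to be conserved at every internal chain metabolite, so
overlays look like a steady-state FBA solution without solving one. What it
deliberately does **not** emulate: realistic network topology (hubs,
cofactor coupling beyond the toy water replicas), realistic flux magnitudes
or degeneracy, compartments, or genuine LP solutions for published models —
passing tests demonstrate the visualization pipeline's correctness, not
biological fidelity of the inputs. Reproducing real iJR904/iAF1260 flux
states would require the models and an LP solver and is out of scope.

Problem sizes are chosen to keep the whole suite quick while exercising the
target scale: round-trip properties run on 100 generated fixtures of 3–8
reactions, edit-algebra properties on 200+ random reaction pairs, and the
layout-engine checks on graphs up to ~45 nodes — the partial-layout scale the
tool is designed for.

## Known limitations

* Metabolite mapping is not compartment-aware; two compartments' versions of
  a compound are distinct model ids, as in SBML.
* No hierarchical/circular/grid layouts and no edge-crossing minimization;
  the single embedder with pinning covers the intended workflow of curating
  mostly-fixed drawings.
* CD-SBML writing and SBML Layout/Render emission are not implemented.
* Omics overlays (expression, metabolomics) are a natural extension of the
  overlay layer but not part of it today.
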