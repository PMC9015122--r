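---
title: "Harmonizing drawn pathway interactions into a semantic graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing drawn pathway interactions into a semantic graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsem)
```

## The problem

Biological pathway diagrams encode causal knowledge — conversions,
inhibitions, catalysis — as drawings: boxes connected by lines with
arrowheads. Databases such as WikiPathways store these drawings in GPML,
an XML format that records *graphics*: a line is "point A connected to
point B with arrowhead token T". Humans read the biology off the picture
effortlessly; software cannot, especially because several drawing
notations coexist (plain WikiPathways arrows, MIM, SBGN) and an
inhibition looks different in each.

`pathsem` turns one GPML drawing into **two graph layers**:

* the **graphical layer** (`gpml_layer`) keeps every drawn element —
  nodes, lines, anchors, groups, free text labels — whether or not it has
  a biological reading;
* the **semantic layer** (`wp_layer`) keeps only what is biologically
  identifiable: datanodes resolved to database identifiers, and
  interactions harmonized into a fixed nine-class vocabulary.

Every semantic resource links back to its drawn counterpart with
`wp:isAbout`, which is what makes curation reports possible: a drawn line
with no semantic counterpart is, by construction, a curation gap with a
recorded reason.

## The interaction model

The nine interaction classes form a fixed hierarchy. Everything is an
`Interaction`. All classes except `Binding` and `ComplexBinding` are
subclasses of `DirectedInteraction` — binding events are symmetric and
carry no direction. The directed classes are `Conversion`, `Inhibition`,
`Catalysis`, `Stimulation` and `TranscriptionTranslation`, plus the
generic `DirectedInteraction` itself for arrows whose mechanism the
author did not specify.

A directed interaction has exactly one `source` and one `target`, and at
least two `participants`; bindings have participants only. These
constraints are exactly what `default_shapes()` encodes and
`validate_shapes()` checks, and `export_shex()` writes them out in ShEx
compact syntax for external validators.

The store asserts only the *most specific* class of each resource;
`types_of()` computes the superclass closure on demand. This keeps
"non-specified interaction" counting trivial (an interaction typed only
`wp:Interaction`) and matches how participant profiles are conventionally
printed, where a catalyzed reaction participant appears as
`Conversion, DirectedInteraction, Interaction` but a protein node appears
simply as `Protein`.

## From drawing to semantics

Conversion proceeds in four stages, all deterministic (iteration is
sorted by `graphId` everywhere; there is no randomness in the converter).

**1. Datanode resolution.** A drawn node is accepted iff it carries a
non-empty xref whose datasource the registry knows, and its declared type
is not `Unknown`. Accepted nodes mint identifiers.org-style CURIEs
(`ensembl:ENSG00000169057`, `hmdb:HMDB0004913`, `chebi:CHEBI:29987`).
Rejection is a value with a reason (`no_xref`, `unknown_datasource`,
`unknown_type`), never an error — missing xrefs are the dominant cause of
semantic-layer exclusion in real corpora. Two drawn nodes sharing one
identifier resolve to the *same* IRI with two labels; label-based queries
then return one row per label, which is deliberate (it reproduces how
row-based query results are reported).

**2. Edge bundling.** Lines can carry anchors — addressable points along
the line — and other lines may terminate on them. That is how catalysis
is drawn: an enzyme's line ends on the anchor of a conversion line.
`bundle_edges()` groups each spine line with its attached legs; a leg
never also forms its own bundle, and a leg attached to another leg joins
the transitive spine.

**3. Bundle classification.** The spine's end arrowhead is looked up in
the arrowhead map (a CSV config shipped in `inst/extdata/`, editable so
the canonical upstream mapping table can be dropped in). Directed classes
take the start node as source, end node as target. Each regulator leg
(catalysis, stimulation, inhibition tokens) becomes its own interaction
whose target is the *spine interaction's IRI* and whose participants are
exactly the regulator and the spine IRI. Plain legs and directional
non-regulator legs become extra participants of the spine, while the
single source/target slots keep the spine endpoints — so multi-input
reactions stay shape-valid at the cost of not distinguishing extra inputs
from extra outputs, a known simplification.

Decisions the drawing conventions leave open were settled as follows:

* a token on the start point only means the line was drawn backwards:
  direction is reversed;
* tokens on both ends (double-headed lines) split into two directed
  interactions sharing participants, and the event is noted for curation;
* an unmapped token degrades to a generic `DirectedInteraction` (any
  token is presumed directional) and is logged `unsupported_arrowhead`;
* a line ending on a free text label, on an unresolved node, on an
  unresolved group, or on nothing is rejected with `label_endpoint`,
  `participant_unresolved`, `group_unresolved` or `dangling_endpoint`
  respectively.

**4. Groups and complexes.** A group of style `Complex` with at least two
resolved members yields one `ComplexBinding` whose participants are the
complex node plus all members, and one undirected pairwise connection per
unordered member pair — `choose(n, 2)` of them — which keeps members
mutually reachable. The pairwise connections are emitted as generic
undirected interactions; whether they should instead be typed `Binding`
is genuinely ambiguous in the source conventions, and generic typing is
the conservative choice (they count as non-specified, not as binding
events). If no identified Complex datanode backs the group, the complex
node is logged `unannotated_complex` but the binding is still emitted
around a minted IRI, so membership stays queryable. Style `Group` (a
user-drawn box, very often a set of isoenzymes) is *not* a biological
complex: endpoints on it are rejected by default. With
`expand_isoenzymes = TRUE` a regulator leg from such a group is instead
duplicated once per resolved member — useful, but off by default because
user groups can mean many things.

Pathway-link nodes are typed only as plain `wp:Datanode`, not as
`wp:Pathway`, reproducing a quirk of the upstream data model so that
outputs remain directly comparable with published tables; the conversion
log records them.

## IRI minting

Interaction IRIs follow the observable upstream pattern
`<WPID>_r<revision>/WP/Interaction/<graphId>`, complex bindings
`<WPID>_r<revision>/ComplexBinding/<groupGraphId>`, and graphical-layer
elements `<WPID>_r<revision>/<Kind>/<graphId>`. Reusing drawn `graphId`s
as IRI local names keeps every output row traceable to the drawing. The
namespace each CURIE prefix expands to is configurable via
`vocab_namespaces()`; Turtle export/import uses that table.

## Reports and queries

`datanode_stats()` counts hierarchy-inclusively (a protein counts as
`Protein`, `GeneProduct` and `Datanode`), with an `exclusive` flag for
most-specific counting, and tracks drawn-only nodes per declared type.
`interaction_stats()` maintains the identity *directed + non-directed =
total* on every input and reports percentages to one decimal, recomputed
from the counts. `unconverted_interactions()` emits one curation row per
labelled endpoint of each drawn-only line. `heuristic_flags()` applies
two drawing-quality rules of thumb: an undirected line between two
metabolites is probably an untyped conversion, and a conversion between
two different proteins is probably a mis-annotation.

`direct_neighbors()` answers up/downstream questions (upstream = the
query node is the target), excluding undirected edges; label matching is
exact by default with an opt-in case-insensitive mode.
`catalysis_table()` lists enzyme / substrate / product rows, with
`strict = TRUE` restricting to reactions explicitly typed `Conversion`.
`enzyme_order()` joins that table on shared metabolites — enzyme E1
producing what E2 consumes acts upstream of E2 — and `reachable()` gives
the depth-limited transitive closure, passing through catalysis so an
enzyme reaches the products of the reactions it drives. Traversal through
undirected edges is not done, and traversal through complex membership is
off by default (`through_complexes = TRUE` opts in), since group
semantics are the least settled part of the drawing conventions.

## Synthetic data: what it shows and what it does not

Two kinds of generated input back the test suite and the acceptance
script; both are built in code at run time.

The **typed fixture corpus** (`nine_type_corpus()`,
`make_fixture()`) draws each interaction class in every notation that can
express it, plus the classic failure scenarios (label endpoints,
unannotated nodes, isoenzyme groups, double-headed lines, multi-leg
reactions), each with a machine-checkable expected outcome. Fixtures use
real identifiers (MECP2, the ganglioside chain) so they double as
documentation.

The **random pathway generator** (`make_random_pathway()`) draws
`node_count` typed nodes, annotates each with probability
`annotation_rate`, and connects ordered pairs at `edge_density` with a
mix of directed arrowheads and plain lines. Defaults (10 nodes, density
0.15, annotation 0.8) sit in the range of small curated human pathways,
where most nodes carry xrefs and connectivity is sparse. It is seeded,
byte-reproducible, and restores the session's random state. It emulates
*structure*, not content: no anchors, no groups, no coordinates of
visual meaning, no realistic label vocabulary, and annotation failures
are independent coin flips rather than the correlated gaps (whole
complexes, lipid species missing from databases) seen in real corpora.
Property tests on it therefore demonstrate conversion bookkeeping —
conservation of edges, reachability agreement with a brute-force oracle
on the drawing, shape conformance — not fidelity to any particular
database release.

Two **synthetic reconstructions** (`synthetic_mecp2_pathway()`,
`synthetic_sphingolipid_pathway()`) rebuild, from their published
interaction tables, the MECP2 regulatory neighborhood and the catalyzed
ganglioside conversion chain. They reproduce the published query results
(3 upstream / 7 downstream neighbor rows; 5 conversion-typed catalysis
rows, with the plain-arrow GD3→GD2 step visible only without strict
typing) and demonstrate the duplicate-label behaviour. They contain only
the neighborhood the tables describe, so whole-pathway statistics
computed on them will not match the full originals — they are
demonstrations of the query machinery, not copies of the pathways.

## Problem sizes and tolerances

The shipped checks run at deliberately small scale: 200 random pathways
of 8 nodes for the conservation sweep, 25 pathways of up to 20 nodes for
the reachability/oracle comparison, 30 pathways of 20 nodes for the
annotation-rate calibration (checked within three standard errors of the
binomial expectation). These sizes give stable results in seconds on one
CPU; all of them scale linearly if larger sweeps are wanted. Percentages
are compared after rounding to one decimal, the precision at which such
tables are conventionally printed.

## Known limitations

* Direction is never *inferred*: an undirected metabolite–metabolite line
  is flagged for curation, not silently promoted to a conversion.
* Extra inputs/outputs of multi-leg reactions are recorded as plain
  participants; their input/output role is not preserved.
* The Turtle reader supports the subset the package writes plus common
  dump constructs (prefixes, `a`, `;`/`,` lists, tagged/typed literals);
  blank nodes and multi-line literals are not supported.
* Identifier cross-mapping between datasources (e.g. Entrez to Ensembl)
  is out of scope; nodes resolve to whatever datasource they are drawn
  with.
* Shape validation implements node-kind and arity constraints natively;
  it is not a full ShEx engine (no recursion, no value sets), which is
  why the shapes are also exported as `.shex` text for external engines.
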