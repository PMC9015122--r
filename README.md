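# pathsem

Semantic harmonization of biological pathway diagrams.

Pathway databases such as WikiPathways store pathways as *drawings*
(GPML: boxes, lines, arrowheads, anchors, groups, text labels). The
biology — "GD3 is converted to GD2, catalyzed by B4GALNT1", "HDAC1
influences MECP2" — is in the picture, but not in a form software can
query. `pathsem` converts a GPML drawing into a two-layer graph:

* a **graphical layer** holding every drawn element verbatim, and
* a **semantic layer** holding only identifiable biology: datanodes
  resolved to database identifiers (`ensembl:…`, `hmdb:…`,
  `chebi:CHEBI:…`) and interactions harmonized across the WikiPathways,
  MIM and SBGN arrowhead notations into nine classes —

```
Interaction
├── DirectedInteraction          (exactly one source, one target)
│   ├── Conversion
│   ├── Inhibition
│   ├── Catalysis                (enzyme → the reaction it drives)
│   ├── Stimulation
│   └── TranscriptionTranslation
└── Binding                      (symmetric; no source/target)
    └── ComplexBinding
```

Catalysis is recognized the way it is drawn: a line from the enzyme
ending on an *anchor* of the reaction line. Complex-style groups expand
into one `ComplexBinding` plus `choose(n, 2)` pairwise member
connections. Everything that cannot be interpreted — lines to text
labels, nodes without xrefs, user-defined groups, dangling ends — is
rejected with a machine-readable reason in a conversion log, the basis
of curation reports. Per-class shape constraints (two or more
participants; exactly one source and target for directed classes,
forbidden for bindings) are validated natively and exportable as ShEx.

## Worked example

A conversion with a catalysis leg, drawn in MIM notation:

```r
library(pathsem)

fx <- make_fixture(fixture_spec("Catalysis", "MIM"))
layers <- build_semantic_layer(fx$pathway)
layers$log
#> <conversion_log: 3/3 nodes accepted, 2/2 edges accepted>

interaction_stats(layers$wp, layers$gpml)
#> interactions: 2 total, 2 directed (100.0%), 0 non-directed (0.0%), 0 non-specified (0.0%)
#> drawn-only interactions: 0 of 2 drawn (100.0% converted)
#>   Interaction               2
#>   DirectedInteraction       2
#>   Conversion                1
#>   Catalysis                 1
```

The two drawn lines became a `Conversion` (GD3 → GD2) and a `Catalysis`
whose source is the enzyme and whose target is the conversion's IRI.

On the bundled synthetic reconstruction of the ganglioside conversion
chain (built in code from its published interaction table):

```r
s <- build_semantic_layer(synthetic_sphingolipid_pathway())
catalysis_table(s$wp, strict = TRUE)[, c("substrate_label", "product_label", "enzyme")]
#>    substrate_label    product_label                  enzyme
#> 1              GD3 O-Acetylated GD3 ensembl:ENSG00000169359
#> 2           LacCer              GM3 ensembl:ENSG00000115525
#> 3 Lactosylceramide              GM3 ensembl:ENSG00000115525
#> 4             GT1b            GQ1bA ensembl:ENSG00000101638
#> 5              GD2             GD1b ensembl:ENSG00000235863

enzyme_order(s$wp)
#>           upstream_enzyme       downstream_enzyme shared_metabolite
#> 1 ensembl:ENSG00000135454 ensembl:ENSG00000235863  hmdb:HMDB0004925
```

Five conversion-typed catalysis rows (one reaction appears twice because
its substrate is drawn under two labels), and the enzyme ordering:
B4GALNT1 produces the GD2 that B3GALT4 consumes, so anything acting on
B4GALNT1 also affects the downstream conversion. `direct_neighbors()`
answers the analogous up/downstream question for signaling
(`direct_neighbors(wp, "MECP2", "upstream")`), and `reachable()` gives
depth-limited closures, passing through catalysis links.

## Command line

A thin launcher at `inst/cli/pathsem.R` exposes the same pipeline:

```sh
Rscript inst/cli/pathsem.R convert WP1423_r94289.gpml --out out/   # Turtle x2 + log CSVs
Rscript inst/cli/pathsem.R validate out.gpml        # exit 1 on shape violations
Rscript inst/cli/pathsem.R stats dump_wp.ttl --gpml-layer dump_gpml.ttl
Rscript inst/cli/pathsem.R neighbors p.gpml --query MECP2 --direction upstream
```

`stats`, `curate` and friends accept either GPML or Turtle dumps, so
release-scale statistics can be recomputed from an official RDF dump.
Every run writes a `run_summary.json` with input hashes and the
effective configuration; identical inputs give byte-identical outputs.

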