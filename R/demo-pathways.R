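#' Synthetic reconstructions of the two published use-case neighborhoods
#'
#' These builders construct, in code, small GPML pathways that reproduce
#' the published query results for the two worked examples: the direct
#' regulatory neighborhood of MECP2 (the Rett-syndrome gene, from the
#' MECP2 pathways pathway) and the catalyzed conversion chain of ganglio
#' sphingolipid metabolism. They are *synthetic*: only the drawn content
#' needed by the interaction tables is reconstructed, not the full
#' pathways, so whole-pathway statistics will not match the originals.
#' They exist so the network queries can be demonstrated and tested
#' offline with realistic identifiers.
#'
#' @name demo_pathways
NULL

#' @rdname demo_pathways
#' @details `synthetic_mecp2_pathway()` rebuilds the MECP2 neighborhood:
#'   three gene products upstream (HNRNPF, MYT1, HNRNPH1) and four directed
#'   interactions downstream, three of whose targets are drawn twice under
#'   different labels (glutamate/Glutamate, CREB1/CREB, GRIA1/AMPA) but
#'   share one identifier, which is why label-based neighbor queries return
#'   seven downstream rows.
#' @return A [gpml_pathway()].
#' @export
synthetic_mecp2_pathway <- function() {
  gene <- function(id, label, ensg, group_ref = "") {
    gpml_datanode(id, text_label = label, type = "GeneProduct",
                  xref_datasource = "Ensembl", xref_id = ensg,
                  group_ref = group_ref)
  }
  nodes <- list(
    gene("mecp2", "MECP2", "ENSG00000169057"),
    # upstream regulators
    gene("hnrnpf", "HNRNPF", "ENSG00000169813"),
    gene("myt1", "MYT1", "ENSG00000196132"),
    gene("hnrnph1", "HNRNPH1", "ENSG00000169045"),
    # downstream targets; duplicated drawn nodes share one identifier
    gpml_datanode("glu1", text_label = "glutamate", type = "Metabolite",
                  xref_datasource = "ChEBI", xref_id = "CHEBI:29987"),
    gpml_datanode("glu2", text_label = "Glutamate", type = "Metabolite",
                  xref_datasource = "ChEBI", xref_id = "CHEBI:29987"),
    gene("creb1", "CREB1", "ENSG00000118260"),
    gene("creb2", "CREB", "ENSG00000118260"),
    gene("bdnf", "BDNF", "ENSG00000176697"),
    gene("gria1", "GRIA1", "ENSG00000155511"),
    gene("ampa", "AMPA", "ENSG00000155511")
  )
  arrow <- function(id, from, to) fx_line(id, from, to, head = "Arrow")
  edges <- list(
    arrow("id1c3def3d", "hnrnpf", "mecp2"),
    arrow("id8e7af5c", "myt1", "mecp2"),
    arrow("ida6a9fa9d", "hnrnph1", "mecp2"),
    arrow("id4f207df3", "mecp2", "glu1"),
    arrow("ida4a8b443", "mecp2", "creb1"),
    arrow("id4a259c62", "mecp2", "bdnf"),
    arrow("id3bcd32", "mecp2", "gria1")
  )
  gpml_pathway(wp_id = "WP3584", revision = 96364L,
               title = "MECP2 neighborhood (synthetic reconstruction)",
               organism = "Homo sapiens", nodes = nodes, edges = edges)
}

#' @rdname demo_pathways
#' @details `synthetic_sphingolipid_pathway()` rebuilds the catalyzed
#'   ganglioside conversion chain: four conversion-typed reactions
#'   (LacCer->GM3 with a doubly-labelled substrate, GD3->O-acetylated GD3,
#'   GD2->GD1b, GT1b->GQ1b) each catalyzed by its enzyme, plus the
#'   GD3->GD2 step drawn with a plain arrow (so it is a generic directed
#'   interaction, not a conversion) and catalyzed by B4GALNT1, and one
#'   doubly-glycosylated metabolite with no database identifier.
#' @export
synthetic_sphingolipid_pathway <- function() {
  met <- function(id, label, acc, ds = "HMDB") {
    gpml_datanode(id, text_label = label, type = "Metabolite",
                  xref_datasource = ds, xref_id = acc)
  }
  enz <- function(id, label, ensg) {
    gpml_datanode(id, text_label = label, type = "GeneProduct",
                  xref_datasource = "Ensembl", xref_id = ensg)
  }
  nodes <- list(
    met("laccer1", "Lactosylceramide", "HMDB0006750"),
    met("laccer2", "LacCer", "HMDB0006750"),
    met("gm3", "GM3", "HMDB0004844"),
    met("gd3", "GD3", "HMDB0004913"),
    met("oagd3", "O-Acetylated GD3", "73427362", ds = "PubChem-compound"),
    met("gd2", "GD2", "HMDB0004925"),
    met("gd1b", "GD1b", "HMDB0004926"),
    met("gt1b", "GT1b", "HMDB0004927"),
    met("gq1b", "GQ1bA", "HMDB0004928"),
    # modified with two sugars; absent from the reference databases
    gpml_datanode("galgm1b", text_label = "Gal-GlcNAc-GM1b",
                  type = "Metabolite"),
    enz("st3gal5", "ST3GAL5", "ENSG00000115525"),
    enz("casd1", "CASD1", "ENSG00000169359"),
    enz("b3galt4", "B3GALT4", "ENSG00000235863"),
    enz("st8sia5", "ST8SIA5", "ENSG00000101638"),
    enz("b4galnt1", "B4GALNT1", "ENSG00000135454")
  )
  conv <- function(id, from, to, anchor, head = "mim-conversion") {
    fx_line(id, from, to, head = head,
            anchors = list(gpml_anchor(anchor, 0.5)))
  }
  cat_leg <- function(id, enzyme, anchor) {
    fx_line(id, enzyme, anchor, head = "mim-catalysis")
  }
  edges <- list(
    conv("idb121743e", "laccer1", "gm3", "anc1"),
    cat_leg("cat1", "st3gal5", "anc1"),
    conv("id5f3f21f", "gd3", "oagd3", "anc2"),
    cat_leg("cat2", "casd1", "anc2"),
    conv("idde73da53", "gd2", "gd1b", "anc3"),
    cat_leg("cat3", "b3galt4", "anc3"),
    conv("idc09b2721", "gt1b", "gq1b", "anc4"),
    cat_leg("cat4", "st8sia5", "anc4"),
    # drawn with a plain arrow: directed but not conversion-typed
    conv("idgd3gd2", "gd3", "gd2", "anc5", head = "Arrow"),
    cat_leg("cat5", "b4galnt1", "anc5")
  )
  gpml_pathway(wp_id = "WP1423", revision = 94289L,
               title = "Ganglio sphingolipid metabolism (synthetic reconstruction)",
               organism = "Homo sapiens", nodes = nodes, edges = edges)
}
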