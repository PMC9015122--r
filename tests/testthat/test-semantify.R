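test_that("datanode resolution mints identifier IRIs and typed rejections", {
  reg <- default_datasource_registry()
  r <- resolve_datanode(gpml_datanode("n1", "MECP2", "GeneProduct",
                                      "Ensembl", "ENSG00000169057"), reg)
  expect_true(r$accepted)
  expect_equal(r$iri, "ensembl:ENSG00000169057")
  expect_equal(r$type_class, "wp:GeneProduct")

  r <- resolve_datanode(gpml_datanode("n2", "GD3", "Metabolite",
                                      "HMDB", "HMDB0004913"), reg)
  expect_equal(r$iri, "hmdb:HMDB0004913")

  r <- resolve_datanode(gpml_datanode("n3", "glutamate", "Metabolite",
                                      "ChEBI", "29987"), reg)
  expect_equal(r$iri, "chebi:CHEBI:29987")

  r <- resolve_datanode(gpml_datanode("n4", "Gal-GlcNAc-GM1b",
                                      "Metabolite"), reg)
  expect_false(r$accepted)
  expect_equal(r$reason, "no_xref")

  r <- resolve_datanode(gpml_datanode("n5", "x", "Protein",
                                      "MadeUpDB", "123"), reg)
  expect_equal(r$reason, "unknown_datasource")

  r <- resolve_datanode(gpml_datanode("n6", "x", "Unknown",
                                      "Ensembl", "ENSG1"), reg)
  expect_equal(r$reason, "unknown_type")
})

test_that("edges bundle via anchors; unused anchors stay singletons", {
  fx <- make_fixture(fixture_spec("Catalysis", "MIM"))
  b <- bundle_edges(fx$pathway)
  expect_length(b, 1)
  expect_equal(b[[1]]$spine$graph_id, "e1")
  expect_length(b[[1]]$legs, 1)
  expect_equal(b[[1]]$legs[[1]]$edge$graph_id, "e2")

  single <- make_fixture(fixture_spec("Conversion", "MIM"))$pathway
  b <- bundle_edges(single)
  expect_length(b, 1)
  expect_length(b[[1]]$legs, 0)

  # two independent lines each carrying an unused anchor
  p <- gpml_pathway(nodes = list(
    gpml_datanode("n1", "A", "Protein", "Ensembl", "E1"),
    gpml_datanode("n2", "B", "Protein", "Ensembl", "E2"),
    gpml_datanode("n3", "C", "Protein", "Ensembl", "E3"),
    gpml_datanode("n4", "D", "Protein", "Ensembl", "E4")),
    edges = list(
      gpml_edge("e1", list(edge_point("n1"), edge_point("n2", "Arrow")),
                anchors = list(gpml_anchor("a1"))),
      gpml_edge("e2", list(edge_point("n3"), edge_point("n4", "Arrow")),
                anchors = list(gpml_anchor("a2")))))
  b <- bundle_edges(p)
  expect_length(b, 2)
  expect_true(all(vapply(b, function(x) length(x$legs), 1L) == 0))
})

test_that("inhibition lines harmonize identically across notations", {
  layers <- lapply(c("WP", "MIM", "SBGN"), function(no) {
    build_semantic_layer(make_fixture(fixture_spec("Inhibition",
                                                   no))$pathway)
  })
  types <- lapply(layers, function(l)
    match_triples(l$wp)[c("subject", "predicate", "object")])
  expect_equal(types[[2]], types[[1]])
  expect_equal(types[[3]], types[[1]])
  one <- match_triples(layers[[1]]$wp, predicate = "rdf:type",
                       object = "wp:Inhibition")
  expect_equal(nrow(one), 1)
})

test_that("a catalyzed conversion yields conversion plus catalysis", {
  fx <- make_fixture(fixture_spec("Catalysis", "MIM"))
  layers <- build_semantic_layer(fx$pathway)
  wp <- layers$wp
  conv <- pathsem:::subjects_with(wp, "rdf:type", "wp:Conversion")
  cata <- pathsem:::subjects_with(wp, "rdf:type", "wp:Catalysis")
  expect_length(conv, 1)
  expect_length(cata, 1)
  # the catalysis targets the conversion and its participants are exactly
  # {enzyme, conversion IRI}
  expect_equal(pathsem:::objects_of(wp, cata, "wp:target"), conv)
  expect_setequal(pathsem:::objects_of(wp, cata, "wp:participants"),
                  c("ensembl:ENSG00000135454", conv))
  expect_equal(pathsem:::objects_of(wp, conv, "wp:source"),
               "hmdb:HMDB0004913")
  expect_equal(pathsem:::objects_of(wp, conv, "wp:target"),
               "hmdb:HMDB0004925")
})

test_that("plain lines become generic undirected interactions", {
  fx <- make_fixture(fixture_spec("Interaction"))
  wp <- build_semantic_layer(fx$pathway)$wp
  iri <- pathsem:::subjects_with(wp, "rdf:type", "wp:Interaction")
  expect_length(iri, 1)
  expect_length(pathsem:::objects_of(wp, iri, "wp:source"), 0)
  expect_length(pathsem:::objects_of(wp, iri, "wp:target"), 0)
  expect_length(pathsem:::objects_of(wp, iri, "wp:participants"), 2)
})

test_that("problem drawings are rejected with machine-readable reasons", {
  lab <- build_semantic_layer(make_fixture(fixture_spec("label_edge"))$pathway)
  expect_equal(lab$log$edges$status, "rejected")
  expect_equal(lab$log$edges$reason, "label_endpoint")

  un <- build_semantic_layer(
    make_fixture(fixture_spec("unannotated_node"))$pathway)
  expect_equal(un$log$edges$reason, "participant_unresolved")
  expect_true("no_xref" %in% un$log$nodes$reason)

  dangling <- gpml_pathway(nodes = list(
    gpml_datanode("n1", "A", "Protein", "Ensembl", "E1")),
    edges = list(gpml_edge("e1", list(edge_point("n1"),
                                      edge_point("", "Arrow")))))
  dl <- build_semantic_layer(dangling)
  expect_equal(dl$log$edges$reason, "dangling_endpoint")

  iso <- build_semantic_layer(
    make_fixture(fixture_spec("isoenzyme_group"))$pathway)
  expect_true("group_unresolved" %in% iso$log$edges$reason)
})

test_that("unmapped arrowheads degrade to generic directed interactions", {
  p <- gpml_pathway(nodes = list(
    gpml_datanode("n1", "A", "Protein", "Ensembl", "E1"),
    gpml_datanode("n2", "B", "Protein", "Ensembl", "E2")),
    edges = list(gpml_edge("e1", list(
      edge_point("n1"), edge_point("n2", "future-arrowhead")))))
  layers <- build_semantic_layer(p)
  iri <- pathsem:::subjects_with(layers$wp, "rdf:type",
                                 "wp:DirectedInteraction")
  expect_length(iri, 1)
  expect_match(paste(layers$log$notes, collapse = " "),
               "unsupported_arrowhead")
  expect_equal(layers$log$edges$status, "accepted")
})

test_that("double-headed lines split into two directed interactions", {
  fx <- make_fixture(fixture_spec("double_headed"))
  layers <- build_semantic_layer(fx$pathway)
  di <- pathsem:::subjects_with(layers$wp, "rdf:type",
                                "wp:DirectedInteraction")
  expect_length(di, 2)
  srcs <- sort(unname(vapply(di, function(i)
    pathsem:::objects_of(layers$wp, i, "wp:source"), character(1))))
  tgts <- sort(unname(vapply(di, function(i)
    pathsem:::objects_of(layers$wp, i, "wp:target"), character(1))))
  expect_equal(srcs, tgts)  # each node is source of one, target of the other
  expect_match(paste(layers$log$notes, collapse = " "), "double-headed")
})

test_that("an arrowhead on the start point reverses the direction", {
  p <- gpml_pathway(nodes = list(
    gpml_datanode("n1", "A", "Protein", "Ensembl", "E1"),
    gpml_datanode("n2", "B", "Protein", "Ensembl", "E2")),
    edges = list(gpml_edge("e1", list(
      edge_point("n1", arrow_head = "Arrow"), edge_point("n2")))))
  wp <- build_semantic_layer(p)$wp
  iri <- pathsem:::subjects_with(wp, "rdf:type", "wp:DirectedInteraction")
  expect_equal(pathsem:::objects_of(wp, iri, "wp:source"), "ensembl:E2")
  expect_equal(pathsem:::objects_of(wp, iri, "wp:target"), "ensembl:E1")
})

test_that("complexes expand into a binding plus all member pairs", {
  fx <- make_fixture(fixture_spec("ComplexBinding"))
  layers <- build_semantic_layer(fx$pathway)
  wp <- layers$wp
  cb <- pathsem:::subjects_with(wp, "rdf:type", "wp:ComplexBinding")
  expect_length(cb, 1)
  parts <- pathsem:::objects_of(wp, cb, "wp:participants")
  expect_length(parts, 4)  # complex node + 3 members
  expect_length(pathsem:::objects_of(wp, cb, "wp:source"), 0)

  pairs <- setdiff(pathsem:::subjects_with(wp, "rdf:type", "wp:Interaction"),
                   cb)
  expect_length(pairs, choose(3, 2))
  # symmetry: each pair connection is undirected with two participants
  for (pr in pairs) {
    expect_length(pathsem:::objects_of(wp, pr, "wp:participants"), 2)
    expect_length(pathsem:::objects_of(wp, pr, "wp:source"), 0)
  }
  # the unannotated complex node is logged
  expect_true("unannotated_complex" %in% layers$log$nodes$reason)
})

test_that("complex member order does not change the emitted triples", {
  fx <- make_fixture(fixture_spec("ComplexBinding"))
  p2 <- fx$pathway
  p2$nodes <- rev(p2$nodes)
  t1 <- match_triples(build_semantic_layer(fx$pathway)$wp)
  t2 <- match_triples(build_semantic_layer(p2)$wp)
  expect_equal(t2, t1)
})

test_that("single-member complexes are degenerate, not bindings", {
  p <- gpml_pathway(nodes = list(
    gpml_datanode("n1", "A", "Protein", "Ensembl", "E1",
                  group_ref = "grp1")),
    groups = list(gpml_group("grp1", "g1", "Complex")))
  layers <- build_semantic_layer(p)
  expect_length(pathsem:::subjects_with(layers$wp, "rdf:type",
                                        "wp:ComplexBinding"), 0)
  expect_equal(layers$log$groups$status, "degenerate")
})

test_that("a complex catalyzing a reaction is the catalysis source", {
  # three sulfotransferases in a complex drive a conversion
  enz <- function(id, label, acc) {
    gpml_datanode(id, label, "Protein", "Ensembl", acc, group_ref = "grp1")
  }
  p <- gpml_pathway(nodes = list(
    enz("s1", "SULT1A1", "ENSG00000196502"),
    enz("s2", "SULT1E1", "ENSG00000109193"),
    enz("s3", "SULT2A1", "ENSG00000105398"),
    gpml_datanode("m1", "cis-4-hydroxytamoxifen", "Metabolite", "HMDB",
                  "HMDB0060948"),
    gpml_datanode("m2", "trans-4-sulfoxytamoxifen", "Metabolite", "HMDB",
                  "HMDB0062512")),
    edges = list(
      gpml_edge("e1", list(edge_point("m1"),
                           edge_point("m2", "mim-conversion")),
                anchors = list(gpml_anchor("a1"))),
      gpml_edge("e2", list(edge_point("g1"),
                           edge_point("a1", "mim-catalysis")))),
    groups = list(gpml_group("grp1", "g1", "Complex")))
  wp <- build_semantic_layer(p)$wp
  cata <- pathsem:::subjects_with(wp, "rdf:type", "wp:Catalysis")
  expect_length(cata, 1)
  src <- pathsem:::objects_of(wp, cata, "wp:source")
  expect_match(src, "/Complex/grp1$")
  expect_length(pathsem:::subjects_with(wp, "rdf:type",
                                        "wp:ComplexBinding"), 1)
})

test_that("isoenzyme expansion emits one catalysis per group member", {
  fx <- make_fixture(fixture_spec("isoenzyme_group"))
  off <- build_semantic_layer(fx$pathway)
  expect_length(pathsem:::subjects_with(off$wp, "rdf:type", "wp:Catalysis"),
                0)
  on <- build_semantic_layer(fx$pathway, expand_isoenzymes = TRUE)
  cata <- pathsem:::subjects_with(on$wp, "rdf:type", "wp:Catalysis")
  expect_length(cata, 2)
})

test_that("multi-leg reactions keep single source/target slots", {
  fx <- make_fixture(fixture_spec("multi_leg"))
  layers <- build_semantic_layer(fx$pathway)
  conv <- pathsem:::subjects_with(layers$wp, "rdf:type", "wp:Conversion")
  expect_length(pathsem:::objects_of(layers$wp, conv, "wp:source"), 1)
  expect_length(pathsem:::objects_of(layers$wp, conv, "wp:target"), 1)
  expect_length(pathsem:::objects_of(layers$wp, conv, "wp:participants"), 3)
  # the merged leg still counts as converted
  expect_true(all(layers$log$edges$status == "accepted"))
})

test_that("pathway-link nodes get the plain-datanode typing quirk", {
  p <- gpml_pathway(nodes = list(
    gpml_datanode("n1", "Apoptosis", "Pathway", "WikiPathways", "WP254")))
  wp <- build_semantic_layer(p)$wp
  expect_equal(pathsem:::objects_of(wp, "wikipathways:WP254", "rdf:type"),
               "wp:Datanode")
})

test_that("an empty pathway yields only the pathway resources", {
  layers <- build_semantic_layer(gpml_pathway(wp_id = "WP1", title = "t"))
  expect_equal(unique(match_triples(layers$wp)$subject),
               "wikipathways:WP1_r0")
  expect_equal(unique(match_triples(layers$gpml)$subject), "WP1_r0")
})

test_that("conversion is conserved: every edge is accepted or rejected once", {
  for (seed in 1:10) {
    p <- make_random_pathway(node_count = 10, edge_density = 0.2,
                             annotation_rate = 0.6, seed = seed)
    layers <- build_semantic_layer(p)
    expect_equal(sort(layers$log$edges$graph_id),
                 sort(vapply(p$edges, `[[`, "", "graph_id")))
    expect_false(any(duplicated(layers$log$edges$graph_id)))
  }
})

test_that("the semantic layer links back to the drawing via isAbout", {
  layers <- build_semantic_layer(synthetic_sphingolipid_pathway())
  wp_inter <- pathsem:::resources_of_class(layers$wp, "wp:Interaction")
  about <- match_triples(layers$gpml, predicate = "wp:isAbout")
  expect_true(all(wp_inter %in% about$object))
})
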