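chain_pathway <- function() {
  # A -> B -> C with plain arrows
  nodes <- lapply(1:3, function(i)
    gpml_datanode(sprintf("n%d", i), c("A", "B", "C")[i], "GeneProduct",
                  "Ensembl", sprintf("E%d", i)))
  edges <- list(
    gpml_edge("e1", list(edge_point("n1"), edge_point("n2", "Arrow"))),
    gpml_edge("e2", list(edge_point("n2"), edge_point("n3", "Arrow"))))
  gpml_pathway(nodes = nodes, edges = edges)
}

test_that("neighbor queries split by direction and exclude undirected", {
  wp <- build_semantic_layer(chain_pathway())$wp
  up <- direct_neighbors(wp, "B", "upstream")
  dn <- direct_neighbors(wp, "B", "downstream")
  expect_equal(up$source_label, "A")
  expect_equal(dn$target_label, "C")
  # B has no outgoing edge in a 2-node A -> B drawing
  p2 <- gpml_pathway(nodes = list(
    gpml_datanode("n1", "A", "GeneProduct", "Ensembl", "E1"),
    gpml_datanode("n2", "B", "GeneProduct", "Ensembl", "E2")),
    edges = list(gpml_edge("e1", list(edge_point("n1"),
                                      edge_point("n2", "Arrow")))))
  wp2 <- build_semantic_layer(p2)$wp
  expect_equal(nrow(direct_neighbors(wp2, "B", "downstream")), 0)
  expect_message(out <- direct_neighbors(wp2, "nosuchnode"), "no node")
  expect_equal(nrow(out), 0)
})

test_that("upstream and downstream rows are disjoint on acyclic drawings", {
  for (seed in 1:5) {
    p <- make_random_pathway(node_count = 8, edge_density = 0.2,
                             annotation_rate = 1, seed = seed)
    wp <- build_semantic_layer(p)$wp
    for (q in c("G001", "P002", "M003")) {
      up <- suppressMessages(direct_neighbors(wp, q, "upstream"))
      dn <- suppressMessages(direct_neighbors(wp, q, "downstream"))
      if (nrow(up) > 0 && nrow(dn) > 0) {
        expect_equal(nrow(merge(up, dn)), 0)
      }
    }
  }
})

test_that("the MECP2 reconstruction answers with 3 upstream / 7 downstream", {
  wp <- build_semantic_layer(synthetic_mecp2_pathway())$wp
  up <- direct_neighbors(wp, "MECP2", "upstream")
  dn <- direct_neighbors(wp, "MECP2", "downstream")
  expect_equal(nrow(up), 3)
  expect_setequal(up$source_label, c("HNRNPF", "MYT1", "HNRNPH1"))
  expect_equal(nrow(dn), 7)
  # duplicated drawn nodes sharing an identifier yield one row per label
  expect_setequal(dn$target_label,
                  c("glutamate", "Glutamate", "CREB1", "CREB", "BDNF",
                    "GRIA1", "AMPA"))
  expect_true(all(dn$source == "ensembl:ENSG00000169057"))
})

test_that("case-insensitive label matching is available", {
  wp <- build_semantic_layer(synthetic_mecp2_pathway())$wp
  expect_equal(nrow(suppressMessages(direct_neighbors(wp, "mecp2",
                                                      "upstream"))), 0)
  expect_equal(nrow(direct_neighbors(wp, "mecp2", "upstream",
                                     ignore_case = TRUE)), 3)
})

test_that("the catalysis table reports enzyme, substrate and product", {
  fx <- make_fixture(fixture_spec("Catalysis", "MIM"))
  wp <- build_semantic_layer(fx$pathway)$wp
  ct <- catalysis_table(wp)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$enzyme, "ensembl:ENSG00000135454")
  expect_equal(ct$substrate_label, "GD3")
  expect_equal(ct$product_label, "GD2")

  # no catalysis at all
  wp2 <- build_semantic_layer(chain_pathway())$wp
  expect_equal(nrow(catalysis_table(wp2)), 0)
})

test_that("the sphingolipid reconstruction yields the five strict rows", {
  wp <- build_semantic_layer(synthetic_sphingolipid_pathway())$wp
  strict <- catalysis_table(wp, strict = TRUE)
  expect_equal(nrow(strict), 5)
  expect_setequal(
    paste(strict$substrate_label, strict$product_label, sep = "->"),
    c("Lactosylceramide->GM3", "LacCer->GM3", "GD3->O-Acetylated GD3",
      "GD2->GD1b", "GT1b->GQ1bA"))
  # the plain-arrow GD3 -> GD2 step appears only without strict typing
  all_rows <- catalysis_table(wp)
  expect_equal(nrow(all_rows), 6)
  expect_true("ensembl:ENSG00000135454" %in% all_rows$enzyme)
})

test_that("enzyme ordering joins catalyses on shared metabolites", {
  wp <- build_semantic_layer(synthetic_sphingolipid_pathway())$wp
  eo <- enzyme_order(wp)
  expect_equal(nrow(eo), 1)
  expect_equal(eo$upstream_enzyme, "ensembl:ENSG00000135454")   # B4GALNT1
  expect_equal(eo$downstream_enzyme, "ensembl:ENSG00000235863") # B3GALT4
  expect_equal(eo$shared_metabolite, "hmdb:HMDB0004925")        # GD2

  # single conversion: nothing to order
  fx <- make_fixture(fixture_spec("Catalysis", "MIM"))
  expect_equal(nrow(enzyme_order(build_semantic_layer(fx$pathway)$wp)), 0)
})

test_that("enzyme pairs equal the substrate-product join, also on chains", {
  # chain of 3 catalyzed conversions sharing intermediates
  met <- function(id, l, acc) gpml_datanode(id, l, "Metabolite", "HMDB", acc)
  enz <- function(id, l, acc) gpml_datanode(id, l, "Protein", "Ensembl", acc)
  conv <- function(id, from, to, anc) {
    gpml_edge(id, list(edge_point(from), edge_point(to, "mim-conversion")),
              anchors = list(gpml_anchor(anc)))
  }
  leg <- function(id, from, anc) {
    gpml_edge(id, list(edge_point(from), edge_point(anc, "mim-catalysis")))
  }
  p <- gpml_pathway(nodes = list(
    met("m1", "M1", "HMDB0000001"), met("m2", "M2", "HMDB0000002"),
    met("m3", "M3", "HMDB0000003"), met("m4", "M4", "HMDB0000004"),
    enz("p1", "EZ1", "E1"), enz("p2", "EZ2", "E2"), enz("p3", "EZ3", "E3")),
    edges = list(conv("c1", "m1", "m2", "a1"), leg("l1", "p1", "a1"),
                 conv("c2", "m2", "m3", "a2"), leg("l2", "p2", "a2"),
                 conv("c3", "m3", "m4", "a3"), leg("l3", "p3", "a3")))
  wp <- build_semantic_layer(p)$wp
  eo <- enzyme_order(wp)
  expect_equal(nrow(eo), 2)  # adjacent pairs only

  # recomputation from the catalysis table
  ct <- unique(catalysis_table(wp)[c("enzyme", "substrate", "product")])
  joined <- merge(ct, ct, by.x = "product", by.y = "substrate")
  expect_equal(nrow(joined), nrow(eo))

  # transitive closure through reachability covers the third enzyme's
  # substrate chain: EZ1 ultimately feeds all downstream metabolites
  r <- reachable(wp, "ensembl:E1", "downstream")
  expect_setequal(r, c("hmdb:HMDB0000002", "hmdb:HMDB0000003",
                       "hmdb:HMDB0000004"))
})

test_that("reachability is depth-limited and excludes the start", {
  wp <- build_semantic_layer(chain_pathway())$wp
  expect_equal(reachable(wp, "ensembl:E1", "downstream", max_depth = 0),
               character(0))
  expect_equal(reachable(wp, "ensembl:E1", "downstream", max_depth = 1),
               "ensembl:E2")
  expect_setequal(reachable(wp, "ensembl:E1", "downstream", max_depth = 2),
                  c("ensembl:E2", "ensembl:E3"))
  expect_setequal(reachable(wp, "ensembl:E3", "upstream", max_depth = 2),
                  c("ensembl:E1", "ensembl:E2"))
})

test_that("an enzyme reaches the products of the reactions it drives", {
  wp <- build_semantic_layer(synthetic_sphingolipid_pathway())$wp
  r <- reachable(wp, "ensembl:ENSG00000135454", "downstream", max_depth = 3)
  expect_true(all(c("hmdb:HMDB0004925", "hmdb:HMDB0004926") %in% r))
})

test_that("semantic-layer reachability matches the drawing-model oracle", {
  for (seed in 1:12) {
    p <- make_random_pathway(node_count = 5 + (seed * 3) %% 16,
                             edge_density = 0.15, annotation_rate = 0.8,
                             seed = seed)
    wp <- build_semantic_layer(p)$wp
    iri_map <- oracle_iri_map(p)
    if (length(iri_map) == 0) next
    start_id <- names(iri_map)[1]
    for (dir in c("downstream", "upstream")) {
      expected_ids <- oracle_reachable_drawing(p, start_id, dir)
      expected <- sort(unname(iri_map[intersect(expected_ids,
                                                names(iri_map))]))
      got <- reachable(wp, iri_map[[start_id]], dir)
      expect_equal(got, expected, info = paste(seed, dir))
    }
  }
})

test_that("complex traversal is off by default and opt-in", {
  fx <- make_fixture(fixture_spec("ComplexBinding"))
  wp <- build_semantic_layer(fx$pathway)$wp
  member <- "ensembl:ENSG00000169057"
  expect_equal(reachable(wp, member, "downstream", max_depth = 2),
               character(0))
  with_complex <- reachable(wp, member, "downstream", max_depth = 2,
                            through_complexes = TRUE)
  expect_true(length(with_complex) > 0)
})
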