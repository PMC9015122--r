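#' Seeded GPML fixtures with known ground truth
#'
#' Generates small GPML pathways for every harmonized interaction type and
#' for the classic problem scenarios (lines ending on text labels,
#' unannotated nodes, isoenzyme groups, double-headed lines, multi-leg
#' reactions), together with the conversion outcome each one must produce.
#' Identifiers are realistic (MECP2/Ensembl, GD3/HMDB) so example-level
#' tests double as documentation. All randomness is locally seeded; no
#' global random state is touched.
#'
#' @name fixtures
NULL

FIXTURE_TYPES <- c(WP_INTERACTION_CLASSES,
                   "label_edge", "unannotated_node", "isoenzyme_group",
                   "double_headed", "multi_leg")

# which notations can draw each interaction type
.FIXTURE_NOTATIONS <- list(
  Interaction = "WP",
  DirectedInteraction = "WP",
  Conversion = c("MIM", "SBGN"),
  Inhibition = c("WP", "MIM", "SBGN"),
  Catalysis = c("MIM", "SBGN"),
  Binding = "MIM",
  ComplexBinding = c("WP", "MIM", "SBGN"),
  Stimulation = c("MIM", "SBGN"),
  TranscriptionTranslation = "MIM",
  label_edge = "WP",
  unannotated_node = c("MIM", "SBGN"),
  isoenzyme_group = c("MIM", "SBGN"),
  double_headed = "WP",
  multi_leg = c("MIM", "SBGN")
)

.FIXTURE_TOKENS <- list(
  Conversion = c(MIM = "mim-conversion", SBGN = "sbgn-production"),
  Inhibition = c(WP = "TBar", MIM = "mim-inhibition",
                 SBGN = "sbgn-inhibition"),
  Catalysis = c(MIM = "mim-catalysis", SBGN = "sbgn-catalysis"),
  Stimulation = c(MIM = "mim-stimulation", SBGN = "sbgn-stimulation"),
  Binding = c(MIM = "mim-binding"),
  TranscriptionTranslation = c(MIM = "mim-transcription-translation"),
  DirectedInteraction = c(WP = "Arrow")
)

#' @rdname fixtures
#' @param interaction_type One of the nine interaction classes or the
#'   scenarios `label_edge`, `unannotated_node`, `isoenzyme_group`,
#'   `double_headed`, `multi_leg`.
#' @param notation `"WP"`, `"MIM"` or `"SBGN"`; must be valid for the type.
#' @param seed Integer seed (reserved for randomised variants; the shipped
#'   fixtures are fully deterministic).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(interaction_type, notation = NULL, seed = 1L) {
  interaction_type <- match.arg(interaction_type, FIXTURE_TYPES)
  valid <- .FIXTURE_NOTATIONS[[interaction_type]]
  if (is.null(notation)) notation <- valid[1]
  if (!notation %in% valid) {
    stop(sprintf("notation %s cannot draw %s (valid: %s)", notation,
                 interaction_type, paste(valid, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(interaction_type = interaction_type, notation = notation,
                 seed = as.integer(seed)), class = "fixture_spec")
}

# standard characters used across fixtures
.FX <- list(
  gene_a = list(label = "MECP2", type = "GeneProduct",
                ds = "Ensembl", id = "ENSG00000169057"),
  gene_b = list(label = "CREB1", type = "GeneProduct",
                ds = "Ensembl", id = "ENSG00000118260"),
  gene_c = list(label = "BDNF", type = "GeneProduct",
                ds = "Ensembl", id = "ENSG00000176697"),
  met_a = list(label = "GD3", type = "Metabolite",
               ds = "HMDB", id = "HMDB0004913"),
  met_b = list(label = "GD2", type = "Metabolite",
               ds = "HMDB", id = "HMDB0004925"),
  enzyme = list(label = "B4GALNT1", type = "Protein",
                ds = "Ensembl", id = "ENSG00000135454")
)

fx_node <- function(graph_id, spec, group_ref = "") {
  gpml_datanode(graph_id, text_label = spec$label, type = spec$type,
                xref_datasource = spec$ds, xref_id = spec$id,
                group_ref = group_ref)
}

fx_line <- function(graph_id, from, to, head = "", tail = "",
                    anchors = list()) {
  gpml_edge(graph_id, points = list(
    edge_point(graph_ref = from, arrow_head = tail, x = 0, y = 0),
    edge_point(graph_ref = to, arrow_head = head, x = 100, y = 0)),
    anchors = anchors)
}

#' Build one fixture pathway and its expected conversion outcome
#'
#' @param s A [fixture_spec()].
#' @return `list(pathway, expected)` where `expected` lists the interaction
#'   classes that must appear in the semantic layer
#'   (`interaction_classes`), the number of accepted and rejected edges,
#'   and the expected edge rejection reasons.
#' @examples
#' fx <- make_fixture(fixture_spec("Inhibition", "SBGN"))
#' fx$expected$interaction_classes
#' @export
make_fixture <- function(s) {
  stopifnot(inherits(s, "fixture_spec"))
  ty <- s$interaction_type
  tok <- function(cls) .FIXTURE_TOKENS[[cls]][[s$notation]]
  wp_id <- "WP9001"
  expected <- list(interaction_classes = character(0),
                   accepted_edges = 0L, rejected_edges = 0L,
                   rejection_reasons = character(0))
  nodes <- list(); edges <- list(); groups <- list(); labels <- list()

  if (ty %in% c("Interaction", "DirectedInteraction", "Inhibition",
                "Stimulation", "Binding", "TranscriptionTranslation")) {
    nodes <- list(fx_node("n1", .FX$gene_a), fx_node("n2", .FX$gene_b))
    head <- if (ty == "Interaction") "" else tok(ty)
    edges <- list(fx_line("e1", "n1", "n2", head = head))
    expected$interaction_classes <- ty
    expected$accepted_edges <- 1L
  } else if (ty == "Conversion") {
    nodes <- list(fx_node("m1", .FX$met_a), fx_node("m2", .FX$met_b))
    edges <- list(fx_line("e1", "m1", "m2", head = tok("Conversion")))
    expected$interaction_classes <- "Conversion"
    expected$accepted_edges <- 1L
  } else if (ty == "Catalysis") {
    # conversion spine with an anchored catalysis leg from an enzyme
    nodes <- list(fx_node("m1", .FX$met_a), fx_node("m2", .FX$met_b),
                  fx_node("p1", .FX$enzyme))
    spine <- fx_line("e1", "m1", "m2", head = tok("Conversion"),
                     anchors = list(gpml_anchor("a1", 0.5)))
    leg <- fx_line("e2", "p1", "a1", head = tok("Catalysis"))
    edges <- list(spine, leg)
    expected$interaction_classes <- c("Conversion", "Catalysis")
    expected$accepted_edges <- 2L
  } else if (ty == "ComplexBinding") {
    nodes <- list(fx_node("n1", .FX$gene_a, group_ref = "grp1"),
                  fx_node("n2", .FX$gene_b, group_ref = "grp1"),
                  fx_node("n3", .FX$gene_c, group_ref = "grp1"))
    groups <- list(gpml_group("grp1", graph_id = "g1", style = "Complex"))
    expected$interaction_classes <- c("ComplexBinding",
                                      rep("Interaction", 3L))
  } else if (ty == "label_edge") {
    nodes <- list(fx_node("n1", .FX$gene_a))
    labels <- list(gpml_label("l1", "Fatty Acid Oxidation"))
    edges <- list(fx_line("e1", "n1", "l1", head = "Arrow"))
    expected$rejected_edges <- 1L
    expected$rejection_reasons <- "label_endpoint"
  } else if (ty == "unannotated_node") {
    un <- list(label = "Gal-GlcNAc-GM1b", type = "Metabolite",
               ds = "", id = "")
    nodes <- list(fx_node("m1", .FX$met_a), fx_node("m2", un))
    edges <- list(fx_line("e1", "m1", "m2", head = tok("Conversion")))
    expected$rejected_edges <- 1L
    expected$rejection_reasons <- "participant_unresolved"
  } else if (ty == "isoenzyme_group") {
    # user-defined (non-complex) group of enzymes catalyzing a conversion
    iso1 <- list(label = "ST8SIA1", type = "GeneProduct",
                 ds = "Ensembl", id = "ENSG00000111728")
    iso2 <- list(label = "ST8SIA5", type = "GeneProduct",
                 ds = "Ensembl", id = "ENSG00000101638")
    nodes <- list(fx_node("m1", .FX$met_a), fx_node("m2", .FX$met_b),
                  fx_node("p1", iso1, group_ref = "grp1"),
                  fx_node("p2", iso2, group_ref = "grp1"))
    groups <- list(gpml_group("grp1", graph_id = "g1", style = "Group"))
    spine <- fx_line("e1", "m1", "m2", head = tok("Conversion"),
                     anchors = list(gpml_anchor("a1", 0.5)))
    leg <- fx_line("e2", "g1", "a1", head = tok("Catalysis"))
    edges <- list(spine, leg)
    expected$interaction_classes <- "Conversion"
    expected$accepted_edges <- 1L
    expected$rejected_edges <- 1L
    expected$rejection_reasons <- "group_unresolved"
  } else if (ty == "double_headed") {
    nodes <- list(fx_node("n1", .FX$gene_a), fx_node("n2", .FX$gene_b))
    edges <- list(fx_line("e1", "n1", "n2", head = "Arrow", tail = "Arrow"))
    expected$interaction_classes <- rep("DirectedInteraction", 2L)
    expected$accepted_edges <- 1L
  } else if (ty == "multi_leg") {
    # conversion with an extra input attached plain to the spine anchor
    met_c <- list(label = "GD1b", type = "Metabolite",
                  ds = "HMDB", id = "HMDB0004926")
    nodes <- list(fx_node("m1", .FX$met_a), fx_node("m2", .FX$met_b),
                  fx_node("m3", met_c))
    spine <- fx_line("e1", "m1", "m2", head = tok("Conversion"),
                     anchors = list(gpml_anchor("a1", 0.5)))
    leg <- fx_line("e2", "m3", "a1")
    edges <- list(spine, leg)
    expected$interaction_classes <- "Conversion"
    expected$accepted_edges <- 2L
  }

  p <- gpml_pathway(wp_id = wp_id, revision = 1L,
                    title = paste0("fixture ", ty),
                    organism = "Homo sapiens",
                    nodes = nodes, edges = edges, groups = groups,
                    labels = labels)
  list(pathway = p, expected = expected)
}

#' The nine-type fixture corpus
#'
#' One fixture per harmonized interaction class, each in its first valid
#' notation.
#'
#' @return Named list of `make_fixture()` results.
#' @export
nine_type_corpus <- function() {
  out <- lapply(WP_INTERACTION_CLASSES, function(ty)
    make_fixture(fixture_spec(ty)))
  stats::setNames(out, WP_INTERACTION_CLASSES)
}

#' Random seeded pathway generator
#'
#' Draws `node_count` nodes (genes, proteins, metabolites), annotates each
#' with an xref with probability `annotation_rate`, and connects random
#' ordered pairs with directed arrowheads at the given density. Reproducible
#' under the seed; the global random state is restored afterwards.
#'
#' @param node_count Number of datanodes.
#' @param edge_density Probability that an ordered node pair is connected.
#' @param annotation_rate Fraction of nodes carrying an xref (in
#'   expectation).
#' @param seed Integer seed.
#' @return A [gpml_pathway()].
#' @export
make_random_pathway <- function(node_count = 10, edge_density = 0.15,
                                annotation_rate = 0.8, seed = 1L) {
  stopifnot(edge_density >= 0, edge_density <= 1,
            annotation_rate >= 0, annotation_rate <= 1, node_count >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)

  types <- c("GeneProduct", "Protein", "Metabolite")
  ds_of <- c(GeneProduct = "Ensembl", Protein = "Ensembl",
             Metabolite = "HMDB")
  nodes <- lapply(seq_len(node_count), function(i) {
    ty <- sample(types, 1)
    annotated <- stats::runif(1) < annotation_rate
    gpml_datanode(
      graph_id = sprintf("n%03d", i),
      text_label = sprintf("%s%03d", substr(ty, 1, 1), i),
      type = ty,
      xref_datasource = if (annotated) ds_of[[ty]] else "",
      xref_id = if (annotated) {
        if (ty == "Metabolite") sprintf("HMDB%07d", i)
        else sprintf("ENSG%011d", i)
      } else ""
    )
  })
  heads <- c("Arrow", "TBar", "mim-conversion", "mim-inhibition",
             "mim-stimulation", "")
  edges <- list()
  k <- 0L
  for (i in seq_len(node_count)) {
    for (j in seq_len(node_count)) {
      if (i == j) next
      if (stats::runif(1) < edge_density) {
        k <- k + 1L
        edges[[k]] <- fx_line(sprintf("e%03d", k),
                              sprintf("n%03d", i), sprintf("n%03d", j),
                              head = sample(heads, 1))
      }
    }
  }
  gpml_pathway(wp_id = "WP9100", revision = seed,
               title = "random pathway", organism = "Homo sapiens",
               nodes = nodes, edges = edges)
}

#' Write a fixture corpus to a directory
#'
#' Serializes every nine-type and scenario fixture as `.gpml` plus an
#' `expectations.csv` manifest with the expected conversion outcome.
#'
#' @param dir Output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
write_fixture_corpus <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (ty in FIXTURE_TYPES) {
    for (no in .FIXTURE_NOTATIONS[[ty]]) {
      fx <- make_fixture(fixture_spec(ty, no))
      fn <- sprintf("%s_%s.gpml", ty, no)
      serialize_gpml(fx$pathway, file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        file = fn, interaction_type = ty, notation = no,
        expected_classes = paste(fx$expected$interaction_classes,
                                 collapse = ";"),
        accepted_edges = fx$expected$accepted_edges,
        rejected_edges = fx$expected$rejected_edges,
        rejection_reasons = paste(fx$expected$rejection_reasons,
                                  collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "expectations.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
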