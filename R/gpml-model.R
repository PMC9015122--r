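#' Drawing-level model of a GPML pathway
#'
#' A faithful in-memory representation of one GPML file: datanodes, edge
#' lines with their points and anchors, groups and free text labels. No
#' biological interpretation happens at this level; arrowhead tokens are
#' opaque strings and dangling endpoints are retained.
#'
#' @param wp_id Pathway accession, e.g. `"WP1423"`.
#' @param revision Integer revision number.
#' @param title,organism Pathway metadata.
#' @param nodes List of [gpml_datanode()] objects.
#' @param edges List of [gpml_edge()] objects.
#' @param groups List of [gpml_group()] objects.
#' @param labels List of [gpml_label()] objects.
#' @return An object of class `gpml_pathway`.
#' @export
gpml_pathway <- function(wp_id = "WP0", revision = 0L, title = "",
                         organism = "", nodes = list(), edges = list(),
                         groups = list(), labels = list()) {
  p <- structure(
    list(wp_id = wp_id, revision = as.integer(revision), title = title,
         organism = organism, nodes = nodes, edges = edges, groups = groups,
         labels = labels),
    class = "gpml_pathway"
  )
  validate_gpml_pathway(p)
  p
}

GPML_NODE_TYPES <- c("GeneProduct", "Protein", "Metabolite", "Rna",
                     "Complex", "Pathway", "Unknown")

#' @rdname gpml_pathway
#' @param graph_id Element identifier, unique within the pathway.
#' @param text_label Displayed text.
#' @param type Declared node type, one of `GeneProduct`, `Protein`,
#'   `Metabolite`, `Rna`, `Complex`, `Pathway`, `Unknown`.
#' @param xref_datasource,xref_id Database annotation; empty strings when the
#'   node is unannotated (the main cause of semantic-layer exclusion).
#' @param group_ref `GroupId` of the containing group, or `""`.
#' @export
gpml_datanode <- function(graph_id, text_label = "", type = "Unknown",
                          xref_datasource = "", xref_id = "",
                          group_ref = "") {
  type <- match.arg(type, GPML_NODE_TYPES)
  structure(
    list(graph_id = graph_id, text_label = text_label, type = type,
         xref_datasource = xref_datasource, xref_id = xref_id,
         group_ref = group_ref),
    class = "gpml_datanode"
  )
}

#' @rdname gpml_pathway
#' @param graph_ref `graphId` (or `anchorId`) of the element this point
#'   attaches to, `""` if dangling.
#' @param arrow_head Arrowhead token (`"Arrow"`, `"mim-catalysis"`,
#'   `"sbgn-inhibition"`, ...) or `""` for a plain line end. Tokens are
#'   opaque and case-sensitive at this layer.
#' @param x,y Drawing coordinates; parsed but never interpreted.
#' @export
edge_point <- function(graph_ref = "", arrow_head = "", x = 0, y = 0) {
  structure(
    list(graph_ref = graph_ref, arrow_head = arrow_head,
         x = as.numeric(x), y = as.numeric(y)),
    class = "edge_point"
  )
}

#' @rdname gpml_pathway
#' @param anchor_id Identifier of the anchor; addressable like a `graphId`.
#' @param position Fraction along the owning line, in `[0, 1]`.
#' @export
gpml_anchor <- function(anchor_id, position = 0.5) {
  stopifnot(position >= 0, position <= 1)
  structure(list(anchor_id = anchor_id, position = as.numeric(position)),
            class = "gpml_anchor")
}

#' @rdname gpml_pathway
#' @param points Ordered list of [edge_point()]; at least two. The first is
#'   the line's start, the last its end.
#' @param anchors List of [gpml_anchor()] owned by this line.
#' @export
gpml_edge <- function(graph_id, points, anchors = list(),
                      xref_datasource = "", xref_id = "") {
  stopifnot(length(points) >= 2)
  structure(
    list(graph_id = graph_id, points = points, anchors = anchors,
         xref_datasource = xref_datasource, xref_id = xref_id),
    class = "gpml_edge"
  )
}

#' @rdname gpml_pathway
#' @param group_id Identifier referenced by member nodes' `GroupRef`.
#' @param style `"Group"` (loose user grouping) or `"Complex"`.
#' @export
gpml_group <- function(group_id, graph_id = "", style = c("Group", "Complex")) {
  style <- match.arg(style)
  structure(list(group_id = group_id, graph_id = graph_id, style = style),
            class = "gpml_group")
}

#' @rdname gpml_pathway
#' @export
gpml_label <- function(graph_id, text_label = "") {
  structure(list(graph_id = graph_id, text_label = text_label),
            class = "gpml_label")
}

#' @export
print.gpml_pathway <- function(x, ...) {
  cat(sprintf(
    "<gpml_pathway %s_r%d \"%s\" (%s): %d nodes, %d edges, %d groups, %d labels>\n",
    x$wp_id, x$revision, x$title, x$organism,
    length(x$nodes), length(x$edges), length(x$groups), length(x$labels)))
  invisible(x)
}

# all graphIds claimed by a pathway: nodes, edges, groups (graphId), labels,
# anchors
all_graph_ids <- function(p) {
  c(vapply(p$nodes, `[[`, "", "graph_id"),
    vapply(p$edges, `[[`, "", "graph_id"),
    unlist(lapply(p$edges, function(e)
      vapply(e$anchors, `[[`, "", "anchor_id"))),
    Filter(nzchar, vapply(p$groups, `[[`, "", "graph_id")),
    vapply(p$labels, `[[`, "", "graph_id"))
}

validate_gpml_pathway <- function(p) {
  ids <- all_graph_ids(p)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate graphId(s) in pathway: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  group_ids <- vapply(p$groups, `[[`, "", "group_id")
  refs <- Filter(nzchar, vapply(p$nodes, `[[`, "", "group_ref"))
  bad <- setdiff(refs, group_ids)
  if (length(bad) > 0) {
    stop("groupRef to missing group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(p)
}

# members of a group: graphIds of nodes whose group_ref names it
group_members <- function(p, group) {
  ids <- vapply(p$nodes, `[[`, "", "graph_id")
  refs <- vapply(p$nodes, `[[`, "", "group_ref")
  sort(ids[refs == group$group_id])
}

# lookup tables used throughout semantification
pathway_index <- function(p) {
  nodes <- stats::setNames(p$nodes, vapply(p$nodes, `[[`, "", "graph_id"))
  labels <- stats::setNames(p$labels, vapply(p$labels, `[[`, "", "graph_id"))
  groups_by_graphid <- p$groups[nzchar(vapply(p$groups, `[[`, "", "graph_id"))]
  groups_by_graphid <- stats::setNames(
    groups_by_graphid, vapply(groups_by_graphid, `[[`, "", "graph_id"))
  anchors <- list()
  for (e in p$edges) {
    for (a in e$anchors) anchors[[a$anchor_id]] <- e$graph_id
  }
  list(nodes = nodes, labels = labels, groups = groups_by_graphid,
       anchor_owner = anchors)
}

# model equality ignoring list ordering of elements (sorted by graphId)
sort_pathway <- function(p) {
  by_id <- function(xs, field = "graph_id") {
    xs[order(vapply(xs, `[[`, "", field), method = "radix")]
  }
  p$nodes <- by_id(p$nodes)
  p$edges <- by_id(p$edges)
  p$groups <- by_id(p$groups, "group_id")
  p$labels <- by_id(p$labels)
  p
}
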