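#' Parse a GPML document into the drawing-level model
#'
#' Reads the GPML2013a dialect (the format WikiPathways stores pathway
#' drawings in). Every `DataNode`, `Interaction`, `Group`, `Label` and
#' `Anchor` element is represented; other element kinds (`Shape`, `State`,
#' `BiopaxRef`, ...) carry no connectivity and are skipped with a warning.
#' Layout coordinates are parsed but never interpreted.
#'
#' Stock GPML carries the pathway accession and revision in the file name
#' (`WP1423_r94289.gpml`), not in the XML; when parsing from a file those are
#' inferred from the name, and [serialize_gpml()] additionally echoes them as
#' root attributes so model round-trips are exact.
#'
#' @param x GPML XML as a single string, or a file path.
#' @param wp_id,revision Override the pathway accession / revision.
#' @return A [gpml_pathway()].
#' @export
parse_gpml <- function(x, wp_id = NULL, revision = NULL) {
  is_path <- length(x) == 1L && !grepl("<", x, fixed = TRUE) && file.exists(x)
  if (is_path && is.null(wp_id)) {
    m <- regmatches(basename(x),
                    regexec("^(WP[0-9]+)(?:_r([0-9]+))?", basename(x)))[[1]]
    if (length(m) >= 2 && nzchar(m[2])) {
      wp_id <- m[2]
      if (is.null(revision) && nzchar(m[3])) revision <- as.integer(m[3])
    }
  }
  doc <- tryCatch(
    xml2::read_xml(if (is_path) x else paste(x, collapse = "\n")),
    error = function(e) stop("malformed GPML XML: ", conditionMessage(e),
                             call. = FALSE)
  )
  root <- xml2::xml_ns_strip(doc)
  if (xml2::xml_name(root) != "Pathway") {
    stop("not a GPML document: root element is <", xml2::xml_name(root), ">",
         call. = FALSE)
  }
  attr_or <- function(node, name, default = "") {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) default else v
  }
  if (is.null(wp_id)) {
    wp_id <- attr_or(root, "WPID", "WP0")
  }
  if (is.null(revision)) {
    revision <- suppressWarnings(as.integer(attr_or(root, "Revision", "0")))
    if (is.na(revision)) revision <- 0L
  }

  nodes <- lapply(xml2::xml_find_all(root, "./DataNode"), function(nd) {
    xref <- xml2::xml_find_first(nd, "./Xref")
    type <- attr_or(nd, "Type", "Unknown")
    if (!type %in% GPML_NODE_TYPES) type <- "Unknown"
    gpml_datanode(
      graph_id = attr_or(nd, "GraphId"),
      text_label = attr_or(nd, "TextLabel"),
      type = type,
      xref_datasource = if (inherits(xref, "xml_missing")) "" else
        attr_or(xref, "Database"),
      xref_id = if (inherits(xref, "xml_missing")) "" else
        attr_or(xref, "ID"),
      group_ref = attr_or(nd, "GroupRef")
    )
  })

  edges <- lapply(xml2::xml_find_all(root, "./Interaction"), function(ed) {
    gr <- xml2::xml_find_first(ed, "./Graphics")
    pts <- lapply(xml2::xml_find_all(gr, "./Point"), function(pt) {
      edge_point(graph_ref = attr_or(pt, "GraphRef"),
                 arrow_head = attr_or(pt, "ArrowHead"),
                 x = as.numeric(attr_or(pt, "X", "0")),
                 y = as.numeric(attr_or(pt, "Y", "0")))
    })
    if (length(pts) < 2) {
      stop("Interaction ", attr_or(ed, "GraphId"), " has fewer than 2 points",
           call. = FALSE)
    }
    anc <- lapply(xml2::xml_find_all(gr, "./Anchor"), function(an) {
      gpml_anchor(anchor_id = attr_or(an, "GraphId"),
                  position = as.numeric(attr_or(an, "Position", "0.5")))
    })
    xref <- xml2::xml_find_first(ed, "./Xref")
    gpml_edge(
      graph_id = attr_or(ed, "GraphId"),
      points = pts, anchors = anc,
      xref_datasource = if (inherits(xref, "xml_missing")) "" else
        attr_or(xref, "Database"),
      xref_id = if (inherits(xref, "xml_missing")) "" else attr_or(xref, "ID")
    )
  })

  groups <- lapply(xml2::xml_find_all(root, "./Group"), function(gp) {
    style <- attr_or(gp, "Style", "Group")
    if (!style %in% c("Group", "Complex")) style <- "Group"
    gpml_group(group_id = attr_or(gp, "GroupId"),
               graph_id = attr_or(gp, "GraphId"),
               style = style)
  })

  labels <- lapply(xml2::xml_find_all(root, "./Label"), function(lb) {
    gpml_label(graph_id = attr_or(lb, "GraphId"),
               text_label = attr_or(lb, "TextLabel"))
  })

  known <- c("DataNode", "Interaction", "Group", "Label", "Graphics",
             "Xref", "Comment", "BiopaxRef", "Attribute", "InfoBox", "Biopax")
  other <- setdiff(unique(xml2::xml_name(xml2::xml_children(root))), known)
  if (length(other) > 0) {
    warning("ignoring GPML element(s) with no connectivity: ",
            paste(other, collapse = ", "), call. = FALSE)
  }

  gpml_pathway(
    wp_id = wp_id, revision = revision,
    title = attr_or(root, "Name"), organism = attr_or(root, "Organism"),
    nodes = nodes, edges = edges, groups = groups, labels = labels
  )
}

#' Serialize the drawing-level model back to GPML
#'
#' Produces a GPML2013a document such that
#' `parse_gpml(serialize_gpml(p))` is model-equal to `p`.
#'
#' @param p A [gpml_pathway()].
#' @param path Optional file path; when given the XML is written there.
#' @return The XML as a single string (invisibly when `path` is given).
#' @export
serialize_gpml <- function(p, path = NULL) {
  stopifnot(inherits(p, "gpml_pathway"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  att <- function(name, value, keep_empty = FALSE) {
    if (!keep_empty && !nzchar(value)) return("")
    sprintf(' %s="%s"', name, esc(as.character(value)))
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<Pathway xmlns="http://pathvisio.org/GPML/2013a"%s%s%s%s>',
            att("Name", p$title), att("Organism", p$organism),
            att("WPID", p$wp_id),
            att("Revision", as.character(p$revision)))
  )
  for (n in p$nodes) {
    lines <- c(lines, sprintf(
      '  <DataNode%s%s%s%s>',
      att("TextLabel", n$text_label), att("GraphId", n$graph_id),
      att("GroupRef", n$group_ref), att("Type", n$type)))
    lines <- c(lines, sprintf('    <Xref%s%s />',
                              att("Database", n$xref_datasource, TRUE),
                              att("ID", n$xref_id, TRUE)))
    lines <- c(lines, "  </DataNode>")
  }
  for (e in p$edges) {
    lines <- c(lines, sprintf("  <Interaction%s>", att("GraphId", e$graph_id)),
               "    <Graphics>")
    for (pt in e$points) {
      lines <- c(lines, sprintf(
        '      <Point X="%s" Y="%s"%s%s />', format(pt$x), format(pt$y),
        att("GraphRef", pt$graph_ref), att("ArrowHead", pt$arrow_head)))
    }
    for (a in e$anchors) {
      lines <- c(lines, sprintf(
        '      <Anchor Position="%s"%s />', format(a$position),
        att("GraphId", a$anchor_id)))
    }
    lines <- c(lines, "    </Graphics>",
               sprintf('    <Xref%s%s />',
                       att("Database", e$xref_datasource, TRUE),
                       att("ID", e$xref_id, TRUE)),
               "  </Interaction>")
  }
  for (lb in p$labels) {
    lines <- c(lines, sprintf("  <Label%s%s />",
                              att("TextLabel", lb$text_label),
                              att("GraphId", lb$graph_id)))
  }
  for (g in p$groups) {
    lines <- c(lines, sprintf("  <Group%s%s%s />",
                              att("GroupId", g$group_id),
                              att("GraphId", g$graph_id),
                              att("Style", g$style)))
  }
  lines <- c(lines, "</Pathway>")
  xml <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(xml, path)
    return(invisible(xml))
  }
  xml
}
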