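#' Statistics and curation reports over the two layers
#'
#' These functions reproduce the standard summary tables for a converted
#' pathway set: hierarchy-inclusive datanode counts, interaction counts
#' split into directed / non-directed / non-specified, participant profiles
#' of the interactions, interaction identifier sources, a curation list of
#' drawn-but-unconverted interactions, and heuristic quality flags. They
#' work equally on layers produced by [build_semantic_layer()] or loaded
#' from Turtle dumps with [read_turtle()].
#'
#' @name reporting
NULL

# drawn gpml datanode IRIs with no semantic counterpart
gpml_only_nodes <- function(gpml) {
  all <- subjects_with(gpml, WP_PREDICATES[["type"]], "gpml:DataNode")
  linked <- subjects_with(gpml, WP_PREDICATES[["isAbout"]])
  setdiff(all, linked)
}

# drawn gpml interaction IRIs with no semantic counterpart
gpml_only_interactions <- function(gpml) {
  all <- subjects_with(gpml, WP_PREDICATES[["type"]], "gpml:Interaction")
  linked <- subjects_with(gpml, WP_PREDICATES[["isAbout"]])
  setdiff(all, linked)
}

#' Hierarchy-inclusive datanode counts
#'
#' Counts semantic-layer datanodes per class, where each node counts towards
#' every class in its closure (a protein counts as Protein, GeneProduct and
#' Datanode), plus the drawn-only nodes per declared type. Pathway nodes
#' appear in the semantic layer typed only as plain datanodes, so their
#' semantic count is folded into `Datanode`; drawn-only `Unknown` and
#' `Pathway` nodes are tracked under their own rows.
#'
#' @param wp,gpml The two layers.
#' @param exclusive Count each node only under its most specific class.
#' @return Data frame `class`, `count_wp`, `count_gpml_only`.
#' @export
datanode_stats <- function(wp, gpml, exclusive = FALSE) {
  P <- WP_PREDICATES
  classes <- c("Datanode", "GeneProduct", "Protein", "Metabolite", "Rna",
               "Complex", "Unknown", "Pathway")

  count_wp <- vapply(classes, function(cl) {
    if (cl %in% c("Unknown", "Pathway")) return(NA_integer_)
    if (exclusive) {
      typed <- match_triples(wp, predicate = P[["type"]],
                             object = paste0("wp:", cl))
      length(unique(typed$subject))
    } else {
      length(resources_of_class(wp, paste0("wp:", cl)))
    }
  }, integer(1))

  only <- gpml_only_nodes(gpml)
  declared <- vapply(only, function(iri) {
    d <- objects_of(gpml, iri, "gpml:declaredType")
    if (length(d) == 0) "Unknown" else d[1]
  }, character(1))
  count_only <- vapply(classes, function(cl) {
    if (cl == "Datanode") return(NA_integer_)
    if (exclusive || cl %in% c("Unknown", "Pathway")) {
      return(sum(declared == cl))
    }
    sum(vapply(declared, function(d) {
      d %in% GPML_NODE_TYPES && !d %in% c("Unknown", "Pathway") &&
        is_subclass_of(paste0("wp:", d), paste0("wp:", cl))
    }, logical(1)))
  }, integer(1))

  # interactions are not datanodes; exclude pathway resources from wp counts
  data.frame(class = classes, count_wp = count_wp,
             count_gpml_only = count_only, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Interaction counts and conversion percentages
#'
#' The identity `directed + non-directed = total` holds by construction;
#' non-specified interactions (no class more specific than the generic
#' undirected interaction) are a subset of the non-directed ones.
#' Percentages are reported to one decimal.
#'
#' @param wp,gpml The two layers.
#' @return A list of class `interaction_stats` with counts, per-class counts
#'   and percentages.
#' @export
interaction_stats <- function(wp, gpml) {
  P <- WP_PREDICATES
  iris <- resources_of_class(wp, "wp:Interaction")
  total <- length(iris)
  directed_iris <- resources_of_class(wp, "wp:DirectedInteraction")
  directed <- length(directed_iris)
  non_directed <- total - directed
  specific <- paste0("wp:", setdiff(WP_INTERACTION_CLASSES, "Interaction"))
  non_specified <- sum(vapply(setdiff(iris, directed_iris), function(iri) {
    !any(types_of(wp, iri) %in% specific)
  }, logical(1)))

  per_class <- vapply(WP_INTERACTION_CLASSES, function(cl) {
    length(resources_of_class(wp, paste0("wp:", cl)))
  }, integer(1))

  gpml_total <- length(subjects_with(gpml, P[["type"]], "gpml:Interaction"))
  gpml_only <- length(gpml_only_interactions(gpml))
  pct <- function(x, denom) if (denom == 0) NA_real_ else
    round(100 * x / denom, 1)

  structure(list(
    total = total,
    directed = directed,
    non_directed = non_directed,
    non_specified = non_specified,
    per_class = per_class,
    gpml_only = gpml_only,
    gpml_total = gpml_total,
    pct_non_directed = pct(non_directed, total),
    pct_non_specified = pct(non_specified, total),
    pct_directed = pct(directed, total),
    pct_gpml_converted = pct(gpml_total - gpml_only, gpml_total)
  ), class = "interaction_stats")
}

#' @export
print.interaction_stats <- function(x, ...) {
  cat(sprintf(
    "interactions: %d total, %d directed (%.1f%%), %d non-directed (%.1f%%), %d non-specified (%.1f%%)\n",
    x$total, x$directed, x$pct_directed, x$non_directed,
    x$pct_non_directed, x$non_specified, x$pct_non_specified))
  cat(sprintf("drawn-only interactions: %d of %d drawn (%.1f%% converted)\n",
              x$gpml_only, x$gpml_total, x$pct_gpml_converted))
  tab <- x$per_class[x$per_class > 0]
  for (cl in names(tab)) cat(sprintf("  %-25s %d\n", cl, tab[[cl]]))
  invisible(x)
}

#' Participant profiles of the interactions
#'
#' For each interaction, the profile concatenates each participant's type
#' labels: node participants contribute their most specific class, and
#' participants that are themselves interactions contribute their full
#' interaction-class closure (so a catalyzed conversion shows up as
#' `Conversion, DirectedInteraction, Interaction` inside a Catalysis
#' profile). Counts are keyed by (profile, interaction class), descending
#' then lexicographic.
#'
#' @param wp Semantic layer.
#' @return Data frame `participants`, `count`, `type`.
#' @export
participant_profiles <- function(wp) {
  P <- WP_PREDICATES
  iris <- resources_of_class(wp, "wp:Interaction")
  if (length(iris) == 0) {
    return(data.frame(participants = character(0), count = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  inter_set <- iris
  profile_of <- function(iri) {
    parts <- objects_of(wp, iri, P[["participant"]])
    labels <- unlist(lapply(parts, function(pa) {
      if (pa %in% inter_set) {
        sub("^wp:", "", sort(types_of(wp, pa)))
      } else {
        cls <- most_specific_node_class(wp, pa)
        if (is.na(cls)) character(0) else cls
      }
    }))
    paste(sort(labels), collapse = ", ")
  }
  cls <- vapply(iris, function(i) most_specific_class(wp, i), character(1))
  prof <- vapply(iris, profile_of, character(1))
  agg <- stats::aggregate(list(count = seq_along(iris)),
                          by = list(participants = prof, type = cls),
                          FUN = length)
  agg <- agg[order(-agg$count, agg$participants, agg$type,
                   method = "radix"), c("participants", "count", "type")]
  rownames(agg) <- NULL
  agg
}

# most specific node class (not interaction class) of a resource, or NA
most_specific_node_class <- function(g, iri) {
  asserted <- objects_of(g, iri, WP_PREDICATES[["type"]])
  asserted <- intersect(asserted, paste0("wp:", WP_NODE_CLASSES))
  if (length(asserted) == 0) return(NA_character_)
  depth <- vapply(asserted, function(cl) length(class_closure(cl)),
                  integer(1))
  sub("^wp:", "", asserted[which.max(depth)])
}

#' Interaction identifier counts per datasource
#'
#' Counts semantic-layer interactions that carry an identifier annotation,
#' grouped by datasource name, descending.
#'
#' @param wp Semantic layer.
#' @return Data frame `datasource`, `count`.
#' @export
xref_source_counts <- function(wp) {
  P <- WP_PREDICATES
  iris <- resources_of_class(wp, "wp:Interaction")
  src <- match_triples(wp, predicate = P[["identifierSource"]])
  src <- src[src$subject %in% iris, , drop = FALSE]
  if (nrow(src) == 0) {
    return(data.frame(datasource = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- as.data.frame(table(datasource = src$object),
                       stringsAsFactors = FALSE)
  names(tab) <- c("datasource", "count")
  tab <- tab[order(-tab$count, tab$datasource, method = "radix"), ]
  rownames(tab) <- NULL
  tab
}

#' Curation list of drawn-but-unconverted interactions
#'
#' One row per (drawn-only interaction, endpoint that carries a label):
#' the graphical interaction IRI, the endpoint's graph reference, and the
#' text shown at that endpoint. This is the worklist a curator uses to see
#' why a drawn line has no semantic counterpart.
#'
#' @param gpml,wp The two layers.
#' @return Data frame `gpml_interaction`, `graph_ref`, `participant_label`,
#'   sorted by interaction IRI.
#' @export
unconverted_interactions <- function(gpml, wp) {
  only <- gpml_only_interactions(gpml)
  # graphId -> element IRI and label
  ids <- match_triples(gpml, predicate = "gpml:graphId")
  label_of <- function(ref) {
    el <- ids$subject[ids$object == ref]
    if (length(el) == 0) return(NA_character_)
    lb <- objects_of(gpml, el[1], WP_PREDICATES[["label"]])
    if (length(lb) == 0) NA_character_ else lb[1]
  }
  rows <- list()
  for (iri in sort(only)) {
    refs <- objects_of(gpml, iri, "gpml:graphRef")
    for (ref in refs) {
      lb <- label_of(ref)
      if (!is.na(lb) && nzchar(lb)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gpml_interaction = iri, graph_ref = ref, participant_label = lb,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(list(
    data.frame(gpml_interaction = character(0), graph_ref = character(0),
               participant_label = character(0), stringsAsFactors = FALSE)),
    rows))
  out[order(out$gpml_interaction, out$graph_ref, method = "radix"), ,
      drop = FALSE]
}

#' Heuristic curation flags on the semantic layer
#'
#' Applies the drawing-quality heuristics: an undirected connection between
#' two metabolites is likely an unannotated conversion
#' (`undirected_metabolite_pair`); a conversion between two different
#' proteins is a likely mis-annotation (`protein_conversion`); a generic
#' directed interaction with no specific class is flagged
#' (`untyped_directed`).
#'
#' @param wp Semantic layer.
#' @return Data frame `iri`, `flag`.
#' @export
heuristic_flags <- function(wp) {
  P <- WP_PREDICATES
  iris <- resources_of_class(wp, "wp:Interaction")
  rows <- list()
  flag <- function(iri, f) {
    rows[[length(rows) + 1L]] <<- data.frame(iri = iri, flag = f,
                                             stringsAsFactors = FALSE)
  }
  for (iri in iris) {
    cls <- most_specific_class(wp, iri)
    parts <- objects_of(wp, iri, P[["participant"]])
    part_cls <- vapply(parts, function(pa)
      most_specific_node_class(wp, pa), character(1))
    if (cls == "Interaction" && length(parts) == 2 &&
        all(part_cls == "Metabolite", na.rm = FALSE) &&
        !anyNA(part_cls)) {
      flag(iri, "undirected_metabolite_pair")
    }
    if (cls == "Conversion") {
      prot <- parts[!is.na(part_cls) & part_cls %in% c("Protein",
                                                       "GeneProduct")]
      if (length(unique(prot)) >= 2) flag(iri, "protein_conversion")
    }
    if (cls == "DirectedInteraction") flag(iri, "untyped_directed")
  }
  do.call(rbind, c(list(
    data.frame(iri = character(0), flag = character(0),
               stringsAsFactors = FALSE)), rows))
}
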