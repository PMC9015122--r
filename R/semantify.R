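#' Harmonize a pathway drawing into the semantic layer
#'
#' This is the core of the package: a drawn pathway becomes a pair of graph
#' layers. The *graphical layer* records every drawn element verbatim. The
#' *semantic layer* holds only datanodes that resolve to a database
#' identifier and interactions whose drawing could be interpreted: lines are
#' bundled with the legs attached to their anchors (which is how catalysis is
#' drawn onto a conversion), arrowhead tokens from the WikiPathways, MIM and
#' SBGN notations are harmonized into the nine interaction classes, and
#' groups of style Complex expand into a complex binding plus pairwise
#' member connections. Every element that cannot be interpreted is rejected
#' with a machine-readable reason in the conversion log; nothing is dropped
#' silently.
#'
#' @name semantify
NULL

NODE_REJECT_REASONS <- c("no_xref", "unknown_datasource", "unknown_type",
                         "label_not_node", "unannotated_complex")
EDGE_REJECT_REASONS <- c("participant_unresolved", "label_endpoint",
                         "dangling_endpoint", "group_unresolved",
                         "unsupported_arrowhead")

#' Resolve one datanode against the datasource registry
#'
#' A node is accepted iff it has a non-empty xref, its datasource is known
#' to the registry, and its declared type is not `Unknown`. Rejection is a
#' value, not an error: the outcome carries one of the reasons `no_xref`,
#' `unknown_datasource` or `unknown_type`.
#'
#' @param n A [gpml_datanode()].
#' @param registry Datasource registry data frame
#'   (see [default_datasource_registry()]).
#' @return A list with `graph_id`, `accepted`, and either the semantic node
#'   fields (`iri`, `type_class`, `label`, `identifier_source`,
#'   `identifier_id`) or a `reason`.
#' @export
resolve_datanode <- function(n, registry = default_datasource_registry()) {
  rejected <- function(reason) {
    list(graph_id = n$graph_id, accepted = FALSE, reason = reason,
         label = n$text_label, type = n$type)
  }
  if (!nzchar(n$xref_datasource) || !nzchar(n$xref_id)) {
    return(rejected("no_xref"))
  }
  prefix <- registry_prefix(registry, n$xref_datasource)
  if (is.na(prefix)) return(rejected("unknown_datasource"))
  if (n$type == "Unknown") return(rejected("unknown_type"))
  list(
    graph_id = n$graph_id, accepted = TRUE,
    iri = mint_identifier_iri(prefix, n$xref_id),
    type_class = paste0("wp:", n$type),
    label = n$text_label,
    identifier_source = n$xref_datasource,
    identifier_id = n$xref_id
  )
}

#' Bundle edges via their anchors
#'
#' An edge whose terminal point attaches to an anchor of another edge is a
#' *leg* of that edge's bundle (e.g. a catalysis line ending on a conversion
#' line's anchor). Edges not touching any anchor form singleton bundles; an
#' edge attached to an anchor never also forms its own bundle.
#'
#' @param p A [gpml_pathway()].
#' @return A list of bundles, each `list(spine, legs)` where `legs` is a
#'   list of `list(edge, anchor_end, anchor_id)`; `anchor_end` is `"start"`
#'   or `"end"`, the end of the leg sitting on the anchor. Bundles are
#'   ordered by spine `graph_id`.
#' @export
bundle_edges <- function(p) {
  idx <- pathway_index(p)
  edges <- stats::setNames(p$edges, vapply(p$edges, `[[`, "", "graph_id"))

  # which edge (if any) does edge e attach to, and by which end?
  attachment <- function(e) {
    start_ref <- e$points[[1]]$graph_ref
    end_ref <- e$points[[length(e$points)]]$graph_ref
    # prefer the end point: a regulator is usually drawn towards the spine
    for (side in c("end", "start")) {
      ref <- if (side == "end") end_ref else start_ref
      owner <- idx$anchor_owner[[ref]]
      if (!is.null(owner) && owner != e$graph_id) {
        return(list(owner = owner, side = side, anchor = ref))
      }
    }
    NULL
  }

  att <- lapply(edges, attachment)
  is_leg <- !vapply(att, is.null, logical(1))

  # follow attachment chains to the spine (a leg on a leg joins the root)
  root_of <- function(id) {
    seen <- character(0)
    while (is_leg[[id]] && !(id %in% seen)) {
      seen <- c(seen, id)
      id <- att[[id]]$owner
    }
    id
  }

  spines <- sort(names(edges)[!is_leg])
  bundles <- lapply(spines, function(s) list(spine = edges[[s]], legs = list()))
  names(bundles) <- spines
  for (id in sort(names(edges)[is_leg])) {
    root <- root_of(id)
    if (!root %in% spines) next  # attachment cycle; leave as orphan
    bundles[[root]]$legs <- c(
      bundles[[root]]$legs,
      list(list(edge = edges[[id]], anchor_end = att[[id]]$side,
                anchor_id = att[[id]]$anchor)))
  }
  unname(bundles)
}

# context shared by the classifiers: pathway IRIs, element index,
# per-node resolutions and per-group resolution
semantify_context <- function(p, resolutions, group_res = list()) {
  pref <- sprintf("%s_r%d", p$wp_id, p$revision)
  list(
    pathway_iri = sprintf("wikipathways:%s_r%d", p$wp_id, p$revision),
    iri_prefix = pref,
    index = pathway_index(p),
    resolutions = resolutions,
    group_res = group_res
  )
}

# resolve an edge endpoint ref to a participant IRI or a rejection reason
resolve_endpoint <- function(ref, ctx) {
  if (!nzchar(ref)) return(list(reason = "dangling_endpoint"))
  if (!is.null(ctx$index$labels[[ref]])) return(list(reason = "label_endpoint"))
  res <- ctx$resolutions[[ref]]
  if (!is.null(res)) {
    if (isTRUE(res$accepted)) return(list(iri = res$iri))
    return(list(reason = "participant_unresolved"))
  }
  grp <- ctx$index$groups[[ref]]
  if (!is.null(grp)) {
    gr <- ctx$group_res[[grp$group_id]]
    if (!is.null(gr) && !is.null(gr$complex_iri)) {
      return(list(iri = gr$complex_iri, group_id = grp$group_id))
    }
    return(list(reason = "group_unresolved", group_id = grp$group_id))
  }
  list(reason = "dangling_endpoint")
}

new_interaction <- function(iri, type_class, participants, source = NA,
                            target = NA, pathway, about = NA) {
  list(iri = iri, type_class = type_class,
       participants = sort(unique(participants)),
       source = source, target = target, pathway = pathway, about = about)
}

REGULATOR_CLASSES <- c("Catalysis", "Stimulation", "Inhibition",
                       "TranscriptionTranslation")

#' Classify one reaction bundle into harmonized interactions
#'
#' The spine line yields one interaction whose class comes from the mapping
#' of its arrowhead; directed classes take the start-point node as source
#' and the end-point node as target. Each regulator leg (catalysis,
#' stimulation, inhibition drawn onto a spine anchor) yields one additional
#' interaction whose target is the spine interaction's IRI. Plain legs add
#' extra participants. Unmapped tokens degrade to a generic directed (or
#' undirected) interaction and are logged as `unsupported_arrowhead`.
#'
#' @param b One bundle from [bundle_edges()].
#' @param ctx Context from `semantify_context()` (internal); built for you
#'   by [build_semantic_layer()].
#' @param mapping Arrowhead map (see [default_arrowhead_map()]).
#' @param expand_isoenzymes Also emit one duplicate regulator interaction
#'   per member when a regulator leg starts at a group.
#' @return `list(interactions, rejections, merged, notes)`; `rejections` is
#'   a data frame with `graph_id` and `reason`; `merged` records legs that
#'   were folded into the spine interaction as extra participants.
#' @export
classify_bundle <- function(b, ctx, mapping = default_arrowhead_map(),
                            expand_isoenzymes = FALSE) {
  interactions <- list()
  rejections <- data.frame(graph_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  merged <- data.frame(graph_id = character(0), iri = character(0),
                       stringsAsFactors = FALSE)
  notes <- character(0)
  reject <- function(id, reason) {
    rejections[nrow(rejections) + 1L, ] <<- list(id, reason)
  }

  spine <- b$spine
  np <- length(spine$points)
  start_pt <- spine$points[[1]]
  end_pt <- spine$points[[np]]
  start_res <- resolve_endpoint(start_pt$graph_ref, ctx)
  end_res <- resolve_endpoint(end_pt$graph_ref, ctx)

  spine_iri <- sprintf("%s/WP/Interaction/%s", ctx$iri_prefix, spine$graph_id)
  gpml_spine_iri <- sprintf("%s/Interaction/%s", ctx$iri_prefix,
                            spine$graph_id)

  spine_ok <- is.null(start_res$reason) && is.null(end_res$reason)
  if (!spine_ok) {
    reason <- if (!is.null(start_res$reason)) start_res$reason else
      end_res$reason
    reject(spine$graph_id, reason)
    # legs cannot target a rejected spine
    for (leg in b$legs) reject(leg$edge$graph_id, "participant_unresolved")
    return(list(interactions = interactions, rejections = rejections,
                merged = merged, notes = notes))
  }

  tok_start <- start_pt$arrow_head
  tok_end <- end_pt$arrow_head
  map_start <- arrowhead_class(mapping, tok_start)
  map_end <- arrowhead_class(mapping, tok_end)

  emit_spine <- function(iri, class, src_iri, tgt_iri) {
    cls <- paste0("wp:", class)
    if (class %in% c("Binding", "ComplexBinding") ||
        class == "Interaction") {
      interactions[[length(interactions) + 1L]] <<- new_interaction(
        iri, cls, c(src_iri, tgt_iri), pathway = ctx$pathway_iri,
        about = gpml_spine_iri)
    } else {
      interactions[[length(interactions) + 1L]] <<- new_interaction(
        iri, cls, c(src_iri, tgt_iri), source = src_iri, target = tgt_iri,
        pathway = ctx$pathway_iri, about = gpml_spine_iri)
    }
  }

  unsupported <- FALSE
  if (nzchar(tok_end) && is.null(map_end)) unsupported <- TRUE
  if (nzchar(tok_start) && is.null(map_start)) unsupported <- TRUE

  if (!nzchar(tok_start) && !nzchar(tok_end)) {
    # plain line: generic undirected interaction (non-specific)
    emit_spine(spine_iri, "Interaction", start_res$iri, end_res$iri)
  } else if (nzchar(tok_start) && nzchar(tok_end)) {
    # double-headed: two directed interactions sharing participants
    cls_fwd <- if (!is.null(map_end)) map_end$class else "DirectedInteraction"
    cls_rev <- if (!is.null(map_start)) map_start$class else
      "DirectedInteraction"
    emit_spine(spine_iri, cls_fwd, start_res$iri, end_res$iri)
    emit_spine(paste0(spine_iri, "_rev"), cls_rev, end_res$iri, start_res$iri)
    notes <- c(notes, sprintf(
      "double-headed line %s split into two directed interactions",
      spine$graph_id))
  } else if (nzchar(tok_end)) {
    cls <- if (!is.null(map_end)) map_end$class else "DirectedInteraction"
    emit_spine(spine_iri, cls, start_res$iri, end_res$iri)
  } else {
    # arrowhead on the start point only: the line was drawn reversed
    cls <- if (!is.null(map_start)) map_start$class else "DirectedInteraction"
    emit_spine(spine_iri, cls, end_res$iri, start_res$iri)
  }
  if (unsupported) {
    notes <- c(notes, sprintf("unsupported_arrowhead on %s (%s)",
                              spine$graph_id,
                              paste(Filter(nzchar, c(tok_start, tok_end)),
                                    collapse = ", ")))
  }

  spine_idx <- 1L   # index of the forward spine interaction
  for (leg in b$legs) {
    e <- leg$edge
    free_pt <- if (leg$anchor_end == "end") e$points[[1]] else
      e$points[[length(e$points)]]
    anchor_pt <- if (leg$anchor_end == "end") e$points[[length(e$points)]]
      else e$points[[1]]
    tok_free <- free_pt$arrow_head
    tok_anchor <- anchor_pt$arrow_head
    map_free <- arrowhead_class(mapping, tok_free)
    map_anchor <- arrowhead_class(mapping, tok_anchor)
    tok_any <- Filter(nzchar, c(tok_anchor, tok_free))
    map_any <- if (!is.null(map_anchor)) map_anchor else map_free

    leg_iri <- sprintf("%s/WP/Interaction/%s", ctx$iri_prefix, e$graph_id)
    gpml_leg_iri <- sprintf("%s/Interaction/%s", ctx$iri_prefix, e$graph_id)

    emit_regulator <- function(class, src_iri, iri = leg_iri,
                               about = gpml_leg_iri) {
      interactions[[length(interactions) + 1L]] <<- new_interaction(
        iri, paste0("wp:", class), c(src_iri, spine_iri),
        source = src_iri, target = spine_iri,
        pathway = ctx$pathway_iri, about = about)
    }

    free_res <- resolve_endpoint(free_pt$graph_ref, ctx)
    if (!is.null(free_res$reason)) {
      # a regulator leg from an unresolved (isoenzyme) group can still be
      # expanded into per-member duplicates when the flag is on
      gr <- if (!is.null(free_res$group_id))
        ctx$group_res[[free_res$group_id]] else NULL
      if (expand_isoenzymes && !is.null(gr) &&
          length(gr$member_iris) > 0 &&
          !is.null(map_any) && map_any$class %in% REGULATOR_CLASSES) {
        for (m in gr$member_iris) {
          emit_regulator(map_any$class, m,
                         iri = sprintf("%s_%s", leg_iri,
                                       gsub("[^A-Za-z0-9]", "", m)))
        }
        next
      }
      reject(e$graph_id, free_res$reason)
      next
    }

    if (!is.null(map_any) && map_any$class %in% REGULATOR_CLASSES) {
      emit_regulator(map_any$class, free_res$iri)
      if (expand_isoenzymes && !is.null(free_res$group_id)) {
        gr <- ctx$group_res[[free_res$group_id]]
        for (m in gr$member_iris) {
          emit_regulator(map_any$class, m,
                         iri = sprintf("%s_%s", leg_iri,
                                       gsub("[^A-Za-z0-9]", "", m)))
        }
      }
    } else if (length(tok_any) == 0 || !is.null(map_any)) {
      # plain participant leg, or a directional non-regulator token (an
      # extra input/output of the reaction): recorded as an extra
      # participant; the single source/target slots keep the spine
      # endpoints
      interactions[[spine_idx]]$participants <- sort(unique(
        c(interactions[[spine_idx]]$participants, free_res$iri)))
      merged[nrow(merged) + 1L, ] <- list(e$graph_id,
                                          interactions[[spine_idx]]$iri)
    } else {
      emit_regulator("DirectedInteraction", free_res$iri)
      notes <- c(notes, sprintf("unsupported_arrowhead on %s (%s)",
                                e$graph_id, paste(tok_any, collapse = ", ")))
    }
  }

  list(interactions = interactions, rejections = rejections,
       merged = merged, notes = notes)
}

#' Harmonize a group into a complex binding
#'
#' A group of style `Complex` with at least two resolved members yields one
#' `ComplexBinding` whose participants are the complex node plus all member
#' IRIs, and one undirected pairwise connection per unordered member pair
#' (which is how the semantic layer keeps complex members connected).
#' The complex node itself is rejected as `unannotated_complex` when no
#' identified Complex datanode backs the group; the binding still refers to
#' a minted complex IRI so the membership stays queryable.
#'
#' @param g A [gpml_group()].
#' @param p The owning [gpml_pathway()].
#' @param resolutions Named list of per-node resolutions.
#' @param ctx Context (internal); built by [build_semantic_layer()].
#' @return `list(interactions, complex_iri, member_iris, status, reason)`.
#' @export
harmonize_group <- function(g, p, resolutions, ctx) {
  members <- group_members(p, g)
  res <- resolutions[members]
  ok <- vapply(res, function(r) isTRUE(r$accepted), logical(1))

  if (g$style != "Complex") {
    # user-defined grouping (often isoenzymes): not a biological complex
    return(list(interactions = list(), complex_iri = NULL,
                member_iris = sort(unique(vapply(res[ok], `[[`, "", "iri"))),
                status = "rejected", reason = "group_unresolved"))
  }

  # an identified Complex datanode inside the group names the complex
  complex_member <- NULL
  for (m in members) {
    r <- res[[m]]
    if (isTRUE(r$accepted) && r$type_class == "wp:Complex") {
      complex_member <- r
      break
    }
  }
  member_iris <- sort(unique(vapply(res[ok], `[[`, "", "iri")))
  if (!is.null(complex_member)) {
    member_iris <- setdiff(member_iris, complex_member$iri)
  }

  if (length(member_iris) == 0) {
    return(list(interactions = list(), complex_iri = NULL,
                member_iris = character(0),
                status = "rejected", reason = "group_unresolved"))
  }
  if (length(member_iris) == 1) {
    return(list(interactions = list(), complex_iri = NULL,
                member_iris = member_iris,
                status = "degenerate", reason = "single_member"))
  }

  annotated <- !is.null(complex_member)
  complex_iri <- if (annotated) complex_member$iri else
    sprintf("%s/Complex/%s", ctx$iri_prefix, g$group_id)
  bind_graphid <- if (nzchar(g$graph_id)) g$graph_id else g$group_id
  binding_iri <- sprintf("%s/ComplexBinding/%s", ctx$iri_prefix, bind_graphid)

  interactions <- list(new_interaction(
    binding_iri, "wp:ComplexBinding", c(complex_iri, member_iris),
    pathway = ctx$pathway_iri,
    about = sprintf("%s/Group/%s", ctx$iri_prefix, g$group_id)))

  pairs <- utils::combn(member_iris, 2, simplify = FALSE)
  for (pr in pairs) {
    pr <- sort(pr)
    iri <- sprintf("%s/pair/%s_%s", binding_iri,
                   gsub("[^A-Za-z0-9]", "", pr[1]),
                   gsub("[^A-Za-z0-9]", "", pr[2]))
    interactions[[length(interactions) + 1L]] <- new_interaction(
      iri, "wp:Interaction", pr, pathway = ctx$pathway_iri)
  }

  list(interactions = interactions, complex_iri = complex_iri,
       member_iris = member_iris,
       status = if (annotated) "accepted" else "unannotated",
       reason = if (annotated) NA_character_ else "unannotated_complex")
}

#' Build both graph layers from a pathway drawing
#'
#' Runs the full harmonization: datanode resolution, edge bundling, bundle
#' classification and group expansion, then materialises the graphical layer
#' (every drawn element) and the semantic layer (accepted content only),
#' linked by `wp:isAbout` triples. All problems become conversion-log
#' entries, never errors.
#'
#' @param p A [gpml_pathway()].
#' @param registry Datasource registry (see [default_datasource_registry()]).
#' @param mapping Arrowhead map (see [default_arrowhead_map()]).
#' @param expand_isoenzymes Emit duplicate regulator interactions for group
#'   members (off by default).
#' @return An object of class `semantic_layers`: `list(wp, gpml, log)` where
#'   `wp` and `gpml` are [triple_graph()]s and `log` is the conversion log.
#' @examples
#' fx <- make_fixture(fixture_spec("Conversion", "MIM"))
#' layers <- build_semantic_layer(fx$pathway)
#' layers$log
#' @export
build_semantic_layer <- function(p, registry = default_datasource_registry(),
                                 mapping = default_arrowhead_map(),
                                 expand_isoenzymes = FALSE) {
  stopifnot(inherits(p, "gpml_pathway"))
  p <- sort_pathway(p)   # deterministic iteration everywhere

  resolutions <- stats::setNames(
    lapply(p$nodes, resolve_datanode, registry = registry),
    vapply(p$nodes, `[[`, "", "graph_id"))

  ctx <- semantify_context(p, resolutions)

  # groups first: edge endpoints may refer to complexes
  group_res <- list()
  group_log <- data.frame(group_id = character(0), status = character(0),
                          reason = character(0), binding_iri = character(0),
                          stringsAsFactors = FALSE)
  group_interactions <- list()
  for (g in p$groups) {
    hg <- harmonize_group(g, p, resolutions, ctx)
    group_res[[g$group_id]] <- hg
    binding_iri <- if (length(hg$interactions) > 0)
      hg$interactions[[1]]$iri else NA_character_
    group_log[nrow(group_log) + 1L, ] <- list(
      g$group_id,
      if (hg$status %in% c("accepted", "unannotated")) "accepted" else
        hg$status,
      if (is.na(hg$reason %||% NA_character_)) NA_character_ else hg$reason,
      binding_iri)
    group_interactions <- c(group_interactions, hg$interactions)
  }
  ctx$group_res <- group_res

  bundles <- bundle_edges(p)
  interactions <- group_interactions
  edge_rej <- data.frame(graph_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  merged <- data.frame(graph_id = character(0), iri = character(0),
                       stringsAsFactors = FALSE)
  notes <- character(0)
  for (b in bundles) {
    cb <- classify_bundle(b, ctx, mapping,
                          expand_isoenzymes = expand_isoenzymes)
    interactions <- c(interactions, cb$interactions)
    edge_rej <- rbind(edge_rej, cb$rejections)
    merged <- rbind(merged, cb$merged)
    notes <- c(notes, cb$notes)
  }

  layers <- materialize_layers(p, resolutions, interactions, ctx, merged)
  log <- build_conversion_log(p, resolutions, interactions, edge_rej,
                              group_log, notes, ctx, merged)
  structure(list(wp = layers$wp, gpml = layers$gpml, log = log),
            class = "semantic_layers")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fill both triple graphs from the classification results
materialize_layers <- function(p, resolutions, interactions, ctx,
                               merged = NULL) {
  wp <- triple_graph("wp_layer")
  gp <- triple_graph("gpml_layer")
  P <- WP_PREDICATES
  pw <- ctx$pathway_iri

  add_triple(wp, pw, P[["type"]], "wp:Pathway")
  if (nzchar(p$title)) add_triple(wp, pw, P[["label"]], p$title,
                                  literal = TRUE)
  gpml_pw <- ctx$iri_prefix
  add_triple(gp, gpml_pw, P[["type"]], "gpml:Pathway")

  for (n in p$nodes) {
    giri <- sprintf("%s/DataNode/%s", ctx$iri_prefix, n$graph_id)
    add_triple(gp, giri, P[["type"]], "gpml:DataNode")
    add_triple(gp, giri, "gpml:graphId", n$graph_id, literal = TRUE)
    add_triple(gp, giri, "gpml:declaredType", n$type, literal = TRUE)
    add_triple(gp, giri, P[["label"]], n$text_label, literal = TRUE)
    add_triple(gp, giri, P[["isPartOf"]], gpml_pw)
    r <- resolutions[[n$graph_id]]
    if (isTRUE(r$accepted)) {
      # pathway nodes are typed only as plain datanodes in the semantic
      # layer (a data-model quirk of the upstream vocabulary, kept so
      # outputs stay comparable); everything else keeps its specific class
      cls <- if (r$type_class == "wp:Pathway") "wp:Datanode" else r$type_class
      add_triple(wp, r$iri, P[["type"]], cls)
      add_triple(wp, r$iri, P[["label"]], r$label, literal = TRUE)
      add_triple(wp, r$iri, P[["identifierSource"]], r$identifier_source,
                 literal = TRUE)
      add_triple(wp, r$iri, P[["identifierId"]], r$identifier_id,
                 literal = TRUE)
      add_triple(wp, r$iri, P[["isPartOf"]], pw)
      add_triple(gp, giri, P[["isAbout"]], r$iri)
    }
  }

  for (lb in p$labels) {
    giri <- sprintf("%s/Label/%s", ctx$iri_prefix, lb$graph_id)
    add_triple(gp, giri, P[["type"]], "gpml:Label")
    add_triple(gp, giri, "gpml:graphId", lb$graph_id, literal = TRUE)
    add_triple(gp, giri, P[["label"]], lb$text_label, literal = TRUE)
    add_triple(gp, giri, P[["isPartOf"]], gpml_pw)
  }

  for (g in p$groups) {
    giri <- sprintf("%s/Group/%s", ctx$iri_prefix, g$group_id)
    add_triple(gp, giri, P[["type"]], "gpml:Group")
    add_triple(gp, giri, "gpml:style", g$style, literal = TRUE)
    if (nzchar(g$graph_id)) {
      add_triple(gp, giri, "gpml:graphId", g$graph_id, literal = TRUE)
    }
    add_triple(gp, giri, P[["isPartOf"]], gpml_pw)
  }

  for (e in p$edges) {
    giri <- sprintf("%s/Interaction/%s", ctx$iri_prefix, e$graph_id)
    add_triple(gp, giri, P[["type"]], "gpml:Interaction")
    add_triple(gp, giri, "gpml:graphId", e$graph_id, literal = TRUE)
    add_triple(gp, giri, P[["isPartOf"]], gpml_pw)
    for (pt in e$points[c(1L, length(e$points))]) {
      if (nzchar(pt$graph_ref)) {
        add_triple(gp, giri, "gpml:graphRef", pt$graph_ref, literal = TRUE)
      }
      if (nzchar(pt$arrow_head)) {
        add_triple(gp, giri, "gpml:arrowHead", pt$arrow_head, literal = TRUE)
      }
    }
    for (a in e$anchors) {
      airi <- sprintf("%s/Anchor/%s", ctx$iri_prefix, a$anchor_id)
      add_triple(gp, airi, P[["type"]], "gpml:Anchor")
      add_triple(gp, airi, "gpml:graphId", a$anchor_id, literal = TRUE)
      add_triple(gp, airi, "gpml:anchorOf", giri)
    }
    if (nzchar(e$xref_datasource)) {
      add_triple(gp, giri, P[["identifierSource"]], e$xref_datasource,
                 literal = TRUE)
      add_triple(gp, giri, P[["identifierId"]], e$xref_id, literal = TRUE)
    }
  }

  edge_xref <- stats::setNames(
    lapply(p$edges, function(e)
      list(source = e$xref_datasource, id = e$xref_id)),
    vapply(p$edges, `[[`, "", "graph_id"))

  for (i in interactions) {
    add_triple(wp, i$iri, P[["type"]], i$type_class)
    for (pa in i$participants) add_triple(wp, i$iri, P[["participant"]], pa)
    if (!is.na(i$source)) add_triple(wp, i$iri, P[["source"]], i$source)
    if (!is.na(i$target)) add_triple(wp, i$iri, P[["target"]], i$target)
    add_triple(wp, i$iri, P[["isPartOf"]], i$pathway)
    if (!is.na(i$about %||% NA_character_)) {
      add_triple(gp, i$about, P[["isAbout"]], i$iri)
      gid <- sub(".*/", "", i$about)
      xr <- edge_xref[[gid]]
      if (!is.null(xr) && nzchar(xr$source)) {
        add_triple(wp, i$iri, P[["identifierSource"]], xr$source,
                   literal = TRUE)
        add_triple(wp, i$iri, P[["identifierId"]], xr$id, literal = TRUE)
      }
    }
    # complexes minted for unannotated groups still need a typed node
    for (pa in i$participants) {
      if (grepl("/Complex/", pa, fixed = TRUE) &&
          length(objects_of(wp, pa, P[["type"]])) == 0) {
        add_triple(wp, pa, P[["type"]], "wp:Complex")
        add_triple(wp, pa, P[["isPartOf"]], pw)
      }
    }
  }

  # legs folded into a spine as extra participants are still converted
  if (!is.null(merged)) {
    for (i in seq_len(nrow(merged))) {
      add_triple(gp,
                 sprintf("%s/Interaction/%s", ctx$iri_prefix,
                         merged$graph_id[i]),
                 P[["isAbout"]], merged$iri[i])
    }
  }

  list(wp = wp, gpml = gp)
}

build_conversion_log <- function(p, resolutions, interactions, edge_rej,
                                 group_log, notes, ctx, merged = NULL) {
  nodes <- do.call(rbind, c(list(
    data.frame(graph_id = character(0), label = character(0),
               type = character(0), outcome = character(0),
               reason = character(0), iri = character(0),
               stringsAsFactors = FALSE)),
    lapply(p$nodes, function(n) {
      r <- resolutions[[n$graph_id]]
      data.frame(
        graph_id = n$graph_id, label = n$text_label, type = n$type,
        outcome = if (isTRUE(r$accepted)) "accepted" else "rejected",
        reason = if (isTRUE(r$accepted)) NA_character_ else r$reason,
        iri = if (isTRUE(r$accepted)) r$iri else NA_character_,
        stringsAsFactors = FALSE)
    })))

  # labels are drawn content, never biological nodes
  if (length(p$labels) > 0) {
    nodes <- rbind(nodes, do.call(rbind, lapply(p$labels, function(lb) {
      data.frame(graph_id = lb$graph_id, label = lb$text_label,
                 type = "Label", outcome = "rejected",
                 reason = "label_not_node", iri = NA_character_,
                 stringsAsFactors = FALSE)
    })))
  }
  # unannotated complexes
  for (i in seq_len(nrow(group_log))) {
    if (identical(group_log$reason[i], "unannotated_complex")) {
      nodes <- rbind(nodes, data.frame(
        graph_id = group_log$group_id[i], label = "", type = "Complex",
        outcome = "rejected", reason = "unannotated_complex",
        iri = NA_character_, stringsAsFactors = FALSE))
    }
  }

  edge_ids <- vapply(p$edges, `[[`, "", "graph_id")
  iri_by_edge <- list()
  for (i in interactions) {
    if (is.na(i$about %||% NA_character_)) next
    gid <- sub(".*/", "", i$about)
    iri_by_edge[[gid]] <- c(iri_by_edge[[gid]], i$iri)
  }
  if (!is.null(merged)) {
    for (i in seq_len(nrow(merged))) {
      iri_by_edge[[merged$graph_id[i]]] <-
        c(iri_by_edge[[merged$graph_id[i]]], merged$iri[i])
    }
  }
  edges <- do.call(rbind, c(list(
    data.frame(graph_id = character(0), status = character(0),
               reason = character(0), interaction_iris = character(0),
               stringsAsFactors = FALSE)),
    lapply(sort(edge_ids), function(id) {
      rej <- edge_rej$reason[edge_rej$graph_id == id]
      data.frame(
        graph_id = id,
        status = if (length(rej) > 0) "rejected" else "accepted",
        reason = if (length(rej) > 0) rej[1] else NA_character_,
        interaction_iris = paste(iri_by_edge[[id]], collapse = ";"),
        stringsAsFactors = FALSE)
    })))

  structure(
    list(nodes = nodes, edges = edges, groups = group_log, notes = notes),
    class = "conversion_log")
}

#' @export
print.conversion_log <- function(x, ...) {
  na <- sum(x$nodes$outcome == "accepted" & x$nodes$type != "Label")
  nr <- sum(x$nodes$outcome == "rejected")
  ea <- sum(x$edges$status == "accepted")
  er <- sum(x$edges$status == "rejected")
  cat(sprintf("<conversion_log: %d/%d nodes accepted, %d/%d edges accepted>\n",
              na, na + nr, ea, ea + er))
  if (er > 0) {
    tab <- table(x$edges$reason[x$edges$status == "rejected"])
    cat("  edge rejections:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write the conversion log as CSV files
#'
#' Emits `<stem>_nodes.csv`, `<stem>_edges.csv` and `<stem>_groups.csv`.
#'
#' @param log A conversion log from [build_semantic_layer()].
#' @param stem Output path stem.
#' @return The paths written, invisibly.
#' @export
write_conversion_log <- function(log, stem) {
  paths <- c(nodes = paste0(stem, "_nodes.csv"),
             edges = paste0(stem, "_edges.csv"),
             groups = paste0(stem, "_groups.csv"))
  utils::write.csv(log$nodes, paths[["nodes"]], row.names = FALSE)
  utils::write.csv(log$edges, paths[["edges"]], row.names = FALSE)
  utils::write.csv(log$groups, paths[["groups"]], row.names = FALSE)
  invisible(paths)
}
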