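#' Network queries over the semantic layer
#'
#' The semantic layer is a directed biological network: directed
#' interactions run from their source to their target, catalysis links an
#' enzyme to the reaction it drives, and the reaction's product is what the
#' enzyme ultimately feeds. These queries answer the two standard use
#' cases: who is directly up-/downstream of a node, and in what order do
#' enzymes act along a chain of conversions.
#'
#' @name network_analysis
NULL

# node IRIs whose label matches (exact by default) or whose IRI matches
match_query_nodes <- function(wp, query, ignore_case = FALSE) {
  P <- WP_PREDICATES
  labs <- match_triples(wp, predicate = P[["label"]])
  hit <- if (ignore_case) {
    tolower(labs$object) == tolower(query)
  } else {
    labs$object == query
  }
  iris <- unique(labs$subject[hit])
  if (query %in% subjects_with(wp, P[["type"]])) {
    iris <- unique(c(iris, query))
  }
  # only datanodes, not pathways or interactions
  iris[vapply(iris, function(i)
    any(types_of(wp, i) == "wp:Datanode"), logical(1))]
}

#' Direct up- and downstream neighbors of a node
#'
#' Upstream rows are directed interactions with the query node as target;
#' downstream rows have it as source. Undirected interactions are excluded.
#' One row is emitted per label combination (drawn nodes sharing one
#' identifier contribute one row per label, matching how label-based
#' queries report).
#'
#' @param wp Semantic layer.
#' @param query Node label (exact match) or identifier IRI.
#' @param direction `"upstream"`, `"downstream"` or `"both"`.
#' @param ignore_case Match labels case-insensitively.
#' @return Data frame `source`, `source_label`, `target`, `target_label`,
#'   `pathway`, `interaction`, sorted by pathway then interaction IRI.
#'   Empty (with a notice) when no node matches.
#' @export
direct_neighbors <- function(wp, query,
                             direction = c("both", "upstream", "downstream"),
                             ignore_case = FALSE) {
  direction <- match.arg(direction)
  P <- WP_PREDICATES
  empty <- data.frame(source = character(0), source_label = character(0),
                      target = character(0), target_label = character(0),
                      pathway = character(0), interaction = character(0),
                      stringsAsFactors = FALSE)
  nodes <- match_query_nodes(wp, query, ignore_case)
  if (length(nodes) == 0) {
    message("no node matching \"", query, "\"")
    return(empty)
  }
  labels_of <- function(iri) {
    lb <- objects_of(wp, iri, P[["label"]])
    if (length(lb) == 0) NA_character_ else sort(unique(lb))
  }
  directed <- resources_of_class(wp, "wp:DirectedInteraction")
  rows <- list()
  for (iri in directed) {
    src <- objects_of(wp, iri, P[["source"]])
    tgt <- objects_of(wp, iri, P[["target"]])
    if (length(src) != 1 || length(tgt) != 1) next
    want <- (direction %in% c("upstream", "both") && tgt %in% nodes) ||
            (direction %in% c("downstream", "both") && src %in% nodes)
    if (!want) next
    pw <- objects_of(wp, iri, P[["isPartOf"]])
    pw <- if (length(pw) == 0) NA_character_ else pw[1]
    for (sl in labels_of(src)) {
      for (tl in labels_of(tgt)) {
        rows[[length(rows) + 1L]] <- data.frame(
          source = src, source_label = sl, target = tgt, target_label = tl,
          pathway = pw, interaction = iri, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(list(empty), rows))
  out <- out[order(out$pathway, out$interaction, out$source_label,
                   out$target_label, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enzyme--conversion catalysis table
#'
#' One row per (catalysis, catalyzed directed interaction, substrate label,
#' product label): the enzyme driving the reaction, the reaction's source
#' metabolite (substrate) and target metabolite (product). With
#' `strict = TRUE` only reactions explicitly typed as conversions qualify;
#' otherwise any catalyzed directed interaction is reported.
#'
#' @param wp Semantic layer.
#' @param pathway Pathway IRI to restrict to, or `NULL` for all.
#' @param strict Restrict to conversion-typed reactions.
#' @return Data frame `enzyme`, `substrate`, `substrate_label`, `product`,
#'   `product_label`, `conversion`.
#' @export
catalysis_table <- function(wp, pathway = NULL, strict = FALSE) {
  P <- WP_PREDICATES
  empty <- data.frame(enzyme = character(0), substrate = character(0),
                      substrate_label = character(0), product = character(0),
                      product_label = character(0), conversion = character(0),
                      stringsAsFactors = FALSE)
  catas <- resources_of_class(wp, "wp:Catalysis")
  rows <- list()
  for (ca in catas) {
    if (!is.null(pathway)) {
      pw <- objects_of(wp, ca, P[["isPartOf"]])
      if (!pathway %in% pw) next
    }
    enz <- objects_of(wp, ca, P[["source"]])
    conv <- objects_of(wp, ca, P[["target"]])
    if (length(enz) != 1 || length(conv) != 1) next
    if (!"wp:DirectedInteraction" %in% types_of(wp, conv)) next
    if (strict && !"wp:Conversion" %in% types_of(wp, conv)) next
    sub_iri <- objects_of(wp, conv, P[["source"]])
    prd_iri <- objects_of(wp, conv, P[["target"]])
    if (length(sub_iri) != 1 || length(prd_iri) != 1) next
    slabs <- objects_of(wp, sub_iri, P[["label"]])
    plabs <- objects_of(wp, prd_iri, P[["label"]])
    if (length(slabs) == 0) slabs <- NA_character_
    if (length(plabs) == 0) plabs <- NA_character_
    for (sl in sort(unique(slabs))) {
      for (pl in sort(unique(plabs))) {
        rows[[length(rows) + 1L]] <- data.frame(
          enzyme = enz, substrate = sub_iri, substrate_label = sl,
          product = prd_iri, product_label = pl, conversion = conv,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(list(empty), rows))
  out <- out[order(out$conversion, out$enzyme, out$substrate_label,
                   out$product_label, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Order of enzymes along shared metabolites
#'
#' A pair `(E1, E2, M)` is reported whenever enzyme `E1` catalyzes a
#' reaction producing metabolite `M` and `E2` catalyzes a reaction consuming
#' `M`: anything affecting the upstream enzyme also affects the downstream
#' reaction through substrate availability. The pairs are exactly the
#' substrate--product joins of [catalysis_table()]; longer-range ordering is
#' available through [reachable()].
#'
#' @param wp Semantic layer.
#' @param pathway Pathway IRI restriction, or `NULL`.
#' @param strict Passed to [catalysis_table()].
#' @return Data frame `upstream_enzyme`, `downstream_enzyme`,
#'   `shared_metabolite`.
#' @export
enzyme_order <- function(wp, pathway = NULL, strict = FALSE) {
  ct <- catalysis_table(wp, pathway, strict = strict)
  ct <- unique(ct[c("enzyme", "substrate", "product")])
  rows <- list()
  for (i in seq_len(nrow(ct))) {
    down <- ct[ct$substrate == ct$product[i], , drop = FALSE]
    for (j in seq_len(nrow(down))) {
      rows[[length(rows) + 1L]] <- data.frame(
        upstream_enzyme = ct$enzyme[i],
        downstream_enzyme = down$enzyme[j],
        shared_metabolite = ct$product[i],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(list(
    data.frame(upstream_enzyme = character(0),
               downstream_enzyme = character(0),
               shared_metabolite = character(0),
               stringsAsFactors = FALSE)), rows))
  out <- unique(out)
  out <- out[order(out$upstream_enzyme, out$downstream_enzyme,
                   out$shared_metabolite, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# adjacency used by reachable(): one hop from a node IRI
reach_step <- function(wp, iri, direction, through_complexes = FALSE) {
  P <- WP_PREDICATES
  out <- character(0)
  if (direction == "downstream") {
    for (i in subjects_with(wp, P[["source"]], iri)) {
      tgt <- objects_of(wp, i, P[["target"]])
      for (t in tgt) {
        if ("wp:Interaction" %in% types_of(wp, t) &&
            !"wp:Datanode" %in% types_of(wp, t)) {
          # catalysis onto a reaction: the enzyme reaches the product
          out <- c(out, objects_of(wp, t, P[["target"]]))
        } else {
          out <- c(out, t)
        }
      }
    }
  } else {
    for (i in subjects_with(wp, P[["target"]], iri)) {
      src <- objects_of(wp, i, P[["source"]])
      out <- c(out, src)
    }
    # reactions producing iri are targets of catalysis: their enzymes are
    # upstream of iri
    for (i in subjects_with(wp, P[["target"]], iri)) {
      for (reg in subjects_with(wp, P[["target"]], i)) {
        out <- c(out, objects_of(wp, reg, P[["source"]]))
      }
    }
  }
  if (through_complexes) {
    for (b in subjects_with(wp, P[["participant"]], iri)) {
      if ("wp:ComplexBinding" %in% types_of(wp, b)) {
        out <- c(out, objects_of(wp, b, P[["participant"]]))
      }
    }
  }
  out <- out[vapply(out, function(x)
    "wp:Datanode" %in% types_of(wp, x), logical(1))]
  sort(unique(out))
}

#' Depth-limited reachability over directed interactions
#'
#' Breadth-first traversal from a start node, following directed
#' interactions source-to-target (or the converse for `upstream`) and
#' passing through catalysis links, so an enzyme reaches the products of
#' the reactions it drives. The start node itself is excluded.
#'
#' @param wp Semantic layer.
#' @param start Node IRI.
#' @param direction `"downstream"` or `"upstream"`.
#' @param max_depth Maximum number of hops; `0` reaches nothing.
#' @param through_complexes Also traverse complex-binding membership.
#' @return Sorted character vector of reachable node IRIs.
#' @export
reachable <- function(wp, start,
                      direction = c("downstream", "upstream"),
                      max_depth = Inf, through_complexes = FALSE) {
  direction <- match.arg(direction)
  seen <- character(0)
  frontier <- start
  depth <- 0
  while (length(frontier) > 0 && depth < max_depth) {
    nxt <- unique(unlist(lapply(frontier, reach_step, wp = wp,
                                direction = direction,
                                through_complexes = through_complexes)))
    nxt <- setdiff(nxt, c(seen, start))
    seen <- c(seen, nxt)
    frontier <- nxt
    depth <- depth + 1
  }
  sort(seen)
}
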