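# Independent oracles used by the property tests. These work directly on
# the drawing-level model and deliberately share no code with the
# converter or the graph store.

# brute-force reachability over the drawing: a directed step exists from
# node A to node B when a line runs A -> B whose end point carries any
# arrowhead token, and both nodes carry an xref (i.e. would be accepted).
# Only plain node-to-node lines are considered (the random pathways the
# property tests generate contain nothing else).
oracle_reachable_drawing <- function(p, start_graph_id,
                                     direction = "downstream",
                                     max_depth = Inf) {
  accepted <- vapply(p$nodes, function(n) {
    nzchar(n$xref_datasource) && nzchar(n$xref_id) && n$type != "Unknown"
  }, logical(1))
  ok_ids <- vapply(p$nodes, `[[`, "", "graph_id")[accepted]

  steps <- list()
  for (e in p$edges) {
    from <- e$points[[1]]$graph_ref
    to <- e$points[[length(e$points)]]$graph_ref
    head_tok <- e$points[[length(e$points)]]$arrow_head
    tail_tok <- e$points[[1]]$arrow_head
    if (!(from %in% ok_ids) || !(to %in% ok_ids)) next
    if (nzchar(head_tok)) steps[[length(steps) + 1L]] <- c(from, to)
    if (nzchar(tail_tok)) steps[[length(steps) + 1L]] <- c(to, from)
  }
  if (direction == "upstream") {
    steps <- lapply(steps, rev)
  }
  seen <- character(0)
  frontier <- start_graph_id
  depth <- 0
  while (length(frontier) > 0 && depth < max_depth) {
    nxt <- unique(unlist(lapply(steps, function(s) {
      if (s[1] %in% frontier) s[2] else NULL
    })))
    nxt <- setdiff(nxt, c(seen, start_graph_id))
    seen <- c(seen, nxt)
    frontier <- nxt
    depth <- depth + 1
  }
  sort(seen)
}

# identifier IRI a random-pathway node would resolve to (mirrors the
# generator's id scheme, not the converter)
oracle_node_iri <- function(p, graph_id) {
  for (n in p$nodes) {
    if (n$graph_id == graph_id) {
      prefix <- c(Ensembl = "ensembl", HMDB = "hmdb")[[n$xref_datasource]]
      return(paste0(prefix, ":", n$xref_id))
    }
  }
  NA_character_
}

# all (graph_id -> iri) pairs for accepted nodes of a random pathway
oracle_iri_map <- function(p) {
  ids <- vapply(p$nodes, `[[`, "", "graph_id")
  ok <- vapply(p$nodes, function(n)
    nzchar(n$xref_datasource) && nzchar(n$xref_id), logical(1))
  stats::setNames(
    vapply(ids[ok], function(g) oracle_node_iri(p, g), character(1)),
    ids[ok])
}
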