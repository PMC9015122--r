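#' Structural shapes for the nine interaction classes
#'
#' Each harmonized interaction class has a shape stating what a conforming
#' resource must look like: at least two participant IRIs for every class,
#' and exactly one source and one target for the directed classes, while
#' binding and complex binding forbid source/target (they are symmetric).
#' Validation dispatches on the most specific class of each interaction and
#' never consults an external engine; the shapes can also be exported as
#' ShEx-syntax text so external validators can be run on the same graph.
#'
#' @return A data frame with one row per interaction class: `class`,
#'   `min_participants`, `source_arity`, `target_arity` (`"exactly-one"` or
#'   `"forbidden"`), `participant_node_kind`.
#' @examples
#' default_shapes()
#' @export
default_shapes <- function() {
  cls <- WP_INTERACTION_CLASSES
  undirected <- cls %in% c("Binding", "ComplexBinding", "Interaction")
  data.frame(
    class = cls,
    min_participants = 2L,
    source_arity = ifelse(undirected, "forbidden", "exactly-one"),
    target_arity = ifelse(undirected, "forbidden", "exactly-one"),
    participant_node_kind = "IRI",
    stringsAsFactors = FALSE
  )
}

# most specific asserted interaction class of a resource, or NA
most_specific_class <- function(g, iri) {
  asserted <- objects_of(g, iri, WP_PREDICATES[["type"]])
  asserted <- intersect(asserted, paste0("wp:", WP_INTERACTION_CLASSES))
  if (length(asserted) == 0) return(NA_character_)
  # the class whose closure is largest is the most specific
  depth <- vapply(asserted, function(cl) length(class_closure(cl)),
                  integer(1))
  sub("^wp:", "", asserted[which.max(depth)])
}

#' Validate a semantic layer against the interaction shapes
#'
#' Every interaction in the graph is evaluated against exactly one shape:
#' the one for its most specific class. The generic `Interaction` shape
#' treats source/target as forbidden since an undirected connection carries
#' no direction slots.
#'
#' @param g A semantic-layer [triple_graph()].
#' @param shapes Shape table from [default_shapes()].
#' @return An object of class `validation_report`: a list with
#'   `per_interaction` (data frame `iri`, `shape`, `conforms`, `violations`),
#'   `summary` (violation counts per class) and `conforms` (overall flag).
#' @export
validate_shapes <- function(g, shapes = default_shapes()) {
  P <- WP_PREDICATES
  iris <- resources_of_class(g, "wp:Interaction")
  rows <- lapply(iris, function(iri) {
    cls <- most_specific_class(g, iri)
    sh <- shapes[shapes$class == cls, ]
    if (nrow(sh) == 0) {
      return(data.frame(iri = iri, shape = cls, conforms = FALSE,
                        violations = "no shape for class",
                        stringsAsFactors = FALSE))
    }
    v <- character(0)
    parts <- objects_of(g, iri, P[["participant"]])
    if (length(parts) < sh$min_participants) {
      v <- c(v, sprintf("two or more participants required (found %d)",
                        length(parts)))
    }
    for (slot in c("source", "target")) {
      n <- length(objects_of(g, iri, P[[slot]]))
      arity <- sh[[paste0(slot, "_arity")]]
      if (arity == "exactly-one" && n != 1L) {
        v <- c(v, sprintf("exactly one %s required (found %d)", slot, n))
      }
      if (arity == "forbidden" && n != 0L) {
        v <- c(v, sprintf("%s forbidden for %s (found %d)", slot, cls, n))
      }
    }
    lit <- match_triples(g, subject = iri, predicate = P[["participant"]])
    if (any(lit$is_literal)) {
      v <- c(v, "participants must be IRIs")
    }
    data.frame(iri = iri, shape = cls, conforms = length(v) == 0,
               violations = paste(v, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, c(list(
    data.frame(iri = character(0), shape = character(0),
               conforms = logical(0), violations = character(0),
               stringsAsFactors = FALSE)), rows))
  bad <- per[!per$conforms, , drop = FALSE]
  summary <- if (nrow(bad) > 0) {
    as.data.frame(table(class = bad$shape), stringsAsFactors = FALSE)
  } else {
    data.frame(class = character(0), Freq = integer(0))
  }
  names(summary) <- c("class", "violations")
  structure(list(per_interaction = per, summary = summary,
                 conforms = all(per$conforms)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  n <- nrow(x$per_interaction)
  bad <- sum(!x$per_interaction$conforms)
  cat(sprintf("<validation_report: %d interactions, %d violation(s)%s>\n",
              n, bad, if (x$conforms) ", conforms" else ""))
  if (bad > 0) print(x$per_interaction[!x$per_interaction$conforms, ])
  invisible(x)
}

#' Export the shapes as ShEx-syntax text
#'
#' Writes one shape per interaction class in ShEx compact syntax, mirroring
#' the layout of the published shape directory, so external ShEx validators
#' can check the same constraints.
#'
#' @param shapes Shape table from [default_shapes()].
#' @param path Output `.shex` file path.
#' @return `path`, invisibly.
#' @export
export_shex <- function(shapes = default_shapes(), path) {
  ns <- vocab_namespaces()
  lines <- c(
    sprintf("PREFIX wp: <%s>", ns[["wp"]]),
    sprintf("PREFIX rdf: <%s>", ns[["rdf"]]),
    ""
  )
  for (i in seq_len(nrow(shapes))) {
    sh <- shapes[i, ]
    body <- c(
      sprintf("  rdf:type [wp:%s] ;", sh$class),
      sprintf("  wp:participants IRI {%d,} %s", sh$min_participants,
              if (sh$source_arity == "exactly-one") ";" else "")
    )
    if (sh$source_arity == "exactly-one") {
      body <- c(body, "  wp:source IRI ;", "  wp:target IRI")
    }
    lines <- c(lines,
               sprintf("<%sShape> {", sh$class), body, "}", "")
  }
  writeLines(lines, path)
  invisible(path)
}
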