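#' Controlled vocabularies for the two graph layers
#'
#' The semantic layer uses a small controlled vocabulary of node classes and
#' interaction classes, with a fixed subclass hierarchy: every interaction
#' class is a subclass of `Interaction`, and every class except `Binding` and
#' `ComplexBinding` is additionally a subclass of `DirectedInteraction`.
#' On the node side, `Protein` and `Rna` are subclasses of `GeneProduct`, and
#' every concrete node class is a subclass of `Datanode`.
#'
#' Class IRIs are kept as compact CURIEs (`wp:Conversion`, `gpml:DataNode`);
#' the namespace each prefix expands to is configurable via [vocab_namespaces()]
#' so the official vocabulary base IRI can be swapped in.
#'
#' @name vocab
NULL

# node classes of the semantic layer
WP_NODE_CLASSES <- c(
  "Datanode", "GeneProduct", "Protein", "Metabolite", "Rna", "Complex",
  "Pathway"
)

# the nine harmonized interaction classes
WP_INTERACTION_CLASSES <- c(
  "Interaction", "DirectedInteraction", "Conversion", "Inhibition",
  "Catalysis", "Binding", "ComplexBinding", "Stimulation",
  "TranscriptionTranslation"
)

# direct-superclass table; closure computed by types_of()
.WP_SUPERCLASS <- list(
  # nodes
  "wp:GeneProduct" = "wp:Datanode",
  "wp:Protein"     = "wp:GeneProduct",
  "wp:Rna"         = "wp:GeneProduct",
  "wp:Metabolite"  = "wp:Datanode",
  "wp:Complex"     = "wp:Datanode",
  # wp:Pathway is the class of pathway resources, not of drawn datanodes;
  # drawn pathway-link nodes are typed plain wp:Datanode (upstream quirk)
  # interactions: all directed classes under DirectedInteraction,
  # Binding/ComplexBinding only under Interaction
  "wp:DirectedInteraction"      = "wp:Interaction",
  "wp:Conversion"               = "wp:DirectedInteraction",
  "wp:Inhibition"               = "wp:DirectedInteraction",
  "wp:Catalysis"                = "wp:DirectedInteraction",
  "wp:Stimulation"              = "wp:DirectedInteraction",
  "wp:TranscriptionTranslation" = "wp:DirectedInteraction",
  "wp:Binding"                  = "wp:Interaction",
  "wp:ComplexBinding"           = "wp:Binding"
)

# predicates shared by both layers
WP_PREDICATES <- c(
  type             = "rdf:type",
  participant      = "wp:participants",
  source           = "wp:source",
  target           = "wp:target",
  isPartOf         = "dcterms:isPartOf",
  isAbout          = "wp:isAbout",
  label            = "rdfs:label",
  identifierSource = "wp:identifierSource",
  identifierId     = "wp:identifierId"
)

.pathsem_ns_default <- c(
  wp    = "http://vocabularies.wikipathways.org/wp#",
  gpml  = "http://vocabularies.wikipathways.org/gpml#",
  rdf   = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs  = "http://www.w3.org/2000/01/rdf-schema#",
  dcterms = "http://purl.org/dc/terms/",
  base  = "http://rdf.wikipathways.org/Pathway/"
)

.pathsem_env <- new.env(parent = emptyenv())

#' Get or set the namespace table used for CURIE expansion
#'
#' @param ns Named character vector mapping prefixes to namespace IRIs; if
#'   missing, returns the current table. Partial updates are merged, so
#'   `vocab_namespaces(c(wp = "http://example.org/wp#"))` replaces only the
#'   `wp` entry.
#' @return The namespace table (invisibly when setting).
#' @export
vocab_namespaces <- function(ns) {
  if (is.null(.pathsem_env$ns)) .pathsem_env$ns <- .pathsem_ns_default
  if (missing(ns)) return(.pathsem_env$ns)
  stopifnot(is.character(ns), !is.null(names(ns)))
  cur <- .pathsem_env$ns
  cur[names(ns)] <- ns
  .pathsem_env$ns <- cur
  invisible(cur)
}

#' Superclass closure of a class CURIE
#'
#' Follows the fixed vocabulary hierarchy upward; a `wp:Conversion` yields
#' `c("wp:Conversion", "wp:DirectedInteraction", "wp:Interaction")`.
#'
#' @param class_iri Class CURIE, e.g. `"wp:Protein"`.
#' @return Character vector of class CURIEs including the input, most specific
#'   first.
#' @export
class_closure <- function(class_iri) {
  out <- character(0)
  cur <- class_iri
  while (!is.na(cur) && !(cur %in% out)) {
    out <- c(out, cur)
    cur <- .WP_SUPERCLASS[[cur]]
    if (is.null(cur)) cur <- NA_character_
  }
  out
}

# TRUE if class (or any superclass) matches `ancestor`
is_subclass_of <- function(class_iri, ancestor) {
  ancestor %in% class_closure(class_iri)
}
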