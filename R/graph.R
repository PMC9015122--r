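#' A minimal two-layer triple store
#'
#' Both graph layers (graphical and semantic) are held in the same container:
#' a mutable set of subject--predicate--object triples with set semantics.
#' Subjects and predicates are IRIs (compact CURIEs are treated as IRIs);
#' objects are IRIs or plain literals. The store supports wildcard matching
#' with deterministic (lexicographic) result order, class-closure queries via
#' the fixed vocabulary hierarchy, and Turtle import/export so externally
#' produced RDF dumps can be loaded for reporting.
#'
#' @param layer Either `"wp_layer"` (semantic) or `"gpml_layer"` (graphical).
#' @return An object of class `triple_graph`.
#' @examples
#' g <- triple_graph("wp_layer")
#' g <- add_triple(g, "ex:a", "rdf:type", "wp:Conversion")
#' match_triples(g, predicate = "rdf:type")
#' @export
triple_graph <- function(layer = c("wp_layer", "gpml_layer")) {
  layer <- match.arg(layer)
  g <- new.env(parent = emptyenv())
  g$layer <- layer
  g$triples <- data.frame(
    subject = character(0), predicate = character(0),
    object = character(0), is_literal = logical(0),
    stringsAsFactors = FALSE
  )
  class(g) <- "triple_graph"
  g
}

#' @export
print.triple_graph <- function(x, ...) {
  cat(sprintf("<triple_graph [%s]: %d triples>\n", x$layer, nrow(x$triples)))
  invisible(x)
}

#' Number of triples in a graph
#' @param g A `triple_graph`.
#' @return Integer count.
#' @export
n_triples <- function(g) nrow(g$triples)

#' Add triples to a graph
#'
#' Duplicate triples are silently collapsed (set semantics). Vectorised over
#' the three positions.
#'
#' @param g A `triple_graph` (modified in place and returned invisibly).
#' @param subject,predicate IRI strings.
#' @param object IRI strings or literal values.
#' @param literal Logical; whether `object` is a literal (recycled).
#' @export
add_triple <- function(g, subject, predicate, object, literal = FALSE) {
  stopifnot(inherits(g, "triple_graph"))
  new <- data.frame(
    subject = as.character(subject), predicate = as.character(predicate),
    object = as.character(object),
    is_literal = rep_len(as.logical(literal), length(object)),
    stringsAsFactors = FALSE
  )
  all <- rbind(g$triples, new)
  g$triples <- all[!duplicated(all[c("subject", "predicate", "object")]), ,
                   drop = FALSE]
  rownames(g$triples) <- NULL
  invisible(g)
}

#' Match triples against a pattern
#'
#' Any position left `NULL` is a wildcard. Results are returned in a
#' deterministic order: lexicographic by subject, then predicate, then object.
#'
#' @param g A `triple_graph`.
#' @param subject,predicate,object Bound values or `NULL` for a wildcard.
#' @return A data frame of matching triples (possibly zero rows).
#' @export
match_triples <- function(g, subject = NULL, predicate = NULL, object = NULL) {
  tr <- g$triples
  keep <- rep(TRUE, nrow(tr))
  if (!is.null(subject))   keep <- keep & tr$subject %in% subject
  if (!is.null(predicate)) keep <- keep & tr$predicate %in% predicate
  if (!is.null(object))    keep <- keep & tr$object %in% object
  out <- tr[keep, , drop = FALSE]
  out <- out[order(out$subject, out$predicate, out$object, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# objects of (subject, predicate), sorted
objects_of <- function(g, subject, predicate) {
  match_triples(g, subject = subject, predicate = predicate)$object
}

# subjects with (predicate, object), sorted unique
subjects_with <- function(g, predicate, object = NULL) {
  unique(match_triples(g, predicate = predicate, object = object)$subject)
}

#' Classes of a resource, including inherited superclasses
#'
#' Looks up the resource's asserted `rdf:type` triples and closes them over
#' the vocabulary hierarchy, so a resource typed `wp:Conversion` also reports
#' `wp:DirectedInteraction` and `wp:Interaction`, and a `wp:Protein` also
#' reports `wp:GeneProduct` and `wp:Datanode`.
#'
#' @param g A `triple_graph`.
#' @param resource IRI of the resource.
#' @return Character vector of class CURIEs (sorted, unique); empty if the
#'   resource is unknown.
#' @export
types_of <- function(g, resource) {
  asserted <- objects_of(g, resource, WP_PREDICATES[["type"]])
  if (length(asserted) == 0) return(character(0))
  sort(unique(unlist(lapply(asserted, class_closure))))
}

# resources in g whose closed type set contains class_iri
resources_of_class <- function(g, class_iri) {
  typed <- match_triples(g, predicate = WP_PREDICATES[["type"]])
  if (nrow(typed) == 0) return(character(0))
  keep <- vapply(typed$object, function(cl) is_subclass_of(cl, class_iri),
                 logical(1))
  sort(unique(typed$subject[keep]))
}

## ---- Turtle serialization -------------------------------------------------

# expand a compact CURIE to a full IRI using the namespace table;
# anything without a known prefix is resolved against the base namespace
expand_iri <- function(x, ns = vocab_namespaces()) {
  if (grepl("^https?://", x)) return(x)
  m <- regmatches(x, regexec("^([A-Za-z][A-Za-z0-9._-]*):(.*)$", x))[[1]]
  if (length(m) == 3 && m[2] %in% names(ns)) {
    return(paste0(ns[[m[2]]], m[3]))
  }
  paste0(ns[["base"]], x)
}

compact_iri <- function(x, ns = vocab_namespaces()) {
  for (p in names(ns)) {
    if (startsWith(x, ns[[p]])) {
      local <- substring(x, nchar(ns[[p]]) + 1L)
      if (p == "base") return(local)
      return(paste0(p, ":", local))
    }
  }
  x
}

ttl_escape <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  x <- gsub("\"", "\\\\\"", x)
  x <- gsub("\n", "\\\\n", x)
  x
}

#' Write a graph layer to Turtle
#'
#' @param g A `triple_graph`.
#' @param path Output file path (`.ttl`).
#' @return `path`, invisibly.
#' @export
write_turtle <- function(g, path) {
  ns <- vocab_namespaces()
  lines <- c(
    sprintf("@prefix %s: <%s> .", setdiff(names(ns), "base"),
            ns[setdiff(names(ns), "base")]),
    sprintf("@base <%s> .", ns[["base"]]),
    ""
  )
  tr <- match_triples(g)
  if (nrow(tr) > 0) {
    term <- function(iri) {
      if (grepl("^[A-Za-z][A-Za-z0-9._-]*:[^/]", iri) &&
          sub(":.*$", "", iri) %in% names(ns)) {
        iri
      } else {
        paste0("<", expand_iri(iri, ns), ">")
      }
    }
    lines <- c(lines, vapply(seq_len(nrow(tr)), function(i) {
      obj <- if (tr$is_literal[i]) {
        paste0("\"", ttl_escape(tr$object[i]), "\"")
      } else {
        term(tr$object[i])
      }
      paste(term(tr$subject[i]), term(tr$predicate[i]), obj, ".")
    }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Turtle file into a graph layer
#'
#' Supports the subset of Turtle the package writes plus the common
#' constructs of externally produced dumps: `@prefix`/`@base` directives,
#' `<>`-quoted IRIs, prefixed names, quoted literals (language tags and
#' datatypes are dropped, labels kept as plain text), `a` for `rdf:type`,
#' and `;`/`,` continuation lists. Blank nodes and multi-line literals are
#' not supported.
#'
#' @param path Path to a `.ttl` file.
#' @param layer Which layer the loaded graph represents.
#' @return A `triple_graph`.
#' @export
read_turtle <- function(path, layer = c("wp_layer", "gpml_layer")) {
  layer <- match.arg(layer)
  g <- triple_graph(layer)
  ns <- vocab_namespaces()
  prefixes <- ns[setdiff(names(ns), "base")]
  base <- ns[["base"]]
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")

  toks <- ttl_tokenize(text)
  i <- 1L
  subj <- NULL; pred <- NULL
  resolve <- function(tok) {
    if (startsWith(tok, "<")) {
      iri <- substr(tok, 2, nchar(tok) - 1L)
      return(compact_iri(iri, c(prefixes, base = base)))
    }
    if (tok == "a") return("rdf:type")
    tok
  }
  while (i <= length(toks)) {
    tok <- toks[i]
    if (tok %in% c("@prefix", "PREFIX")) {
      p <- sub(":$", "", toks[i + 1L])
      prefixes[p] <- substr(toks[i + 2L], 2, nchar(toks[i + 2L]) - 1L)
      i <- i + if (toks[i + 3L] == ".") 4L else 3L
      next
    }
    if (tok %in% c("@base", "BASE")) {
      base <- substr(toks[i + 1L], 2, nchar(toks[i + 1L]) - 1L)
      i <- i + if (length(toks) >= i + 2L && toks[i + 2L] == ".") 3L else 2L
      next
    }
    if (tok == ".") { subj <- NULL; pred <- NULL; i <- i + 1L; next }
    if (tok == ";") { pred <- NULL; i <- i + 1L; next }
    if (tok == ",") { i <- i + 1L; next }
    if (is.null(subj)) { subj <- resolve(tok); i <- i + 1L; next }
    if (is.null(pred)) { pred <- resolve(tok); i <- i + 1L; next }
    if (startsWith(tok, "\"")) {
      val <- gsub("\\\\n", "\n",
             gsub("\\\\\"", "\"",
             gsub("\\\\\\\\", "\\\\", substr(tok, 2, nchar(tok) - 1L))))
      add_triple(g, subj, pred, val, literal = TRUE)
    } else {
      add_triple(g, subj, pred, resolve(tok))
    }
    i <- i + 1L
  }
  g
}

# split turtle text into tokens: IRIs, literals (with trailing @lang/^^type
# stripped), prefixed names, punctuation
ttl_tokenize <- function(text) {
  toks <- character(0)
  n <- nchar(text)
  i <- 1L
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch %in% c(" ", "\t", "\n", "\r")) { i <- i + 1L; next }
    if (ch == "#") {                       # comment to end of line
      j <- regexpr("\n", substr(text, i, n))
      if (j < 0) break
      i <- i + j
      next
    }
    if (ch == "<") {
      j <- regexpr(">", substr(text, i, n))
      toks <- c(toks, substr(text, i, i + j - 1L))
      i <- i + j
      next
    }
    if (ch == "\"") {
      j <- i + 1L
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\") { j <- j + 2L; next }
        if (cj == "\"") break
        j <- j + 1L
      }
      toks <- c(toks, substr(text, i, j))
      i <- j + 1L
      # drop language tag / datatype suffix
      rest <- substr(text, i, n)
      m <- regexpr("^(@[A-Za-z-]+|\\^\\^[^ \t\n\r;,.]+)", rest)
      if (m == 1L) i <- i + attr(m, "match.length")
      next
    }
    if (ch %in% c(".", ";", ",")) {
      # '.' only terminates if followed by whitespace/EOF (not inside a name)
      toks <- c(toks, ch)
      i <- i + 1L
      next
    }
    m <- regexpr("^[^ \t\n\r;,]+", substr(text, i, n))
    tok <- substr(text, i, i + attr(m, "match.length") - 1L)
    # a statement-final '.' can be glued to the token
    if (nchar(tok) > 1L && endsWith(tok, ".") && !grepl("\\d\\.$", tok)) {
      tok <- substr(tok, 1, nchar(tok) - 1L)
      toks <- c(toks, tok, ".")
      i <- i + attr(m, "match.length")
      next
    }
    toks <- c(toks, tok)
    i <- i + attr(m, "match.length")
  }
  toks
}
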