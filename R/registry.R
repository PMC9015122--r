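#' Datasource registry and arrowhead mapping
#'
#' Two small configuration tables drive the harmonization and ship as
#' editable CSV files under `inst/extdata/`, so the canonical upstream
#' mappings can be dropped in without code changes:
#'
#' * the *datasource registry* maps the database names drawn in GPML `Xref`
#'   elements to identifiers.org-style CURIE prefixes (`Ensembl` ->
#'   `ensembl:`, `HMDB` -> `hmdb:`, ...);
#' * the *arrowhead map* maps arrowhead tokens from the three drawing
#'   notations (plain WikiPathways, MIM, SBGN) to the nine harmonized
#'   interaction classes, and records whether a token usually marks a
#'   reaction spine or a regulator leg.
#'
#' @param path Path to a CSV file; defaults to the bundled table.
#' @return A data frame (`datasource`/`prefix` columns, or
#'   `token`/`notation`/`class`/`role` columns).
#' @name registry
NULL

#' @rdname registry
#' @export
default_datasource_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "datasources.csv", package = "pathsem")
  }
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("datasource", "prefix") %in% names(reg)))
  reg
}

#' @rdname registry
#' @export
default_arrowhead_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "arrowheads.csv", package = "pathsem")
  }
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("token", "notation", "class", "role") %in% names(map)))
  bad <- setdiff(map$class, WP_INTERACTION_CLASSES)
  if (length(bad) > 0) {
    stop("arrowhead map names unknown interaction class(es): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  map
}

# mint an identifiers.org-style CURIE for a resolved xref;
# ChEBI accessions keep their CHEBI: namespace inside the local part
mint_identifier_iri <- function(prefix, id) {
  if (prefix == "chebi" && !startsWith(id, "CHEBI:")) {
    id <- paste0("CHEBI:", id)
  }
  paste0(prefix, ":", id)
}

# lookup: datasource name -> prefix, or NA if unknown
registry_prefix <- function(registry, datasource) {
  i <- match(datasource, registry$datasource)
  if (is.na(i)) NA_character_ else registry$prefix[i]
}

# lookup: arrowhead token -> list(class, role), or NULL if unmapped
arrowhead_class <- function(map, token) {
  i <- match(token, map$token)    # exact, case-sensitive
  if (is.na(i)) return(NULL)
  list(class = map$class[i], role = map$role[i])
}
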