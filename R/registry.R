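## The controlled relation vocabulary. Each predicate declares whether
## its object is a concept id or a controlled literal, and (for the
## shared-feature layer) which similarity level it contributes to.

FEATURE_LEVELS <- c("pharmacological", "biomolecular", "physiological",
                    "genetic", "substructure", "contraindication")

#' The default predicate registry
#'
#' Returns the registered relation vocabulary as a data frame with one
#' row per predicate and columns:
#' \describe{
#'   \item{predicate}{relation name (lower case).}
#'   \item{objectKind}{`"concept"` if the object must be a concept id,
#'     `"literal"` for controlled literal objects.}
#'   \item{featureLevel}{the similarity level the predicate feeds
#'     (`NA` for predicates outside the shared-feature layer). Levels
#'     are the four ontology core levels plus `substructure` and
#'     `contraindication`.}
#' }
#'
#' The registry drives three things: literal-vs-entity storage when
#' triples are added, the virtual ternary `feature(drug, level,
#' value)` facts consumed by the shared-feature rule, and the
#' unknown-predicate check during validation.
#'
#' @return data.frame as described.
#' @examples
#' defaultPredicateRegistry()
#' @export
defaultPredicateRegistry <- function() {
  data.frame(
    predicate = c("inhibits", "induces", "substrate_of", "has_role",
                  "has_moa", "gene_association", "involved_in",
                  "snp_association", "has_effect",
                  "has_substructure_class", "contraindicated_if",
                  "related_to", "parent_of", "child_of", "broader",
                  "narrower"),
    objectKind = c("concept", "concept", "concept", "literal",
                   "concept", "concept", "concept",
                   "concept", "concept",
                   "literal", "concept",
                   "concept", "concept", "concept", "concept",
                   "concept"),
    featureLevel = c(NA, NA, NA, NA,
                     "pharmacological", "biomolecular", "biomolecular",
                     "genetic", "physiological",
                     "substructure", "contraindication",
                     NA, NA, NA, NA,
                     NA),
    stringsAsFactors = FALSE)
}

registryLookup <- function(registry, predicate) {
  i <- match(predicate, registry$predicate)
  if (is.na(i)) NULL else registry[i, , drop = FALSE]
}

## Is the object of this predicate a literal? Unregistered predicates
## fall back on the token shape: anything that is not a well-formed
## concept id is stored as a literal.
objectIsLiteral <- function(registry, predicate, object) {
  row <- registryLookup(registry, predicate)
  if (!is.null(row)) row$objectKind == "literal" else !isConceptId(object)
}

featureLevelOf <- function(registry, predicate) {
  row <- registryLookup(registry, predicate)
  if (is.null(row)) NA_character_ else row$featureLevel
}

## Predicates contributing to a given similarity level.
predicatesForLevel <- function(registry, level) {
  registry$predicate[!is.na(registry$featureLevel) &
                       registry$featureLevel == level]
}
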