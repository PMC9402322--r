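## Triple-store data model: construction, entity records, pattern
## matching. All user-visible orderings are lexicographic (C
## collation) so serialized output is deterministic.

newEntityRecord <- function(labels = character()) {
  list(labels = labels, semtypes = character(),
       coreClass = NA_character_, subclass = NA_character_,
       subclassCandidates = character())
}

#' Create an empty knowledge graph
#'
#' @return a [KnowledgeGraph-class] with no triples and no entities.
#' @examples
#' g <- emptyGraph()
#' nTriples(g)
#' @export
emptyGraph <- function() new("KnowledgeGraph")

#' Declare an entity (with optional labels) without adding a triple
#'
#' Entities are normally auto-created by [addTriple()]; this is used
#' by the ETL for concepts that carry labels or semantic types before
#' (or without) participating in any triple.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param id concept id.
#' @param labels character vector of labels to attach.
#' @param semtypes character vector of semantic-type codes to attach
#'   (normalized to upper case).
#' @return the updated graph.
#' @export
declareEntity <- function(graph, id, labels = character(),
                          semtypes = character()) {
  assertConceptId(id)
  e <- graph@entities[[id]] %||% newEntityRecord()
  e$labels <- lexSort(unique(c(e$labels, labels)))
  e$semtypes <- lexSort(unique(c(e$semtypes, toupper(semtypes))))
  graph@entities[[id]] <- e
  graph
}

ensureEntities <- function(graph, ids) {
  for (id in setdiff(unique(ids), names(graph@entities)))
    graph@entities[[id]] <- newEntityRecord()
  graph
}

#' Add one triple to a knowledge graph
#'
#' Triples have set semantics: re-adding an existing triple leaves the
#' graph unchanged. Entity records are auto-created for new concept
#' ids. Whether the object is stored as a literal is decided by the
#' predicate registry (registered literal-object predicates), falling
#' back on the token shape for unregistered predicates.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param subject,predicate,object the triple; subject must be a
#'   well-formed concept id, and so must object unless it is a
#'   literal.
#' @param provenance source tag; one of `MRCONSO`, `MRREL`, `MRSAT`,
#'   `DRUGLINK`, `GENELINK`, `FIXTURE`, `INFERRED`.
#' @param literal logical or `NA`; `NA` (default) consults the
#'   registry.
#' @param registry predicate registry, see
#'   [defaultPredicateRegistry()].
#' @return the updated graph.
#' @examples
#' g <- addTriple(emptyGraph(), "C0000002", "inhibits", "C0000003")
#' nTriples(g); nEntities(g)
#' @export
addTriple <- function(graph, subject, predicate, object,
                      provenance = "FIXTURE", literal = NA,
                      registry = defaultPredicateRegistry()) {
  addTriples(graph,
             data.frame(subject = subject, predicate = predicate,
                        object = object, literal = literal,
                        provenance = provenance,
                        stringsAsFactors = FALSE),
             registry = registry)
}

#' Add a batch of triples (vectorized [addTriple()])
#'
#' @param graph a [KnowledgeGraph-class].
#' @param df data.frame with columns `subject`, `predicate`, `object`
#'   and optionally `literal` and `provenance`.
#' @param provenance default provenance for rows lacking one.
#' @param registry predicate registry.
#' @return the updated graph.
#' @export
addTriples <- function(graph, df, provenance = "FIXTURE",
                       registry = defaultPredicateRegistry()) {
  stopifnot(is(graph, "KnowledgeGraph"))
  if (nrow(df) == 0L) return(graph)
  if (is.null(df$provenance)) df$provenance <- provenance
  if (is.null(df$literal)) df$literal <- NA
  bad <- c("MRCONSO", "MRREL", "MRSAT", "DRUGLINK", "GENELINK",
           "FIXTURE", "INFERRED")
  if (!all(df$provenance %in% bad))
    stop("unknown provenance tag: ",
         setdiff(unique(df$provenance), bad)[[1L]], call. = FALSE)
  assertConceptId(df$subject, "subject concept id")
  na <- is.na(df$literal)
  if (any(na))
    df$literal[na] <- mapply(function(p, o) objectIsLiteral(registry, p, o),
                             df$predicate[na], df$object[na],
                             USE.NAMES = FALSE)
  df$literal <- as.logical(df$literal)
  assertConceptId(df$object[!df$literal], "object concept id")
  if (any(grepl("|", df$object, fixed = TRUE)))
    stop("pipe character is reserved and may not appear in objects",
         call. = FALSE)
  df <- df[, c("subject", "predicate", "object", "literal", "provenance")]
  all <- rbind(graph@triples, df)
  all <- all[!duplicated(tripleKey(all)), , drop = FALSE]
  rownames(all) <- NULL
  graph@triples <- all
  ensureEntities(graph, c(df$subject, df$object[!df$literal]))
}

#' Build a triple pattern
#'
#' Each position is either a constant or a named variable written with
#' a leading question mark (`"?x"`). A pattern with zero variables is
#' a membership test.
#'
#' @param subject,predicate,object constants or `"?var"` tokens.
#' @return a list of class `"TriplePattern"`.
#' @examples
#' triplePattern("?x", "inhibits", "C0000003")
#' @export
triplePattern <- function(subject, predicate, object) {
  structure(list(subject = subject, predicate = predicate,
                 object = object), class = "TriplePattern")
}

#' Match a triple pattern against a graph
#'
#' Returns every variable binding under which the pattern
#' instantiates to a triple of the graph. Bindings are returned as a
#' data frame with one column per distinct variable (named without
#' the `?`), sorted lexicographically over all columns. A variable
#' repeated across positions must bind to the same value. For a
#' fully-constant pattern the result has zero columns and one row if
#' the triple is present, else zero rows.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param pattern a [triplePattern()].
#' @return data.frame of bindings, deterministically ordered.
#' @examples
#' g <- addTriple(emptyGraph(), "C0000002", "inhibits", "C0000003")
#' matchTriples(g, triplePattern("?x", "inhibits", "C0000003"))
#' @export
matchTriples <- function(graph, pattern) {
  stopifnot(inherits(pattern, "TriplePattern"))
  tr <- graph@triples
  slots <- c(subject = pattern$subject, predicate = pattern$predicate,
             object = pattern$object)
  keep <- rep(TRUE, nrow(tr))
  for (pos in names(slots)) {
    if (!isVar(slots[[pos]])) keep <- keep & tr[[pos]] == slots[[pos]]
  }
  tr <- tr[keep, , drop = FALSE]
  vars <- slots[vapply(slots, isVar, TRUE)]
  if (length(vars) == 0L) {
    out <- data.frame(row.names = seq_len(min(nrow(tr), 1L)))
    return(out)
  }
  cols <- list()
  for (v in unique(unname(vars))) {
    positions <- names(vars)[vars == v]
    vals <- tr[[positions[[1L]]]]
    for (p in positions[-1L]) {   # repeated variable: positions must agree
      ok <- vals == tr[[p]]
      tr <- tr[ok, , drop = FALSE]
      vals <- vals[ok]
      for (u in names(cols)) cols[[u]] <- cols[[u]][ok]
    }
    cols[[sub("^\\?", "", v)]] <- vals
  }
  out <- unique(as.data.frame(cols, stringsAsFactors = FALSE,
                              check.names = FALSE))
  if (nrow(out) > 1L) out <- out[do.call(lexOrder, out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Internal: does the graph contain this exact (s, p, o) fact,
## irrespective of provenance?
hasFact <- function(graph, s, p, o) {
  tr <- graph@triples
  any(tr$subject == s & tr$predicate == p & tr$object == o)
}
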