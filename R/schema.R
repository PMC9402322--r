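## The four-class / seven-subclass ontology, semantic-type driven
## classification of instances, and the structural consistency check.

#' The default DDI ontology schema
#'
#' Four core classes (pharmacological, biomolecular, physiological,
#' genetic) and seven subclasses: drugs under pharmacological; genes,
#' enzymes and biological processes under biomolecular; effect and
#' mechanism of action under physiological; SNPs under genetic.
#' Transporters are proteins and live in the `enzymes` subclass,
#' distinguished functionally by a `has_role` annotation
#' (`metabolizing_enzyme` / `transporter`) rather than by an eighth
#' subclass.
#'
#' The semantic-type map assigns instances to subclasses from their
#' UMLS-style type codes. Only T028 (Gene or Genome -> genes) is
#' fixed by the domain convention; the remaining defaults are a
#' deliberately minimal, fully overridable choice: T109/T121/T200 ->
#' drugs, T116/T126 -> enzymes, T038/T042/T043/T044 ->
#' biological_processes, T033/T046/T047/T184 -> effect, T120 ->
#' mechanism_of_action, T086 -> snps.
#'
#' @param semtypeMap optional named character vector overriding or
#'   extending the default semantic-type map (names = type codes,
#'   values = subclasses).
#' @return a [Schema-class].
#' @examples
#' s <- defaultSchema()
#' s@semtypeMap[["T028"]]
#' @export
defaultSchema <- function(semtypeMap = NULL) {
  core <- c("pharmacological", "biomolecular", "physiological", "genetic")
  subs <- c(drugs = "pharmacological",
            genes = "biomolecular",
            enzymes = "biomolecular",
            biological_processes = "biomolecular",
            effect = "physiological",
            mechanism_of_action = "physiological",
            snps = "genetic")
  stm <- c(T109 = "drugs", T121 = "drugs", T200 = "drugs",
           T028 = "genes",
           T116 = "enzymes", T126 = "enzymes",
           T038 = "biological_processes", T042 = "biological_processes",
           T043 = "biological_processes", T044 = "biological_processes",
           T033 = "effect", T046 = "effect", T047 = "effect",
           T184 = "effect",
           T120 = "mechanism_of_action",
           T086 = "snps")
  if (!is.null(semtypeMap)) stm[names(semtypeMap)] <- semtypeMap
  rc <- list(
    inhibits = list(subject = "drugs", object = "enzymes"),
    induces = list(subject = "drugs", object = "enzymes"),
    substrate_of = list(subject = "drugs", object = "enzymes"),
    has_role = list(subject = "enzymes", object = "literal",
                    values = c("metabolizing_enzyme", "transporter")),
    has_moa = list(subject = "drugs", object = "mechanism_of_action"),
    gene_association = list(subject = "drugs", object = "genes"),
    involved_in = list(subject = c("drugs", "genes", "enzymes"),
                       object = "biological_processes"),
    snp_association = list(subject = "drugs", object = "snps"),
    has_effect = list(subject = "drugs", object = "effect"),
    has_substructure_class = list(subject = "drugs", object = "literal"),
    contraindicated_if = list(subject = "drugs", object = "effect"),
    related_to = NULL, parent_of = NULL, child_of = NULL,
    broader = NULL, narrower = NULL)
  new("Schema", coreClasses = core, subclasses = subs,
      semtypeMap = stm, relationConstraints = rc)
}

#' Build a schema from a config list (YAML block)
#'
#' Accepts the structure written by [schemaToList()]: overrides for
#' `semtype_map` are applied on top of the default schema. Core
#' classes and subclasses are fixed by the ontology and cannot be
#' altered here.
#'
#' @param config list, typically `yaml::read_yaml(...)$schema`, with
#'   an optional `semtype_map` element.
#' @return a [Schema-class].
#' @export
schemaFromConfig <- function(config) {
  stm <- NULL
  if (!is.null(config$semtype_map))
    stm <- vapply(config$semtype_map, as.character, "")
  defaultSchema(semtypeMap = stm)
}

#' Render a schema as a config list
#'
#' @param schema a [Schema-class].
#' @return list suitable for `yaml::write_yaml()`.
#' @export
schemaToList <- function(schema) {
  list(core_classes = as.list(schema@coreClasses),
       subclasses = as.list(schema@subclasses),
       semtype_map = as.list(schema@semtypeMap))
}

#' Classify graph entities from their semantic types
#'
#' Each entity's semantic-type codes are mapped through the schema's
#' semantic-type map. Entities whose codes map to exactly one
#' subclass get that subclass and its core class; entities mapping to
#' several subclasses keep all candidates (`subclassCandidates`) and
#' receive the core class only when the candidates agree on one --
#' conflicts across core classes are left for [checkConsistency()].
#' Entities with no mapped type remain unclassified. Idempotent.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param schema a [Schema-class].
#' @return the graph with classification annotations set.
#' @export
classifyGraph <- function(graph, schema) {
  stm <- schema@semtypeMap
  for (id in names(graph@entities)) {
    e <- graph@entities[[id]]
    cand <- lexSort(unique(unname(stm[e$semtypes[e$semtypes %in% names(stm)]])))
    cores <- unique(unname(schema@subclasses[cand]))
    e$subclassCandidates <- if (length(cand) > 1L) cand else character()
    e$subclass <- if (length(cand) == 1L) cand else NA_character_
    e$coreClass <- if (length(cores) == 1L) cores else NA_character_
    graph@entities[[id]] <- e
  }
  graph
}

violationRow <- function(kind, item, detail) {
  data.frame(kind = kind, item = item, detail = detail,
             stringsAsFactors = FALSE)
}

renderTriple <- function(tr)
  sprintf("(%s, %s, %s)", tr$subject, tr$predicate, tr$object)

#' Check ontology consistency of a classified graph
#'
#' Structural checks over classes, subclasses and instances:
#' \itemize{
#'   \item `MULTI_CLASS_CONFLICT` -- an entity whose candidate
#'     subclasses span more than one core class;
#'   \item `UNKNOWN_PREDICATE` -- a triple whose predicate is not in
#'     the registered vocabulary;
#'   \item `DOMAIN_VIOLATION` / `RANGE_VIOLATION` -- a triple whose
#'     classified endpoints (or literal/controlled-value contract)
#'     violate the predicate's constraints; endpoints that are still
#'     unclassified are not judged;
#'   \item `UNCLASSIFIED` -- entities with no mapped semantic type;
#'     warn-level by default (real terminology loads always contain
#'     unmapped types), escalated to a violation when
#'     `strictUnclassified = TRUE`.
#' }
#'
#' @param graph a classified [KnowledgeGraph-class] (see
#'   [classifyGraph()]).
#' @param schema a [Schema-class].
#' @param strictUnclassified logical; treat unclassified entities as
#'   violations.
#' @param checkDomainRange logical; disable to check class membership
#'   only.
#' @param registry predicate registry.
#' @return a [ConsistencyReport-class].
#' @export
checkConsistency <- function(graph, schema, strictUnclassified = FALSE,
                             checkDomainRange = TRUE,
                             registry = defaultPredicateRegistry()) {
  vio <- list()
  warn <- list()
  for (id in lexSort(names(graph@entities))) {
    e <- graph@entities[[id]]
    cand <- e$subclassCandidates
    cores <- unique(unname(schema@subclasses[cand]))
    if (length(cores) > 1L) {
      vio[[length(vio) + 1L]] <- violationRow(
        "MULTI_CLASS_CONFLICT", id,
        sprintf("subclass candidates {%s} span core classes {%s}",
                paste(cand, collapse = ", "),
                paste(lexSort(cores), collapse = ", ")))
    } else if (is.na(e$subclass) && length(cand) == 0L) {
      row <- violationRow("UNCLASSIFIED", id,
                          "no semantic type maps to a subclass")
      if (strictUnclassified) vio[[length(vio) + 1L]] <- row
      else warn[[length(warn) + 1L]] <- row
    }
  }
  tr <- graph@triples
  subclassOf <- function(eid) {
    e <- graph@entities[[eid]]
    if (!is.na(e$subclass)) e$subclass else e$subclassCandidates
  }
  for (i in seq_len(nrow(tr))) {
    p <- tr$predicate[[i]]
    if (is.null(registryLookup(registry, p))) {
      if (tr$provenance[[i]] != "INFERRED")
        vio[[length(vio) + 1L]] <- violationRow(
          "UNKNOWN_PREDICATE", renderTriple(tr[i, ]),
          sprintf("predicate '%s' is not in the registered vocabulary", p))
      next
    }
    if (!checkDomainRange) next
    rc <- schema@relationConstraints[[p]]
    if (is.null(rc)) next
    subcls <- subclassOf(tr$subject[[i]])
    if (length(subcls) > 0L && !any(subcls %in% rc$subject)) {
      vio[[length(vio) + 1L]] <- violationRow(
        "DOMAIN_VIOLATION", renderTriple(tr[i, ]),
        sprintf("subject subclass {%s} not in allowed {%s}",
                paste(subcls, collapse = ", "),
                paste(rc$subject, collapse = ", ")))
      next
    }
    if (identical(rc$object, "literal")) {
      if (!tr$literal[[i]]) {
        vio[[length(vio) + 1L]] <- violationRow(
          "RANGE_VIOLATION", renderTriple(tr[i, ]),
          sprintf("predicate '%s' requires a literal object", p))
      } else if (!is.null(rc$values) && !tr$object[[i]] %in% rc$values) {
        vio[[length(vio) + 1L]] <- violationRow(
          "RANGE_VIOLATION", renderTriple(tr[i, ]),
          sprintf("literal '%s' not in controlled set {%s}",
                  tr$object[[i]], paste(rc$values, collapse = ", ")))
      }
    } else if (!tr$literal[[i]]) {
      objcls <- subclassOf(tr$object[[i]])
      if (length(objcls) > 0L && !any(objcls %in% rc$object)) {
        vio[[length(vio) + 1L]] <- violationRow(
          "RANGE_VIOLATION", renderTriple(tr[i, ]),
          sprintf("object subclass {%s} not in allowed {%s}",
                  paste(objcls, collapse = ", "),
                  paste(rc$object, collapse = ", ")))
      }
    } else {
      vio[[length(vio) + 1L]] <- violationRow(
        "RANGE_VIOLATION", renderTriple(tr[i, ]),
        sprintf("predicate '%s' requires a concept object", p))
    }
  }
  bind <- function(rows) {
    if (length(rows) == 0L)
      return(data.frame(kind = character(), item = character(),
                        detail = character(), stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  v <- bind(vio)
  new("ConsistencyReport", violations = v, warnings = bind(warn),
      isConsistent = nrow(v) == 0L)
}

#' Render a consistency report as JSON
#'
#' @param report a [ConsistencyReport-class].
#' @return character scalar of stable JSON.
#' @export
consistencyReportJSON <- function(report) {
  asRows <- function(df) lapply(seq_len(nrow(df)), function(i)
    list(kind = df$kind[[i]], item = df$item[[i]], detail = df$detail[[i]]))
  as.character(stableJSON(list(
    is_consistent = report@isConsistent,
    violations = asRows(report@violations),
    warnings = asRows(report@warnings))))
}
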