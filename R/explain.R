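## Explanation artifacts: the per-drug mechanistic feature profile and
## the summary interaction report (one row per pharmacological-effect
## target kind, one row per biomedical-feature level, "NA" where a
## row has no matches).

## Core-class bucket for a profile fact: the counterpart entity's
## core class when classified, else the predicate's feature level
## folded onto a core class (substructure is a chemical/drug-side
## property -> pharmacological; contraindications describe clinical
## conditions -> physiological), else "unclassified".
LEVEL_TO_CORE <- c(pharmacological = "pharmacological",
                   biomolecular = "biomolecular",
                   physiological = "physiological",
                   genetic = "genetic",
                   substructure = "pharmacological",
                   contraindication = "physiological")

#' Mechanistic feature profile of one drug
#'
#' Every registered-predicate fact in which the drug participates
#' (either as subject or as object), deduplicated and grouped two
#' ways: by source (provenance tag) and by ontology core class. The
#' two groupings cover the same fact multiset; facts whose class
#' cannot be determined fall into the `"unclassified"` bucket.
#' Ordering is deterministic.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param drug drug concept id (must exist).
#' @param registry predicate registry.
#' @return a [FeatureProfile-class].
#' @export
featureProfile <- function(graph, drug,
                           registry = defaultPredicateRegistry()) {
  assertDrugKnown(graph, drug)
  tr <- graph@triples
  reg <- tr$predicate %in% registry$predicate
  asSubj <- reg & tr$subject == drug
  asObj <- reg & !tr$literal & tr$object == drug
  rows <- rbind(
    data.frame(predicate = tr$predicate[asSubj], value = tr$object[asSubj],
               direction = rep("out", sum(asSubj)),
               provenance = tr$provenance[asSubj],
               counterpart = ifelse(tr$literal[asSubj], NA_character_,
                                    tr$object[asSubj]),
               stringsAsFactors = FALSE),
    data.frame(predicate = tr$predicate[asObj], value = tr$subject[asObj],
               direction = rep("in", sum(asObj)),
               provenance = tr$provenance[asObj],
               counterpart = tr$subject[asObj], stringsAsFactors = FALSE))
  rows <- unique(rows)
  rows <- rows[lexOrder(rows$predicate, rows$value, rows$direction,
                        rows$provenance), , drop = FALSE]
  bucket <- function(i) {
    cp <- rows$counterpart[[i]]
    if (!is.na(cp)) {
      cc <- graph@entities[[cp]]$coreClass
      if (!is.na(cc)) return(cc)
    }
    lv <- featureLevelOf(registry, rows$predicate[[i]])
    if (!is.na(lv)) return(unname(LEVEL_TO_CORE[[lv]]))
    "unclassified"
  }
  fact <- rows[, c("predicate", "value", "direction"), drop = FALSE]
  bySource <- split(fact, rows$provenance)
  byClass <- split(fact, vapply(seq_len(nrow(rows)), bucket, ""))
  tidy <- function(l) {
    l <- l[lexSort(names(l))]
    lapply(l, function(df) { rownames(df) <- NULL; df })
  }
  new("FeatureProfile", drug = drug, perSource = tidy(bySource),
      perClass = tidy(byClass))
}

labelOf <- function(graph, id) {
  e <- graph@entities[[id]]
  if (!is.null(e) && length(e$labels) > 0L) e$labels[[1L]] else id
}

assessmentToList <- function(assessment) {
  a <- assessment
  mechRow <- function(m) list(
    target = m@target, target_kind = m@targetKind,
    perpetrator = m@perpetrator, perpetrator_role = m@perpetratorRole,
    victim = m@victim, rule = m@ruleId)
  featRows <- function(level) {
    vals <- vapply(Filter(function(m) m@level == level, a@featureMatches),
                   function(m) m@value, "")
    if (length(vals) == 0L) "NA" else as.list(lexSort(vals))
  }
  kinds <- vapply(a@mechanismMatches, function(m) m@targetKind, "")
  list(
    drug_a = a@drugA, drug_b = a@drugB, verdict = a@verdict,
    threshold = a@threshold,
    pharmacological_effects = list(
      metabolizing_enzymes =
        lapply(a@mechanismMatches[kinds == "metabolizing_enzyme"], mechRow),
      transporters =
        lapply(a@mechanismMatches[kinds == "transporter"], mechRow)),
    biomedical_features = list(
      pharmacological = featRows("pharmacological"),
      biomolecular = featRows("biomolecular"),
      physiological = featRows("physiological"),
      genetic = featRows("genetic"),
      substructure = featRows("substructure"),
      contraindication = featRows("contraindication")),
    shared_level_count = a@sharedLevelCount,
    mechanism_match_count = length(a@mechanismMatches),
    rationale = as.list(a@rationale),
    proofs = a@proof)
}

#' Render a DDI assessment report
#'
#' `json` emits a machine-readable report mirroring the summary-table
#' layout (a pharmacological-effects block with metabolizing-enzyme
#' and transporter rows; a biomedical-features block with one row per
#' similarity level, `"NA"` where a row has no matches) plus the
#' verdict, rationale and proof appendix; it validates against the
#' schema shipped at `inst/schema/ddi_report.schema.json` (see
#' [validateReportJSON()]). `markdown` renders the same content as a
#' human-readable table. Reports are pure functions of the
#' assessment: byte-identical across runs.
#'
#' @param assessment a [DDIAssessment-class].
#' @param format `"json"` or `"markdown"`.
#' @param graph optional [KnowledgeGraph-class]; when given, markdown
#'   uses entity labels instead of raw concept ids.
#' @return character scalar (the rendered report).
#' @export
renderReport <- function(assessment, format = c("json", "markdown"),
                         graph = NULL) {
  format <- match.arg(format)
  x <- assessmentToList(assessment)
  if (format == "json") return(as.character(stableJSON(x)))
  nm <- function(id) if (is.null(graph)) id else labelOf(graph, id)
  a <- assessment
  da <- nm(a@drugA); db <- nm(a@drugB)
  lines <- c(
    sprintf("# Potential mechanism of interaction: %s + %s", da, db),
    "",
    sprintf("**Verdict: %s** (mechanism matches: %d; shared feature levels: %d; threshold: %g)",
            a@verdict, length(a@mechanismMatches), a@sharedLevelCount,
            a@threshold),
    "",
    sprintf("| | %s | %s |", da, db),
    "|---|---|---|")
  cell <- function(kind, drug) {
    ms <- Filter(function(m) m@targetKind == kind, a@mechanismMatches)
    parts <- character()
    for (m in ms) {
      if (m@perpetrator == drug)
        parts <- c(parts, sprintf("%s %s", nm(m@target), m@perpetratorRole))
      if (m@victim == drug)
        parts <- c(parts, sprintf("%s substrate", nm(m@target)))
    }
    if (length(parts) == 0L) "NA" else paste(lexSort(unique(parts)),
                                             collapse = "; ")
  }
  lines <- c(lines,
    "| *Pharmacological effects* | | |",
    sprintf("| Metabolizing enzymes | %s | %s |",
            cell("metabolizing_enzyme", a@drugA),
            cell("metabolizing_enzyme", a@drugB)),
    sprintf("| Transporters | %s | %s |",
            cell("transporter", a@drugA), cell("transporter", a@drugB)),
    "| *Biomedical features* | | |")
  featCell <- function(level) {
    vals <- vapply(Filter(function(m) m@level == level, a@featureMatches),
                   function(m) if (grepl("^C[0-9]{7}$", m@value))
                     nm(m@value) else m@value, "")
    if (length(vals) == 0L) "NA" else paste(lexSort(vals), collapse = "; ")
  }
  rows <- c(pharmacological = "Pharmacological (MoA)",
            biomolecular = "Biomolecular", physiological = "Physiological",
            genetic = "Genetic", substructure = "Substructure",
            contraindication = "Contraindication")
  for (lv in names(rows)) {
    v <- featCell(lv)
    lines <- c(lines, sprintf("| %s | %s | %s |", rows[[lv]], v, v))
  }
  lines <- c(lines, "", "## Rationale", "",
             paste0("- ", a@rationale))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Structurally validate a JSON report
#'
#' Checks a parsed or serialized report against the shipped report
#' schema's structural requirements (required keys, types, verdict
#' and row-shape constraints).
#'
#' @param json report text (or an already-parsed list).
#' @return `TRUE` invisibly; otherwise an error describing the first
#'   violation.
#' @export
validateReportJSON <- function(json) {
  x <- if (is.character(json)) jsonlite::fromJSON(json,
                                                  simplifyVector = FALSE)
       else json
  need <- c("drug_a", "drug_b", "verdict", "threshold",
            "pharmacological_effects", "biomedical_features",
            "shared_level_count", "mechanism_match_count", "rationale",
            "proofs")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L)
    stop("report missing required key: ", miss[[1L]], call. = FALSE)
  if (!x$verdict %in% c("POTENTIAL_DDI", "NO_EVIDENCE"))
    stop("invalid verdict: ", x$verdict, call. = FALSE)
  if (!all(c("metabolizing_enzymes", "transporters") %in%
             names(x$pharmacological_effects)))
    stop("pharmacological_effects must have metabolizing_enzymes and transporters rows",
         call. = FALSE)
  lv <- c("pharmacological", "biomolecular", "physiological", "genetic",
          "substructure", "contraindication")
  if (!all(lv %in% names(x$biomedical_features)))
    stop("biomedical_features must have one row per similarity level",
         call. = FALSE)
  for (l in lv) {
    row <- x$biomedical_features[[l]]
    if (!(identical(row, "NA") || is.list(row)))
      stop("feature row must be \"NA\" or an array: ", l, call. = FALSE)
  }
  invisible(TRUE)
}
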