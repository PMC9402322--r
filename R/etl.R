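## Extract & Transform: read the pipe-delimited RRF-dialect
## terminology files and the external-link CSVs, and assemble the
## knowledge graph. The dialects (deliberately narrower than real
## 18-column UMLS RRF) are:
##   MRCONSO: CUI|SAB|CODE|STR        concept atoms
##   MRREL:   CUI1|REL|RELA|CUI2|SAB  relationships
##   MRSAT:   CUI|ATN|ATV             attributes (ATN=SEMTYPE carries
##                                    semantic-type codes)
##   links:   CSV with header external_id,external_source,cui,
##            relation,target

RRF_FIELDS <- list(MRCONSO = 4L, MRREL = 5L, MRSAT = 3L)

## Coarse REL labels are normalized to predicates when no specific
## RELA is present.
REL_MAP <- c(RO = "related_to", PAR = "parent_of", CHD = "child_of",
             RB = "broader", RN = "narrower")

#' Read an RRF-dialect file
#'
#' One record per pipe-delimited line, no header. Malformed lines
#' (wrong field count, malformed CUI, or an empty mandatory field)
#' are skipped and counted; a non-empty file in which *no* line
#' matches the requested kind is treated as the wrong file and raises
#' an error.
#'
#' @param path file path.
#' @param kind `"MRCONSO"`, `"MRREL"` or `"MRSAT"`.
#' @return list with `records` (data.frame; columns depend on
#'   `kind`), `parsed`, `skipped` and `skippedLines` (1-based line
#'   numbers).
#' @examples
#' f <- tempfile()
#' writeLines(c("C0000001|NCI|X1|aspirin", "garbage"), f)
#' readRRF(f, "MRCONSO")$parsed
#' @export
readRRF <- function(path, kind = c("MRCONSO", "MRREL", "MRSAT")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  nf <- RRF_FIELDS[[kind]]
  parts <- strsplit(lines, "|", fixed = TRUE)
  ok <- lengths(parts) == nf
  field <- function(i) vapply(parts[ok], `[[`, "", i)
  if (any(ok)) {
    cui1 <- field(1L)
    good <- isCui(cui1)
    if (kind == "MRCONSO") {
      rec <- data.frame(cui = cui1, sab = field(2L), code = field(3L),
                        label = field(4L), stringsAsFactors = FALSE)
      good <- good & nzchar(rec$label)
    } else if (kind == "MRREL") {
      rec <- data.frame(cui1 = cui1, rel = field(2L), rela = field(3L),
                        cui2 = field(4L), sab = field(5L),
                        stringsAsFactors = FALSE)
      good <- good & isCui(rec$cui2)
    } else {
      rec <- data.frame(cui = cui1, atn = field(2L), atv = field(3L),
                        stringsAsFactors = FALSE)
      good <- good & nzchar(rec$atn)
    }
    rec <- rec[good, , drop = FALSE]
    rownames(rec) <- NULL
    okIdx <- which(ok)
    skippedLines <- sort(c(which(!ok), okIdx[!good]))
  } else {
    rec <- switch(kind,
      MRCONSO = data.frame(cui = character(), sab = character(),
                           code = character(), label = character()),
      MRREL = data.frame(cui1 = character(), rel = character(),
                         rela = character(), cui2 = character(),
                         sab = character()),
      MRSAT = data.frame(cui = character(), atn = character(),
                         atv = character()))
    skippedLines <- seq_along(lines)
  }
  if (length(lines) > 0L && nrow(rec) == 0L)
    stop(sprintf("'%s' contains no well-formed %s-dialect record; wrong kind?",
                 path, kind), call. = FALSE)
  list(records = rec, parsed = nrow(rec),
       skipped = length(skippedLines), skippedLines = skippedLines)
}

#' Read an external-link CSV (DrugBank/PharmGKB-style records)
#'
#' The CSV must carry the exact header
#' `external_id,external_source,cui,relation,target`. `cui` may be
#' empty for records that are only joinable through a previously
#' aliased external id.
#'
#' @param path file path.
#' @return list with `records` (data.frame), `parsed`, `skipped`,
#'   `skippedLines`.
#' @export
readLinkCSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  want <- c("external_id", "external_source", "cui", "relation", "target")
  if (!identical(names(df), want))
    stop(sprintf("'%s' does not match the link-CSV dialect (header must be %s)",
                 path, paste(want, collapse = ",")), call. = FALSE)
  ok <- nzchar(df$external_id) &
    df$external_source %in% c("DRUGBANK_LIKE", "PHARMGKB_LIKE") &
    nzchar(df$relation) & nzchar(df$target) &
    (!nzchar(df$cui) | isCui(df$cui))
  rec <- df[ok, , drop = FALSE]
  rownames(rec) <- NULL
  list(records = rec, parsed = nrow(rec), skipped = sum(!ok),
       skippedLines = which(!ok) + 1L)   # +1: header line
}

externalPrefix <- c(DRUGBANK_LIKE = "DB", PHARMGKB_LIKE = "PGKB")

#' Assemble a knowledge graph from parsed source records
#'
#' Concept records become labeled entities; relation records become
#' triples whose predicate is the lower-cased `rela` when present,
#' else the normalized coarse `rel` (`RO` -> `related_to`, `PAR` ->
#' `parent_of`, `CHD` -> `child_of`, `RB` -> `broader`, `RN` ->
#' `narrower`); attribute records with `ATN = SEMTYPE` attach the
#' (upper-cased) type code to the entity, any other attribute becomes
#' a literal triple; external links attach their relation triple
#' under the linked CUI when one is known -- either on the record
#' itself or through an alias registered by an earlier record with
#' the same external id -- and under the source-prefixed external id
#' (`DB:...`, `PGKB:...`) otherwise, in which case the id is listed in
#' the report's `unresolvedLinks`.
#'
#' @param concepts,relations,attributes data.frames as returned in
#'   `readRRF(...)$records` (any may be `NULL`).
#' @param links data.frame as returned in `readLinkCSV(...)$records`
#'   (may be `NULL`).
#' @param registry predicate registry.
#' @return list with `graph` (a [KnowledgeGraph-class]) and `report`
#'   (a [LoadReport-class]).
#' @export
buildGraph <- function(concepts = NULL, relations = NULL,
                       attributes = NULL, links = NULL,
                       registry = defaultPredicateRegistry()) {
  g <- emptyGraph()
  counts <- list()
  tally <- function(src, n) counts[[src]] <<- (counts[[src]] %||% 0L) + n

  if (!is.null(concepts) && nrow(concepts) > 0L) {
    for (i in seq_len(nrow(concepts)))
      g <- declareEntity(g, concepts$cui[[i]], labels = concepts$label[[i]])
    tally("MRCONSO", 0L)
  }
  if (!is.null(relations) && nrow(relations) > 0L) {
    pred <- tolower(relations$rela)
    coarse <- REL_MAP[relations$rel]
    noRela <- !nzchar(pred)
    pred[noRela] <- ifelse(is.na(coarse[noRela]),
                           tolower(relations$rel[noRela]), coarse[noRela])
    before <- nrow(g@triples)
    g <- addTriples(g, data.frame(subject = relations$cui1,
                                  predicate = pred,
                                  object = relations$cui2,
                                  literal = NA, provenance = "MRREL",
                                  stringsAsFactors = FALSE),
                    registry = registry)
    tally("MRREL", nrow(g@triples) - before)
  }
  if (!is.null(attributes) && nrow(attributes) > 0L) {
    isSem <- toupper(attributes$atn) == "SEMTYPE"
    for (i in which(isSem))
      g <- declareEntity(g, attributes$cui[[i]],
                         semtypes = attributes$atv[[i]])
    rest <- attributes[!isSem, , drop = FALSE]
    before <- nrow(g@triples)
    if (nrow(rest) > 0L)
      g <- addTriples(g, data.frame(subject = rest$cui,
                                    predicate = tolower(rest$atn),
                                    object = rest$atv, literal = NA,
                                    provenance = "MRSAT",
                                    stringsAsFactors = FALSE),
                      registry = registry)
    tally("MRSAT", nrow(g@triples) - before)
  }
  unresolved <- character()
  if (!is.null(links) && nrow(links) > 0L) {
    ## pass 1: alias registry -- any record carrying both ids makes
    ## the external id resolvable for every record (shared-identifier
    ## join)
    has <- nzchar(links$cui)
    alias <- links$cui[has]
    names(alias) <- links$external_id[has]
    alias <- alias[!duplicated(names(alias))]
    for (i in seq_len(nrow(links))) {
      rec <- links[i, ]
      subj <- if (nzchar(rec$cui)) rec$cui
      else if (rec$external_id %in% names(alias)) alias[[rec$external_id]]
      else {
        unresolved <- c(unresolved, rec$external_id)
        paste0(externalPrefix[[rec$external_source]], ":", rec$external_id)
      }
      prov <- if (rec$external_source == "DRUGBANK_LIKE") "DRUGLINK"
              else "GENELINK"
      before <- nrow(g@triples)
      g <- addTriple(g, subj, tolower(rec$relation), rec$target,
                     provenance = prov, registry = registry)
      tally(prov, nrow(g@triples) - before)
    }
  }
  srcs <- lexSort(names(counts))
  perSource <- data.frame(source = srcs,
                          parsed = vapply(srcs, function(s) switch(s,
                            MRCONSO = nrow(concepts),
                            MRREL = nrow(relations),
                            MRSAT = nrow(attributes),
                            DRUGLINK = sum(links$external_source ==
                                             "DRUGBANK_LIKE"),
                            GENELINK = sum(links$external_source ==
                                             "PHARMGKB_LIKE")), 0L),
                          skipped = rep(0L, length(srcs)),
                          triples = vapply(srcs, function(s)
                            as.integer(counts[[s]]), 0L),
                          stringsAsFactors = FALSE)
  rownames(perSource) <- NULL
  report <- new("LoadReport", perSource = perSource,
                unresolvedLinks = lexSort(unique(unresolved)))
  list(graph = g, report = report)
}

#' Build a knowledge graph straight from source files
#'
#' Convenience wrapper: [readRRF()] / [readLinkCSV()] on each given
#' path, then [buildGraph()]. Per-file skip counts from the readers
#' are merged into the load report.
#'
#' @param mrconso,mrrel,mrsat,links file paths (any may be `NULL`).
#' @param registry predicate registry.
#' @return list with `graph` and `report` as in [buildGraph()].
#' @export
buildGraphFromFiles <- function(mrconso = NULL, mrrel = NULL,
                                mrsat = NULL, links = NULL,
                                registry = defaultPredicateRegistry()) {
  co <- if (!is.null(mrconso)) readRRF(mrconso, "MRCONSO")
  re <- if (!is.null(mrrel)) readRRF(mrrel, "MRREL")
  at <- if (!is.null(mrsat)) readRRF(mrsat, "MRSAT")
  li <- if (!is.null(links)) readLinkCSV(links)
  out <- buildGraph(concepts = co$records, relations = re$records,
                    attributes = at$records, links = li$records,
                    registry = registry)
  skips <- c(MRCONSO = co$skipped %||% NA_integer_,
             MRREL = re$skipped %||% NA_integer_,
             MRSAT = at$skipped %||% NA_integer_)
  ps <- out$report@perSource
  for (s in names(skips)) {
    if (!is.na(skips[[s]]) && s %in% ps$source)
      ps$skipped[ps$source == s] <- skips[[s]]
  }
  if (!is.null(li) && li$skipped > 0L) {
    for (s in intersect(c("DRUGLINK", "GENELINK"), ps$source))
      ps$skipped[ps$source == s] <- li$skipped
  }
  out$report@perSource <- ps
  out
}

#' Render a load report as JSON
#'
#' @param report a [LoadReport-class].
#' @return character scalar of stable JSON: `{per_source: {<src>:
#'   {parsed, skipped, triples}}, unresolved_links: [...]}`.
#' @export
loadReportJSON <- function(report) {
  ps <- report@perSource
  per <- list()
  for (i in seq_len(nrow(ps)))
    per[[ps$source[[i]]]] <- list(parsed = ps$parsed[[i]],
                                  skipped = ps$skipped[[i]],
                                  triples = ps$triples[[i]])
  as.character(stableJSON(list(per_source = per,
                               unresolved_links = as.list(report@unresolvedLinks))))
}
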