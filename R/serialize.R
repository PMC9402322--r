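## Graph serialization: N-Triples, Turtle and a JSON dump, with
## lossless round-trips. RDF has no per-triple provenance slot, so the
## provenance tag is carried in the predicate IRI namespace
## (.../rel/<PROVENANCE>/<predicate>); entity annotations (labels,
## semantic types, class assignments) are emitted as triples under the
## .../rel/meta/ namespace. The parsers cover the subset of the
## formats this package emits (one triple per line) -- there is no
## ambition to be a general RDF toolkit.

ID_BASE <- "http://example.org/mechkg/id/"
REL_BASE <- "http://example.org/mechkg/rel/"
META_PREDS <- c("entity", "label", "semtype", "core_class", "subclass",
                "subclass_candidate")

escapeLiteral <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescapeLiteral <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[[i]], "", fixed = TRUE)[[1L]]
    buf <- character(0)
    j <- 1L
    while (j <= length(chars)) {
      ch <- chars[[j]]
      if (ch == "\\" && j < length(chars)) {
        nxt <- chars[[j + 1L]]
        buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\\" = "\\", "\"" = "\"", nxt))
        j <- j + 2L
      } else {
        buf <- c(buf, ch)
        j <- j + 1L
      }
    }
    out[[i]] <- paste(buf, collapse = "")
  }
  out
}

## Every asserted + annotation triple as (subjectIRI, predIRI, object
## term) rows; object term already rendered (IRI or quoted literal).
graphToTerms <- function(graph) {
  tr <- graph@triples
  rows <- list()
  if (nrow(tr) > 0L) {
    obj <- ifelse(tr$literal,
                  paste0("\"", escapeLiteral(tr$object), "\""),
                  paste0("<", ID_BASE, tr$object, ">"))
    rows[[1L]] <- data.frame(
      s = paste0("<", ID_BASE, tr$subject, ">"),
      p = paste0("<", REL_BASE, tr$provenance, "/", tr$predicate, ">"),
      o = obj, stringsAsFactors = FALSE)
  }
  meta <- function(id, pred, values, asLiteral = TRUE) {
    if (length(values) == 0L) return(NULL)
    data.frame(s = paste0("<", ID_BASE, id, ">"),
               p = paste0("<", REL_BASE, "meta/", pred, ">"),
               o = paste0("\"", escapeLiteral(values), "\""),
               stringsAsFactors = FALSE)
  }
  for (id in names(graph@entities)) {
    e <- graph@entities[[id]]
    rows <- c(rows, list(
      meta(id, "entity", ""),
      meta(id, "label", e$labels),
      meta(id, "semtype", e$semtypes),
      if (!is.na(e$coreClass)) meta(id, "core_class", e$coreClass),
      if (!is.na(e$subclass)) meta(id, "subclass", e$subclass),
      meta(id, "subclass_candidate", e$subclassCandidates)))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) out <- data.frame(s = character(), p = character(),
                                      o = character())
  out[lexOrder(out$s, out$p, out$o), , drop = FALSE]
}

termsToGraph <- function(terms) {
  g <- emptyGraph()
  stripIRI <- function(x, base) substring(gsub("^<|>$", "", x),
                                          nchar(base) + 1L)
  isLit <- startsWith(terms$o, "\"")
  subj <- stripIRI(terms$s, ID_BASE)
  predFull <- stripIRI(terms$p, REL_BASE)
  objVal <- ifelse(isLit,
                   unescapeLiteral(sub("^\"(.*)\"$", "\\1", terms$o)),
                   stripIRI(terms$o, ID_BASE))
  isMeta <- startsWith(predFull, "meta/")
  ## entity annotations first so that declared-but-isolated entities
  ## exist before triples validate against them
  entRows <- ents <- list()
  for (i in which(isMeta)) {
    id <- subj[[i]]
    e <- ents[[id]] %||% newEntityRecord()
    key <- substring(predFull[[i]], 6L)
    val <- objVal[[i]]
    e <- switch(key,
      entity = e,
      label = { e$labels <- c(e$labels, val); e },
      semtype = { e$semtypes <- c(e$semtypes, val); e },
      core_class = { e$coreClass <- val; e },
      subclass = { e$subclass <- val; e },
      subclass_candidate = { e$subclassCandidates <-
                               c(e$subclassCandidates, val); e },
      stop("unknown annotation predicate: ", key, call. = FALSE))
    ents[[id]] <- e
  }
  for (id in names(ents)) {
    e <- ents[[id]]
    e$labels <- lexSort(unique(e$labels))
    e$semtypes <- lexSort(unique(e$semtypes))
    e$subclassCandidates <- lexSort(unique(e$subclassCandidates))
    ents[[id]] <- e
  }
  g@entities <- ents
  di <- which(!isMeta)
  if (length(di) > 0L) {
    parts <- strsplit(predFull[di], "/", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad))
      stop("malformed predicate IRI: ", predFull[di][bad][[1L]],
           call. = FALSE)
    df <- data.frame(subject = subj[di],
                     predicate = vapply(parts, `[[`, "", 2L),
                     object = objVal[di],
                     literal = isLit[di],
                     provenance = vapply(parts, `[[`, "", 1L),
                     stringsAsFactors = FALSE)
    g <- addTriples(g, df)
  }
  validObject(g)
  g
}

graphToJSONList <- function(graph) {
  ids <- lexSort(names(graph@entities))
  ents <- lapply(ids, function(id) {
    e <- graph@entities[[id]]
    list(id = id, labels = as.list(e$labels),
         semtypes = as.list(e$semtypes),
         core_class = if (is.na(e$coreClass)) NULL else e$coreClass,
         subclass = if (is.na(e$subclass)) NULL else e$subclass,
         subclass_candidates = as.list(e$subclassCandidates))
  })
  tr <- graph@triples
  o <- lexOrder(tr$subject, tr$predicate, tr$object, tr$provenance)
  tr <- tr[o, , drop = FALSE]
  trs <- lapply(seq_len(nrow(tr)), function(i)
    list(subject = tr$subject[[i]], predicate = tr$predicate[[i]],
         object = tr$object[[i]], literal = tr$literal[[i]],
         provenance = tr$provenance[[i]]))
  list(entities = ents, triples = trs)
}

#' Serialize a knowledge graph
#'
#' Three formats are supported: `ntriples` and `turtle` (RDF exports;
#' triple provenance is encoded in the predicate IRI namespace and
#' entity annotations as `meta/` triples, making the round trip
#' lossless) and `json` (a plain graph dump with `entities` and
#' `triples` arrays and stable key ordering). Output is byte-identical
#' across runs: all orderings are lexicographic.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param format `"ntriples"`, `"turtle"` or `"json"`.
#' @return a single character scalar (the serialized text).
#' @seealso [deserializeGraph()], [writeGraph()], [readGraph()]
#' @examples
#' g <- addTriple(emptyGraph(), "C0000002", "inhibits", "C0000003")
#' cat(serializeGraph(g, "ntriples"))
#' @export
serializeGraph <- function(graph, format = c("ntriples", "turtle", "json")) {
  format <- match.arg(format)
  if (format == "json")
    return(as.character(stableJSON(graphToJSONList(graph))))
  terms <- graphToTerms(graph)
  if (format == "ntriples") {
    lines <- sprintf("%s %s %s .", terms$s, terms$p, terms$o)
    return(paste0(paste(lines, collapse = "\n"),
                  if (nrow(terms) > 0L) "\n" else ""))
  }
  ## turtle: one @prefix per provenance namespace actually used
  nsOf <- function(p) sub("^<(.*/)[^/]+>$", "\\1", p)
  localOf <- function(p) sub("^<.*/([^/]+)>$", "\\1", p)
  nss <- lexSort(unique(nsOf(terms$p)))
  px <- sprintf("p%d", seq_along(nss))
  names(px) <- nss
  header <- sprintf("@prefix %s: <%s> .", px, nss)
  body <- sprintf("%s %s:%s %s .", terms$s, px[nsOf(terms$p)],
                  localOf(terms$p), terms$o)
  paste0(paste(c(header, body), collapse = "\n"), "\n")
}

parseTermLine <- function(line) {
  ## term = <IRI> | prefix:local | "literal with \" escapes"
  pat <- paste0("^\\s*(<[^>]*>|[A-Za-z0-9_]+:[^\\s<\"]+)\\s+",
                "(<[^>]*>|[A-Za-z0-9_]+:[^\\s<\"]+)\\s+",
                "(<[^>]*>|\"(?:[^\"\\\\]|\\\\.)*\")\\s*\\.\\s*$")
  m <- regmatches(line, regexec(pat, line, perl = TRUE))[[1L]]
  if (length(m) != 4L)
    stop("malformed triple line: ", line, call. = FALSE)
  m[2:4]
}

#' Deserialize a knowledge graph
#'
#' Inverse of [serializeGraph()]: for every format,
#' `deserializeGraph(serializeGraph(g, f), f)` reproduces `g` exactly
#' (triple set and entity annotations).
#'
#' @param text serialized text (single character scalar).
#' @param format `"ntriples"`, `"turtle"` or `"json"`.
#' @return a [KnowledgeGraph-class].
#' @export
deserializeGraph <- function(text, format = c("ntriples", "turtle", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    x <- jsonlite::fromJSON(text, simplifyVector = FALSE)
    g <- emptyGraph()
    for (e in x$entities) {
      rec <- newEntityRecord()
      rec$labels <- lexSort(unique(unlist(e$labels) %||% character()))
      rec$semtypes <- lexSort(unique(unlist(e$semtypes) %||% character()))
      rec$coreClass <- e$core_class %||% NA_character_
      rec$subclass <- e$subclass %||% NA_character_
      rec$subclassCandidates <-
        lexSort(unique(unlist(e$subclass_candidates) %||% character()))
      g@entities[[e$id]] <- rec
    }
    if (length(x$triples) > 0L) {
      df <- do.call(rbind, lapply(x$triples, function(t)
        data.frame(subject = t$subject, predicate = t$predicate,
                   object = t$object, literal = t$literal,
                   provenance = t$provenance, stringsAsFactors = FALSE)))
      g <- addTriples(g, df)
    }
    validObject(g)
    return(g)
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  prefixes <- character()
  rows <- list()
  for (line in lines) {
    lt <- trimws(line)
    if (startsWith(lt, "@prefix")) {
      m <- regmatches(lt, regexec(
        "^@prefix\\s+([A-Za-z0-9_]+):\\s+<([^>]*)>\\s*\\.$", lt))[[1L]]
      if (length(m) != 3L) stop("malformed @prefix line: ", lt, call. = FALSE)
      prefixes[[m[[2L]]]] <- m[[3L]]
      next
    }
    terms <- parseTermLine(lt)
    expand <- function(t) {
      if (startsWith(t, "<") || startsWith(t, "\"")) return(t)
      i <- regexpr(":", t, fixed = TRUE)
      pfx <- substring(t, 1L, i - 1L)
      if (!pfx %in% names(prefixes))
        stop("undeclared prefix: ", pfx, call. = FALSE)
      paste0("<", prefixes[[pfx]], substring(t, i + 1L), ">")
    }
    rows[[length(rows) + 1L]] <-
      data.frame(s = expand(terms[[1L]]), p = expand(terms[[2L]]),
                 o = expand(terms[[3L]]), stringsAsFactors = FALSE)
  }
  terms <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(s = character(), p = character(), o = character())
  termsToGraph(terms)
}

#' Write / read a knowledge graph file
#'
#' Thin file wrappers over [serializeGraph()] /
#' [deserializeGraph()]. The format is taken from the file extension
#' (`.nt`, `.ttl`, `.json`) unless given explicitly.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param path file path.
#' @param format serialization format; `NULL` to infer from `path`.
#' @return `writeGraph` returns `path` invisibly; `readGraph` returns
#'   the graph.
#' @export
writeGraph <- function(graph, path, format = NULL) {
  format <- format %||% formatFromPath(path)
  writeLines(serializeGraph(graph, format), path, sep = "")
  invisible(path)
}

#' @rdname writeGraph
#' @export
readGraph <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% formatFromPath(path)
  deserializeGraph(paste(readLines(path, warn = FALSE), collapse = "\n"),
                   format)
}

formatFromPath <- function(path) {
  switch(tolower(tools::file_ext(path)),
         nt = "ntriples", ntriples = "ntriples",
         ttl = "turtle", turtle = "turtle",
         json = "json",
         stop("cannot infer graph format from path: ", path, call. = FALSE))
}
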