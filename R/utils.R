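## Internal helpers shared across the package.

## Locale-independent lexicographic sort (C collation) so that every
## serialized ordering is identical across platforms and locales.
lexSort <- function(x) {
  if (length(x) == 0L) return(x)
  x[order(x, method = "radix")]
}

lexOrder <- function(...) order(..., method = "radix")

## Concept identifiers are either UMLS-style CUIs ("C" + 7 digits) or
## source-prefixed tokens such as "DB:DB00762" / "PGKB:PA450214" for
## external records that carry no CUI. The pipe character is reserved
## by the RRF dialect; whitespace and ";" are excluded so identifiers
## survive every serialization untouched.
isConceptId <- function(x) {
  grepl("^C[0-9]{7}$", x) |
    grepl("^[A-Za-z][A-Za-z0-9]*:[A-Za-z0-9_.-]+$", x)
}

isCui <- function(x) grepl("^C[0-9]{7}$", x)

assertConceptId <- function(x, what = "concept id") {
  bad <- x[!isConceptId(x)]
  if (length(bad) > 0L) {
    stop(sprintf("malformed %s: '%s'", what, bad[[1L]]), call. = FALSE)
  }
  invisible(x)
}

isVar <- function(x) startsWith(x, "?")

`%||%` <- function(a, b) if (is.null(a)) b else a

## One row per call, no factors, stable column names.
emptyTripleFrame <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), literal = logical(),
             provenance = character(), stringsAsFactors = FALSE)
}

tripleKey <- function(df) {
  paste(df$subject, df$predicate, df$object, df$provenance, sep = "\r")
}

## Stable JSON text used wherever byte-identical output is promised.
stableJSON <- function(x, pretty = TRUE) {
  jsonlite::toJSON(x, auto_unbox = TRUE, pretty = pretty, digits = NA,
                   null = "null", na = "null")
}
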