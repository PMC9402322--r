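## Shared fixtures and independent oracles. Oracles deliberately use
## naive per-row scans and never touch the engine code paths they
## check.

.fixtureCache <- new.env(parent = emptyenv())

## Canonical case-study fixture, built once per test run through the
## full ETL + classification path.
fixtureBundle <- function() {
  if (is.null(.fixtureCache$bundle)) {
    dir <- file.path(tempdir(), "mechkg-fixture")
    fx <- canonicalFixture(dir)
    built <- buildGraphFromFiles(fx$files[["mrconso"]],
                                 fx$files[["mrrel"]],
                                 fx$files[["mrsat"]],
                                 fx$files[["links"]])
    schema <- defaultSchema()
    .fixtureCache$bundle <- list(
      fx = fx, report = built$report, schema = schema,
      raw = built$graph, graph = classifyGraph(built$graph, schema))
  }
  .fixtureCache$bundle
}

defaultRules <- function() {
  if (is.null(.fixtureCache$rules))
    .fixtureCache$rules <- defaultRuleBase()
  .fixtureCache$rules
}

## Exhaustive-scan pattern-match oracle: per-triple unification.
bruteMatch <- function(graph, pattern) {
  tr <- triples(graph)
  slots <- list(subject = pattern$subject, predicate = pattern$predicate,
                object = pattern$object)
  res <- list()
  for (i in seq_len(nrow(tr))) {
    binding <- list()
    ok <- TRUE
    for (pos in names(slots)) {
      pv <- slots[[pos]]
      tv <- tr[[pos]][[i]]
      if (startsWith(pv, "?")) {
        nm <- sub("^\\?", "", pv)
        if (!is.null(binding[[nm]]) && binding[[nm]] != tv) {
          ok <- FALSE; break
        }
        binding[[nm]] <- tv
      } else if (pv != tv) {
        ok <- FALSE; break
      }
    }
    if (ok) res[[length(res) + 1L]] <- binding
  }
  if (length(res) == 0L) return(NULL)
  keys <- vapply(res, function(b)
    paste(unlist(b[sort(names(b))]), collapse = "\r"), "")
  res[!duplicated(keys)]
}

## Normalize a bindings data.frame into a sorted key set for set
## comparisons.
bindingKeys <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(character())
  if (ncol(df) == 0L) return(rep("", nrow(df)))
  cols <- sort(names(df))
  sort(do.call(paste, c(lapply(cols, function(c) df[[c]]), sep = "\r")))
}

bruteKeys <- function(res) {
  if (is.null(res)) return(character())
  sort(vapply(res, function(b)
    paste(unlist(b[sort(names(b))]), collapse = "\r"), ""))
}

## Exhaustive enumeration oracle for the pharmacological-effect layer.
bruteMechanisms <- function(graph, drugA, drugB) {
  tr <- triples(graph)
  roleRows <- tr[tr$predicate == "has_role", , drop = FALSE]
  out <- character()
  for (pv in list(c(drugA, drugB), c(drugB, drugA))) {
    for (act in c("inhibits", "induces")) {
      acts <- tr[tr$predicate == act & tr$subject == pv[[1L]], ,
                 drop = FALSE]
      for (t in unique(acts$object)) {
        isSub <- any(tr$predicate == "substrate_of" &
                       tr$subject == pv[[2L]] & tr$object == t)
        if (!isSub) next
        for (kind in unique(roleRows$object[roleRows$subject == t])) {
          out <- c(out, paste(pv[[1L]], pv[[2L]], t,
                              if (act == "inhibits") "inhibitor"
                              else "inducer",
                              kind, sep = "\r"))
        }
      }
    }
  }
  sort(unique(out))
}

mechanismKeys <- function(matches) {
  sort(vapply(matches, function(m)
    paste(m@perpetrator, m@victim, m@target, m@perpetratorRole,
          m@targetKind, sep = "\r"), ""))
}

## Random knowledge graph over a small DDI vocabulary (used to fuzz
## the engines); includes role annotations, actions, features and a
## little terminology-hierarchy noise.
randomDdiGraph <- function(seed, nDrugs = 3L, nTargets = 2L,
                           pAct = 0.3, pFeat = 0.35) {
  set.seed(seed)
  drugs <- sprintf("C82%05d", seq_len(nDrugs))
  targets <- sprintf("C83%05d", seq_len(nTargets))
  vals <- c("C8700001", "C8700002")
  g0 <- emptyGraph()
  for (id in c(drugs, targets)) g0 <- declareEntity(g0, id)
  rows <- list()
  add <- function(s, p, o) rows[[length(rows) + 1L]] <<-
    data.frame(subject = s, predicate = p, object = o, literal = NA,
               provenance = "FIXTURE", stringsAsFactors = FALSE)
  for (t in targets)
    add(t, "has_role", sample(c("metabolizing_enzyme", "transporter"), 1L))
  for (d in drugs) for (t in targets) {
    if (stats::runif(1) < pAct) add(d, "inhibits", t)
    if (stats::runif(1) < pAct / 2) add(d, "induces", t)
    if (stats::runif(1) < pAct) add(d, "substrate_of", t)
  }
  for (d in drugs) for (v in vals)
    if (stats::runif(1) < pFeat) add(d, "has_effect", v)
  for (d in drugs)
    if (stats::runif(1) < pFeat / 2)
      add(d, "has_substructure_class", "lactone ring")
  if (stats::runif(1) < 0.5) add(targets[[1L]], "broader", "C8600001")
  if (length(rows) == 0L) return(g0)
  addTriples(g0, do.call(rbind, rows))
}

## Random generic graph (arbitrary predicates/literals) for
## serialization and pattern-matching fuzz.
randomGenericGraph <- function(seed, n = 25L) {
  set.seed(seed)
  ids <- sprintf("C81%05d", 1:8)
  preds <- c("related_to", "broader", "has_effect", "inhibits",
             "has_substructure_class", "has_role")
  lits <- c("alpha beta", "gamma\tdelta", "with \"quotes\"",
            "semi;colon", "plain")
  provs <- c("MRREL", "DRUGLINK", "FIXTURE")
  rows <- lapply(seq_len(n), function(i) {
    p <- sample(preds, 1L)
    lit <- p %in% c("has_substructure_class", "has_role") ||
      stats::runif(1) < 0.2
    data.frame(subject = sample(ids, 1L), predicate = p,
               object = if (lit) sample(lits, 1L) else sample(ids, 1L),
               literal = lit, provenance = sample(provs, 1L),
               stringsAsFactors = FALSE)
  })
  g <- addTriples(emptyGraph(), do.call(rbind, rows))
  declareEntity(g, "C8199999", labels = "isolated concept",
                semtypes = "T121")
}

graphSignature <- function(graph) serializeGraph(graph, "json")

closureFacts <- function(closed, pred) {
  tr <- triples(closed)
  tr[tr$predicate == pred, , drop = FALSE]
}
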