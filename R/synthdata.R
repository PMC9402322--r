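## Synthetic source generation, in the same file dialects the ETL
## reads, so the whole pipeline can be exercised end-to-end with no
## external downloads: (a) the canonical case-study fixture (the
## irinotecan + levofloxacin facts), and (b) parameterized random
## graphs with planted DDI mechanisms and an exhaustively enumerated
## ground truth.

#' The 14 substructure classes shared by irinotecan and levofloxacin
#' @return character(14) of controlled substructure-class literals.
#' @export
substructureClasses <- function() {
  c("hydroxy compounds", "heterocyclic compounds", "aromatic compounds",
    "phenols and derivatives", "pyridines and derivatives",
    "benzene and derivatives", "carboxylic acids and derivatives",
    "acetates", "ethers", "aliphatic and aryl amines", "phenyl esters",
    "anisoles", "quinolines and derivatives", "hydroxyquinolines")
}

#' Write the canonical case-study fixture
#'
#' Emits MRCONSO/MRREL/MRSAT-dialect files and a link CSV encoding
#' the irinotecan + levofloxacin facts: irinotecan is a substrate of
#' CYP3A4 and ABCB1, levofloxacin inhibits both, CYP3A4 is annotated
#' as a metabolizing enzyme and ABCB1 as a transporter, both drugs
#' are contraindicated on hypersensitivity to either agent, both
#' decrease DNA integrity, and both carry the same 14 substructure
#' classes. Per-drug (unshared) gene associations exercise the
#' PharmGKB-style link path. Entity ids are stable pseudo-CUIs
#' (C9000001...) so no real terminology identifiers are implied. A
#' `manifest.json` declares the per-file record counts and the
#' expected triple total.
#'
#' @param dir output directory (created if missing).
#' @return list with `files` (named paths: mrconso, mrrel, mrsat,
#'   links, manifest), `drugs`, `targets` (named concept ids) and
#'   `manifest` (the parsed manifest).
#' @export
canonicalFixture <- function(dir) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  iri <- "C9000001"; levo <- "C9000002"
  cyp <- "C9000003"; abcb1 <- "C9000004"
  hsIri <- "C9000005"; hsLevo <- "C9000006"; dna <- "C9000007"
  ugt <- "C9000008"; cypFam <- "C9000009"; gyra <- "C9000010"
  mrconso <- c(
    paste(iri, "NCI", "C0001", "Irinotecan", sep = "|"),
    paste(levo, "NCI", "C0002", "Levofloxacin", sep = "|"),
    paste(cyp, "NCI", "C0003", "CYP3A4", sep = "|"),
    paste(abcb1, "NCI", "C0004", "ABCB1", sep = "|"),
    paste(hsIri, "NDFRT", "N0001", "Hypersensitivity to irinotecan", sep = "|"),
    paste(hsLevo, "NDFRT", "N0002", "Hypersensitivity to levofloxacin", sep = "|"),
    paste(dna, "NDFRT", "N0003", "Decreased DNA integrity", sep = "|"),
    paste(ugt, "NCI", "C0005", "UGT1A1", sep = "|"),
    paste(cypFam, "NCI", "C0006", "Cytochrome P450 family", sep = "|"),
    paste(gyra, "NCI", "C0007", "GYRA", sep = "|"))
  mrrel <- c(
    paste(iri, "RO", "contraindicated_if", hsIri, "NDFRT", sep = "|"),
    paste(iri, "RO", "contraindicated_if", hsLevo, "NDFRT", sep = "|"),
    paste(levo, "RO", "contraindicated_if", hsIri, "NDFRT", sep = "|"),
    paste(levo, "RO", "contraindicated_if", hsLevo, "NDFRT", sep = "|"),
    paste(iri, "RO", "has_effect", dna, "NDFRT", sep = "|"),
    paste(levo, "RO", "has_effect", dna, "NDFRT", sep = "|"),
    paste(cyp, "RB", "", cypFam, "NCI", sep = "|"))
  semtype <- c(T121 = iri, T121.1 = levo, T126 = cyp, T116 = abcb1,
               T046 = hsIri, T046.1 = hsLevo, T046.2 = dna,
               T028 = ugt, T126.1 = cypFam, T028.1 = gyra)
  mrsat <- vapply(seq_along(semtype), function(i)
    paste(semtype[[i]], "SEMTYPE", sub("\\..*$", "", names(semtype)[[i]]),
          sep = "|"), "")
  linkRow <- function(eid, src, cui, rel, target)
    paste(eid, src, cui, rel, target, sep = ",")
  links <- c(
    "external_id,external_source,cui,relation,target",
    linkRow("DB00762", "DRUGBANK_LIKE", iri, "substrate_of", cyp),
    linkRow("DB00762", "DRUGBANK_LIKE", iri, "substrate_of", abcb1),
    linkRow("DB01137", "DRUGBANK_LIKE", levo, "inhibits", cyp),
    linkRow("DB01137", "DRUGBANK_LIKE", levo, "inhibits", abcb1),
    linkRow("DBP00001", "DRUGBANK_LIKE", cyp, "has_role",
            "metabolizing_enzyme"),
    linkRow("DBP00002", "DRUGBANK_LIKE", abcb1, "has_role", "transporter"),
    vapply(substructureClasses(), function(s)
      linkRow("DB00762", "DRUGBANK_LIKE", iri, "has_substructure_class", s),
      "", USE.NAMES = FALSE),
    vapply(substructureClasses(), function(s)
      linkRow("DB01137", "DRUGBANK_LIKE", levo, "has_substructure_class", s),
      "", USE.NAMES = FALSE),
    linkRow("PA450085", "PHARMGKB_LIKE", iri, "gene_association", ugt),
    linkRow("PA450214", "PHARMGKB_LIKE", levo, "gene_association", gyra))
  paths <- c(mrconso = file.path(dir, "mrconso.rrf"),
             mrrel = file.path(dir, "mrrel.rrf"),
             mrsat = file.path(dir, "mrsat.rrf"),
             links = file.path(dir, "links.csv"),
             manifest = file.path(dir, "manifest.json"))
  writeLines(mrconso, paths[["mrconso"]])
  writeLines(mrrel, paths[["mrrel"]])
  writeLines(mrsat, paths[["mrsat"]])
  writeLines(links, paths[["links"]])
  manifest <- list(
    description = "canonical irinotecan + levofloxacin case-study fixture",
    files = list(mrconso = length(mrconso), mrrel = length(mrrel),
                 mrsat = length(mrsat), links = length(links) - 1L),
    triples_expected = length(mrrel) + (length(links) - 1L),
    drugs = list(irinotecan = iri, levofloxacin = levo),
    targets = list(CYP3A4 = cyp, ABCB1 = abcb1))
  writeLines(as.character(stableJSON(manifest)), paths[["manifest"]])
  list(files = paths, drugs = c(irinotecan = iri, levofloxacin = levo),
       targets = c(CYP3A4 = cyp, ABCB1 = abcb1), manifest = manifest)
}

#' Construct simulation parameters
#'
#' Defaults describe a small, sparsely connected pharmacopeia: a
#' dozen drugs over a handful of metabolic enzymes and transporters,
#' background action/feature probabilities low enough that most
#' pairs share nothing, and two planted DDI pairs guaranteed to
#' satisfy the rule base at threshold 1.
#'
#' @param nDrugs,nEnzymes,nTransporters entity counts.
#' @param nFeatureValues candidate feature values per similarity
#'   level.
#' @param pInhibits,pInduces,pSubstrate per drug-protein action
#'   probabilities.
#' @param pFeature per drug-level-value feature probability.
#' @param nPlanted number of planted DDI pairs (disjoint).
#' @param seed integer RNG seed.
#' @return a [SimParams-class].
#' @export
simParams <- function(nDrugs = 12L, nEnzymes = 4L, nTransporters = 2L,
                      nFeatureValues = 3L, pInhibits = 0.08,
                      pInduces = 0.04, pSubstrate = 0.15,
                      pFeature = 0.12, nPlanted = 2L, seed = 1L) {
  new("SimParams", nDrugs = as.integer(nDrugs),
      nEnzymes = as.integer(nEnzymes),
      nTransporters = as.integer(nTransporters),
      nFeatureValues = as.integer(nFeatureValues),
      pInhibits = pInhibits, pInduces = pInduces,
      pSubstrate = pSubstrate, pFeature = pFeature,
      nPlanted = as.integer(nPlanted), seed = as.integer(seed))
}

simCui <- function(block, i) sprintf("C8%d%05d", block, i)

#' Generate synthetic source files with planted DDI mechanisms
#'
#' Draws a random drug/protein/feature universe per the parameters,
#' plants `nPlanted` disjoint drug pairs that are guaranteed to
#' satisfy the rule framework at threshold 1 (a perpetrator-victim
#' action on a role-annotated target plus at least one shared feature
#' level), and writes MRCONSO/MRREL/MRSAT-dialect files plus a link
#' CSV. Because background facts can create rule-satisfying pairs by
#' chance, the ground truth is not the planted list but the full
#' rule-satisfying set, enumerated exhaustively (and independently of
#' the inference engines) at generation time and written to
#' `truth.json`. Output is byte-identical for a fixed seed.
#'
#' @param params a [SimParams-class].
#' @param dir output directory (created if missing).
#' @param theta threshold used for the recorded `potential_ddi`
#'   ground-truth flags.
#' @return list with `files` (named paths), `truth` (the parsed
#'   ground truth) and `drugs` (character vector of drug ids).
#' @export
simulateSources <- function(params, dir, theta = 1) {
  validObject(params)
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(params@seed)
  drugs <- simCui(2, seq_len(params@nDrugs))
  enzymes <- if (params@nEnzymes > 0L) simCui(3, seq_len(params@nEnzymes))
             else character()
  transporters <- if (params@nTransporters > 0L)
    simCui(4, seq_len(params@nTransporters)) else character()
  targets <- c(enzymes, transporters)
  nv <- params@nFeatureValues
  values <- list(
    pharmacological = if (nv > 0L) simCui(5, seq_len(nv)) else character(),
    biomolecular = if (nv > 0L) simCui(6, seq_len(nv)) else character(),
    physiological = if (nv > 0L) simCui(7, seq_len(nv)) else character(),
    genetic = if (nv > 0L) simCui(8, seq_len(nv)) else character(),
    contraindication = if (nv > 0L) simCui(9, seq_len(nv)) else character(),
    substructure = if (nv > 0L) sprintf("ring system %d", seq_len(nv))
                   else character())
  levelPred <- c(pharmacological = "has_moa",
                 biomolecular = "gene_association",
                 physiological = "has_effect",
                 genetic = "snp_association",
                 contraindication = "contraindicated_if",
                 substructure = "has_substructure_class")

  ## background facts
  action <- list(inhibits = character(0))  # edge list per action
  drawPairs <- function(p) {
    hit <- which(stats::runif(length(drugs) * length(targets)) < p)
    if (length(targets) == 0L) return(data.frame(drug = character(),
                                                 target = character()))
    data.frame(drug = drugs[((hit - 1L) %% length(drugs)) + 1L],
               target = targets[((hit - 1L) %/% length(drugs)) + 1L],
               stringsAsFactors = FALSE)
  }
  acts <- list(inhibits = drawPairs(params@pInhibits),
               induces = drawPairs(params@pInduces),
               substrate_of = drawPairs(params@pSubstrate))
  feats <- list()
  for (lv in names(values)) {
    vals <- values[[lv]]
    if (length(vals) == 0L) {
      feats[[lv]] <- data.frame(drug = character(), value = character())
      next
    }
    hit <- which(stats::runif(length(drugs) * length(vals)) < params@pFeature)
    feats[[lv]] <- data.frame(
      drug = drugs[((hit - 1L) %% length(drugs)) + 1L],
      value = vals[((hit - 1L) %/% length(drugs)) + 1L],
      stringsAsFactors = FALSE)
  }

  ## planted pairs: disjoint; each gets one perpetrator action on a
  ## role-annotated target and one shared feature value
  plantedPairs <- list()
  if (params@nPlanted > 0L) {
    ord <- sample(drugs)
    lvPool <- names(values)[lengths(values) > 0L]
    for (k in seq_len(params@nPlanted)) {
      a <- ord[[2L * k - 1L]]; b <- ord[[2L * k]]
      t <- targets[[sample.int(length(targets), 1L)]]
      acts$inhibits <- rbind(acts$inhibits,
                             data.frame(drug = a, target = t,
                                        stringsAsFactors = FALSE))
      acts$substrate_of <- rbind(acts$substrate_of,
                                 data.frame(drug = b, target = t,
                                            stringsAsFactors = FALSE))
      lv <- lvPool[[sample.int(length(lvPool), 1L)]]
      v <- values[[lv]][[sample.int(length(values[[lv]]), 1L)]]
      feats[[lv]] <- rbind(feats[[lv]],
                           data.frame(drug = c(a, b), value = v,
                                      stringsAsFactors = FALSE))
      plantedPairs[[k]] <- list(drug_a = a, drug_b = b, target = t,
                                shared_level = lv)
    }
  }
  for (n in names(acts)) acts[[n]] <- unique(acts[[n]])
  for (n in names(feats)) feats[[n]] <- unique(feats[[n]])

  ## ---- emit source files ----
  lab <- function(id, what, i) sprintf("%s %d", what, i)
  conso <- c(
    sprintf("%s|SYN|D%04d|drug %d", drugs, seq_along(drugs),
            seq_along(drugs)),
    if (length(enzymes) > 0L)
      sprintf("%s|SYN|E%04d|enzyme %d", enzymes, seq_along(enzymes),
              seq_along(enzymes)),
    if (length(transporters) > 0L)
      sprintf("%s|SYN|T%04d|transporter %d", transporters,
              seq_along(transporters), seq_along(transporters)))
  semOf <- c(pharmacological = "T120", biomolecular = "T028",
             physiological = "T046", genetic = "T086",
             contraindication = "T046")
  sat <- c(sprintf("%s|SEMTYPE|T121", drugs),
           if (length(enzymes) > 0L) sprintf("%s|SEMTYPE|T126", enzymes),
           if (length(transporters) > 0L)
             sprintf("%s|SEMTYPE|T116", transporters))
  for (lv in names(semOf)) {
    vals <- values[[lv]]
    if (length(vals) > 0L) {
      conso <- c(conso, sprintf("%s|SYN|V%04d|%s value %d", vals,
                                seq_along(vals), lv, seq_along(vals)))
      sat <- c(sat, sprintf("%s|SEMTYPE|%s", vals, semOf[[lv]]))
    }
  }
  relRows <- character()
  for (lv in c("physiological", "contraindication", "pharmacological")) {
    df <- feats[[lv]]
    if (nrow(df) > 0L)
      relRows <- c(relRows, sprintf("%s|RO|%s|%s|SYN", df$drug,
                                    levelPred[[lv]], df$value))
  }
  linkRows <- character()
  for (n in names(acts)) {
    df <- acts[[n]]
    if (nrow(df) > 0L)
      linkRows <- c(linkRows, sprintf("X%s,DRUGBANK_LIKE,%s,%s,%s",
                                      df$drug, df$drug, n, df$target))
  }
  if (length(enzymes) > 0L)
    linkRows <- c(linkRows, sprintf(
      "X%s,DRUGBANK_LIKE,%s,has_role,metabolizing_enzyme",
      enzymes, enzymes))
  if (length(transporters) > 0L)
    linkRows <- c(linkRows, sprintf(
      "X%s,DRUGBANK_LIKE,%s,has_role,transporter",
      transporters, transporters))
  df <- feats$substructure
  if (nrow(df) > 0L)
    linkRows <- c(linkRows, sprintf(
      "X%s,DRUGBANK_LIKE,%s,has_substructure_class,%s",
      df$drug, df$drug, df$value))
  for (lv in c("biomolecular", "genetic")) {
    df <- feats[[lv]]
    if (nrow(df) > 0L)
      linkRows <- c(linkRows, sprintf("P%s,PHARMGKB_LIKE,%s,%s,%s",
                                      df$drug, df$drug, levelPred[[lv]],
                                      df$value))
  }
  conso <- lexSort(conso); sat <- lexSort(sat)
  relRows <- lexSort(relRows); linkRows <- lexSort(linkRows)

  ## ---- exhaustive ground truth (no inference engine involved) ----
  roleOf <- c(stats::setNames(rep("metabolizing_enzyme", length(enzymes)),
                              enzymes),
              stats::setNames(rep("transporter", length(transporters)),
                              transporters))
  hasAct <- function(kind, d, t)
    any(acts[[kind]]$drug == d & acts[[kind]]$target == t)
  truthPairs <- list()
  if (length(drugs) >= 2L) {
    for (i in seq_len(length(drugs) - 1L)) {
      for (j in seq((i + 1L), length(drugs))) {
        a <- drugs[[i]]; b <- drugs[[j]]
        mechs <- list()
        for (pv in list(c(a, b), c(b, a))) {
          for (t in targets) {
            for (kind in c("inhibits", "induces")) {
              if (hasAct(kind, pv[[1L]], t) &&
                  hasAct("substrate_of", pv[[2L]], t)) {
                mechs[[length(mechs) + 1L]] <- list(
                  perpetrator = pv[[1L]], victim = pv[[2L]], target = t,
                  target_kind = unname(roleOf[[t]]),
                  role = if (kind == "inhibits") "inhibitor" else "inducer")
              }
            }
          }
        }
        lvShared <- character()
        for (lv in names(feats)) {
          df <- feats[[lv]]
          if (length(intersect(df$value[df$drug == a],
                               df$value[df$drug == b])) > 0L)
            lvShared <- c(lvShared, lv)
        }
        lvShared <- lexSort(lvShared)
        if (length(mechs) > 0L || length(lvShared) > 0L)
          truthPairs[[length(truthPairs) + 1L]] <- list(
            drug_a = a, drug_b = b, mechanisms = mechs,
            shared_levels = as.list(lvShared),
            n_shared_levels = length(lvShared),
            potential_ddi = length(mechs) > 0L &&
              length(lvShared) >= theta)
      }
    }
  }
  truth <- list(seed = params@seed, theta = theta,
                drugs = as.list(drugs),
                planted = plantedPairs, pairs = truthPairs)

  paths <- c(mrconso = file.path(dir, "mrconso.rrf"),
             mrrel = file.path(dir, "mrrel.rrf"),
             mrsat = file.path(dir, "mrsat.rrf"),
             links = file.path(dir, "links.csv"),
             truth = file.path(dir, "truth.json"))
  writeLines(conso, paths[["mrconso"]])
  writeLines(relRows, paths[["mrrel"]])
  writeLines(sat, paths[["mrsat"]])
  writeLines(c("external_id,external_source,cui,relation,target", linkRows),
             paths[["links"]])
  writeLines(as.character(stableJSON(truth)), paths[["truth"]])
  list(files = paths, truth = truth, drugs = drugs)
}

#' Plant a single ontology defect in a graph
#'
#' Adds exactly one defect of the requested kind (fresh entity ids in
#' the C7999xxx range, so existing facts are untouched). Run
#' [classifyGraph()] and [checkConsistency()] afterwards; a
#' defect-free graph plus one planted defect yields exactly one
#' violation of the matching kind.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param kind one of `MULTI_CLASS_CONFLICT`, `UNKNOWN_PREDICATE`,
#'   `DOMAIN_VIOLATION`, `RANGE_VIOLATION`.
#' @return the graph with the defect added.
#' @export
plantDefect <- function(graph,
                        kind = c("MULTI_CLASS_CONFLICT", "UNKNOWN_PREDICATE",
                                 "DOMAIN_VIOLATION", "RANGE_VIOLATION")) {
  kind <- match.arg(kind)
  switch(kind,
    MULTI_CLASS_CONFLICT =
      ## semantic types mapping to subclasses in different core
      ## classes (drugs/pharmacological vs snps/genetic)
      declareEntity(graph, "C7999001", labels = "conflicted concept",
                    semtypes = c("T121", "T086")),
    UNKNOWN_PREDICATE = {
      g <- declareEntity(graph, "C7999002", semtypes = "T121")
      g <- declareEntity(g, "C7999003", semtypes = "T121")
      addTriple(g, "C7999002", "frobnicates", "C7999003", literal = FALSE)
    },
    DOMAIN_VIOLATION = {
      g <- declareEntity(graph, "C7999004", semtypes = "T046")  # effect
      g <- declareEntity(g, "C7999005", semtypes = "T126")      # enzyme
      addTriple(g, "C7999004", "inhibits", "C7999005")
    },
    RANGE_VIOLATION = {
      g <- declareEntity(graph, "C7999006", semtypes = "T121")  # drug
      g <- declareEntity(g, "C7999007", semtypes = "T121")      # drug
      addTriple(g, "C7999006", "inhibits", "C7999007")
    })
}
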