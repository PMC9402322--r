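Package: mechkg
Title: Mechanistic Knowledge Graphs and Rule-Based Inference for
    Drug-Drug Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds a mechanistic knowledge graph for drug-drug
    interaction (DDI) analysis from UMLS-style terminology files
    (MRCONSO/MRREL/MRSAT dialects) and DrugBank/PharmGKB-style link
    tables, validates it against a four-class/seven-subclass ontology
    with semantic-type driven classification and structural consistency
    checks, and runs a two-layer backward-chaining Horn-rule engine
    that proves or rejects a potential DDI for a drug pair. Accepted
    hypotheses come with proof trees: perpetrator/victim roles on
    metabolizing enzymes and transporters (inhibition or induction)
    and shared biomedical features across pharmacological,
    biomolecular, physiological and genetic levels. Includes a
    synthetic-source generator with planted ground truth, a
    forward-closure oracle for engine verification, report rendering,
    and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'rules.R'
    'AllGenerics.R'
    'registry.R'
    'kgraph.R'
    'serialize.R'
    'etl.R'
    'schema.R'
    'inference.R'
    'ddi.R'
    'explain.R'
    'synthdata.R'
    'cli.R'
    'mechkg-package.R'
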