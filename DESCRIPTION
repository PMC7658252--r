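Package: synthforge
Title: Forward-Synthesis Enumeration of Virtual Compound Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Builds scored virtual compound libraries by applying
    expert-system style reaction rules to pools of purchasable building
    blocks.  Rules combine SMARTS reactant role patterns, a SMIRKS product
    template and ordered ADD/SUBTRACT/KILL scoring clauses; saved reactions
    are binned into synthesizability classes, products are stored
    deprotected with provenance suffixes, and library-level analytics
    (success rates, theoretical maximum, SAR-neighbor estimates,
    ring-system census, set overlap) and drug-design annotation
    (rule-of-five/three, PAINS, additive demerits, QED) are provided.
    Chemistry primitives are delegated to RDKit through a batch JSON
    subprocess bridge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.9) with RDKit, resolvable as 'python'
    on the PATH (override with the SYNTHFORGE_PYTHON environment variable)
Config/testthat/edition: 3
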