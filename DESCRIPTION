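Package: cazac
Title: Parse, Validate and Search CAZac Activity Descriptors for
    Carbohydrate-Active Enzymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the CAZac activity descriptor, the multicriterion
    nomenclature used to describe the activities of glycoside hydrolases,
    glycoside phosphorylases, transglycosylases, polysaccharide lyases and
    lytic polysaccharide monooxygenases.  Provides parsers and canonical
    renderers for the residue, bond, reactant and mechanism grammars; an
    eight-field activity record model with Enzyme Commission (EC) number
    mapping and validation; readers and writers for activity tables in a
    fixed TSV dialect; a bundled starch-degradation activity table; a
    structured search engine with strict and non-strict residue matching;
    and seeded random generators for property-based testing.  All
    user-facing functions take and return tibbles so pipelines compose
    with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
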