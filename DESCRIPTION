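Package: pepmeta
Title: Portable Encapsulated Projects: Sample Metadata Reading, Modification, and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reads, processes, and validates Portable Encapsulated Projects
    (PEPs): a plain-text standard for biological sample metadata built from a
    YAML project configuration file, a CSV sample table, and an optional CSV
    subsample table. Implements the two project modifiers (import, amend) that
    merge or embed project configurations, the five sample modifiers (remove,
    append, duplicate, imply, derive) that transform sample attributes without
    touching the CSV, subsample merging into multi-valued attributes, and a
    two-stage schema validator extending a JSON-Schema subset with schema
    imports and a required_files keyword for file-existence checks. Includes a
    command-line interface and a deterministic synthetic-PEP fixture
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    yaml,
    jsonlite,
    utils,
    tools,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
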