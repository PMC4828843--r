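Package: dedupr
Title: Cost-Reduced Record De-Duplication via Blocking and Windowing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for de-duplicating person-record datasets at sub-quadratic
    cost. Implements composite-key blocking, multipass blocking and multipass
    sorted-neighbourhood windowing run in succession, with phonetic (soundex)
    and substring-prefix key encodings, edit-distance and q-gram field
    comparators, two-threshold match classification, indexing quality metrics
    (pairs quality, pairs completeness, reduction ratio, F-score), closed-form
    comparison-count estimators, and a synthetic dirty-data generator with a
    known gold standard.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
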