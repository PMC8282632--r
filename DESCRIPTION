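Package: rfcph
Title: Recursive Functional Classification of Pleckstrin Homology Domains
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Position-specific log-ratio scoring of aligned pleckstrin
    homology (PH) domain sequences to predict phosphoinositide (PIP)
    binding.  Builds per-group amino-acid probability matrices from a
    labelled multiple sequence alignment, combines them into a log-ratio
    scoring matrix, scores sequences (S_RFC), derives a binding-call
    threshold from a scrambled-sequence null distribution, and evaluates
    predictions against binary assay outcomes.  Ships transcriptions of
    published binary lipid-pulldown outcome tables and a synthetic
    alignment generator with planted binding-determinant columns so the
    whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    caret,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
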