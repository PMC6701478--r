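Package: kmwalk
Title: Targeted Variant Detection in Raw Sequencing Reads by k-mer Walking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects substitutions, insertions, deletions, indels, internal
    tandem duplications (ITDs) and gene-fusion evidence directly in raw
    (unaligned) sequencing reads by local assembly over a canonical k-mer
    count table, restricted to user-supplied target sequences. A target
    sequence is decomposed into a linear k-mer graph; a depth-first walk
    through the sample's count table finds alternative paths that leave the
    target and rejoin it, which are then classified, quantified by a local
    coverage ratio, and filtered. Includes a Jellyfish-compatible text-dump
    reader/writer, a read simulator with injected ground-truth mutations,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
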