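Package: koextractr
Title: Build Ortholog Reference Gene Sets from KEGG Orthology Annotation Output
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Parses KofamKOALA-style KEGG Orthology (KO) annotation results,
    extracts the matching protein and CDS sequences from batch genome FASTA
    files, tags them with species information from NCBI assembly summaries,
    and groups them into per-KO reference sets. Downstream stages filter
    partial sequences against a reference length, collapse the set to a
    non-redundant representative set at 100% identity, and assess a
    constructed reference database by recall and by false-negative rate
    across identity thresholds. A seeded synthetic-fixture generator
    produces coherent genome/annotation/summary inputs so the whole
    pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    tibble,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
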