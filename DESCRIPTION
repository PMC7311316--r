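Package: pathgaps
Title: Confidence-Tiered Reconstruction of Amino Acid Biosynthesis Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Homology-based reconstruction of biosynthetic pathways in
    bacterial and archaeal genomes. Given a proteome, a set of curated
    pathway definitions, and a reference database of characterized and
    curated proteins plus profile HMMs with trusted cutoffs, the package
    finds candidates for every pathway step, scores them as high, medium,
    or low confidence, handles fused and split proteins, selects the
    highest-confidence path for each pathway, and marks gaps that are
    known gaps in related organisms (assessed via ribosomal marker
    proteins). Ships a synthetic fixture generator so the full engine can
    be exercised without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
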