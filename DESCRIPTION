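Package: glocon
Title: Conformational-State Identification for Protein Structure Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies putative conformational states among protein chains
    sharing a reference (UniProt-style) sequence. Chains are grouped into
    segments of identical sequence coverage, compared pairwise with the
    transformation-independent GLOCON dissimilarity (filtered absolute
    difference of Calpha distance matrices, gap-penalised), clustered by
    UPGMA average linkage with a cut at a fraction of the maximum score,
    and summarised by medoid representative chains. Includes Kabsch
    least-squares superposition for display and for comparing a predicted
    model against each state, mmCIF/PDB input, mmCIF output, and a
    synthetic-ensemble generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
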