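Package: orburb
Title: Active Versus Total Gut Microbiota Profiling from Tag-Aware 16S Amplicon Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to distinguish the transcriptionally active fraction of the
    human gut microbiota from the total community using multiplexed 16S rDNA
    amplicon libraries. Implements tag-aware read preparation for the
    MID-PERMUTAG-linker-primer read structure (demultiplexing, exact
    dereplication that treats the degenerate PERMUTAG as part of the sequence,
    tag stripping), lowest-common-ancestor taxonomic assignment from tabular
    similarity-search hits, family-level abundance profiling across sorted cell
    fractions, community statistics (Bray-Curtis dissimilarity,
    complete-linkage clustering, rarefaction, Shannon diversity, sequential
    permutational multivariate analysis of variance), and an inflection-point
    classifier that splits ordered family-abundance distributions into
    over-represented (ORB) and under-represented (URB) taxa, with per-family
    Welch tests comparing active and total fractions. A synthetic-data module
    generates complete datasets with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    Biostrings,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
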