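Package: lassomine
Title: Genome Mining, Construct Refactoring and MS/MS Topology Annotation
    for Lasso Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering lasso peptide (RiPP) biosynthetic gene
    clusters in assembled metagenomic contigs and confirming the threaded
    topology of their products by mass spectrometry. Includes a precursor
    gene heuristic built around the conserved Thr(-2) motif and
    noncanonical ring-forming residues, Group I/II architecture
    classification and colinearity checks, in-silico refactoring of
    clusters into expression inserts with optimized ribosome binding
    sites, an exact monoisotopic fragment-mass model for macrolactam
    ring-opening and interlocked b/y species, ppm-tolerance extracted ion
    chromatograms and MS2 annotation, and seeded synthetic-data
    generators for contigs and centroided peak lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
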