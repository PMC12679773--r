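Package: annotrack
Title: Census, Comparison and Expression Analysis of Evolving Genome
    Annotation Releases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize how genome annotations evolve across
    releases of a reference annotation (Ensembl GRCh38 dialect GTF).
    Parses gene/transcript/exon hierarchies, computes per-release censuses
    (gene and transcript counts, biotype rankings, isoforms-per-gene
    distributions), performs two- and three-way set comparisons of feature
    identifiers including detection of transient biotype flips, and
    summarizes transcript length distributions (quartiles, N50) by
    harmonized biotype. A companion expression module consumes a
    transcript-by-sample matrix of unique read counts with tissue labels,
    applies per-tissue median-count and counts-per-million filters,
    identifies transcripts newly annotated between an old and a new
    release, and quantifies their summed relative abundance per gene and
    tissue, including threshold sweeps. A synthetic-data module generates
    scripted multi-release GTF series and overdispersed count matrices
    with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    Matrix,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
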