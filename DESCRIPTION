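Package: orthocascade
Title: Reciprocal-Best-Hit Ortholog Cascades, Conservation Statistics and
    Annotation Enrichment for De Novo Transcriptomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics toolkit for de novo assembled
    transcriptomes. Computes reciprocal-best-hit ("blast-back") orthology
    from standard 12-column BLAST tabular hit files, assigns each focal
    transcript to a single reference species through a configurable
    priority cascade, intersects one-to-one orthologs across all
    reference species, summarises transcript lengths and nucleotide /
    amino-acid identity (including the two-proportion z-test used to
    compare species-level mean identities), partitions genes into
    conservation deciles, and tests annotation terms for enrichment with
    an in-house log-space Fisher exact engine with Bonferroni and
    Benjamini-Hochberg adjustment. A seeded multi-species sequence
    simulator with planted orthologs, paralogs, fragmented transcripts,
    per-species dropout and planted annotation enrichment provides ground
    truth for every stage, and a pipeline layer orchestrates the stages
    behind one entry point with a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
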