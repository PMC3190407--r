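Package: taxburst
Title: Quantitative Sunburst Charts for Taxonomic Classifications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts metagenomic classification outputs into quantitative
    hierarchical sunburst charts. Reads BLAST tabular hits, RDP-Classifier and
    PhymmBL per-read tables, generic lineage text files and ACE assemblies;
    assigns reads to an NCBI-dialect taxonomy by lowest common ancestor of the
    top-scoring hits; builds a magnitude-weighted tree with radix compression
    of linear lineages and depth summarization; lays the tree out as a radial
    space-filling chart with recursive HSL coloring or value gradients; and
    renders deterministic, publication-ready SVG plus a self-contained HTML
    wrapper. Includes seed-deterministic fixture generators so the whole
    pipeline is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    xml2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
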