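# taxburst

Quantitative sunburst charts for taxonomic classifications.

Metagenomic studies end with reads or contigs assigned to a taxonomy, with
uncertainty attached. Bar charts flatten the hierarchy; node-link trees with
log-scaled count charts distort relative abundance. **taxburst** builds the
radial space-filling alternative: a chart where each taxon is an annular
wedge whose *angular sweep* is proportional to its magnitude, nesting
encodes rank, and color encodes either lineage or a secondary quantity such
as classifier confidence or BLAST e-value — so abundance and its hierarchical
context are visible across all ranks at once.

The package is a complete pipeline, usable from R or a bundled command-line
script:

* **Importers** — 12-column BLAST tabular hits (with subject→taxon mapping),
  RDP-Classifier-style and PhymmBL-style per-read tables with per-rank
  confidences, generic lineage+magnitude text, reads-per-contig magnitudes
  from ACE assemblies, and NCBI-dialect taxonomy dumps
  (`nodes.dmp`/`names.dmp`/`merged.dmp`).
* **Classification** — each query is assigned to the lowest common ancestor
  (LCA) of its top-scoring hits: hits with bit score ≥ *f*·max survive
  (default *f* = 1, exact ties), and the assignment for a query hitting taxa
  $t_1,\dots,t_k$ is the deepest node on all of their root paths.
* **Tree model** — per-dataset magnitudes with subtree totals
  $M(v) = m(v) + \sum_c M(c)$, magnitude-weighted attribute aggregates,
  radix compression of unary zero-assignment chains, depth summarization,
  deterministic sorting, and name search that honors the visible depth.
* **Layout and color** — sweeps of $360\,M(v)/M(\text{root})$ degrees with
  the unassigned remainder exposed on the parent ring; geometrically
  compressed radial bands; collision-free label placement; a polar fisheye
  zoom as a static transform; recursive HSL hue subdivision (the largest
  child inherits its parent's hue) and linear value gradients.
* **Output** — deterministic SVG, a self-contained HTML page embedding the
  chart's XML, and a versioned chart-XML format whose write/read round trip
  is the identity.

All of it is testable offline: `make_toy_taxonomy()`, `make_synthetic_hits()`
(with ground-truth sidecars) and `make_skewed_profile()` generate every input
format deterministically from a seed.

## Worked example

Generate a 120-taxon toy taxonomy and 200 synthetic queries (25% constructed
as exact sibling-leaf score ties, so their correct assignment is the sibling
pair's parent), classify, and render:

```r
library(taxburst)

db <- make_toy_taxonomy(n_nodes = 120, branching = 3, seed = 42, dir = "taxdump")
fx <- make_synthetic_hits(db, n_queries = 200, hits_per_query = 3,
                          tie_fraction = 0.25, seed = 42)

ch <- chart_from_blast(fx$hits_path, db, taxon_map = fx$taxon_map)
ch
#> <taxburst_chart> root 'toy root': 115 nodes, height 10
#>   datasets:   dataset 1
#>   totals:     200
#>   attributes: avg_log_evalue, identity
```

All 200 queries were classified (the root total equals the query count —
conservation is exact), and every node carries the average log10 e-value and
percent identity of the reads beneath it. Render the chart summarized at six
levels, colored by e-value:

```r
render_chart(ch, out_svg = "chart.svg", max_depth = 6, color_by = "avg_log_evalue")
write_chart_xml(ch, "chart.xml")                 # portable chart document
render_html(ch, render_chart(ch))                # single-file HTML wrapper
```

Search works on visible and compressed names; hidden matches report the
visible ancestor that contains them:

```r
str(search_tree(ch$root, "taxon 1", visible_depth = 4))
#> List of 2
#>  $ matched         : chr [1:8] "toy root/Taxon 2/Taxon 10" ...
#>  $ hidden_ancestors: chr [1:10] "toy root/Taxon 2/Taxon 10/Taxon 12" ...
```

A requested 80%/10% two-domain profile reproduces its wedge angles exactly:

```r
prof <- make_skewed_profile(c(Bacteria = 0.8, Archaea = 0.1), total_magnitude = 1000)
s <- compute_angles(sort_tree(chart_from_text(prof)$root))
s[s$depth == 2, c("name", "sweep")]
#>       name sweep
#>   Bacteria   288
#>    Archaea    36
```

The same pipeline is available from a shell:

```sh
Rscript inst/cli/taxburst import-blast --hits hits.tsv --taxonomy taxdump \
    --taxon-map map.tsv --out chart.xml
Rscript inst/cli/taxburst render --in chart.xml --out chart.svg --max-depth 6
```

Exit codes: 0 success, 1 data error, 2 usage/path error.

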