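---
title: "Methods: quantitative sunburst charts for taxonomic classifications"
author: "taxburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative sunburst charts for taxonomic classifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxburst)
```

## The problem

A metagenomic analysis ends with reads (or contigs) assigned to nodes of a
taxonomic or functional hierarchy, usually with some measure of confidence.
Interpreting those results requires seeing relative abundances across many
ranks at once, together with the uncertainty of the assignments. taxburst
models this as a *quantitative tree* — every node carries a magnitude
assigned directly to it plus the magnitudes of its subtree — and lays the
tree out as a radial space-filling ("sunburst") chart: angular sweep encodes
magnitude, radial depth encodes rank, and color encodes either lineage (a
recursive hue scheme) or a secondary quantity such as classifier confidence
or BLAST e-value.

## The model

### The quantitative tree

A chart node holds a per-dataset vector of **assigned magnitudes** (reads
classified exactly there). The displayed quantity is the subtree total

$$M(v) = m(v) + \sum_{c \in \mathrm{children}(v)} M(c),$$

and every structural operation must conserve $M(\mathrm{root})$ per dataset.
Magnitudes are non-negative reals, not integers, so weighted counts (e.g.
reads per contig from an ACE assembly) are first-class.

Attributes (confidence, log10 e-value, percent identity) are stored as
magnitude-weighted aggregates $(\bar{x}, w)$. Merging two aggregates by
$\bar{x}_{12} = (\bar{x}_1 w_1 + \bar{x}_2 w_2)/(w_1+w_2)$ is exactly
equivalent to pooling the underlying observations, which is what makes depth
pruning and node coloring consistent with per-read aggregation (this
associativity is property-tested).

### LCA classification of alignment hits

A query with multiple alignments is assigned to the **lowest common
ancestor** (LCA) of the taxa of its top-scoring hits. "Top-scoring" is
parameterized as a bit-score factor: hits with
$\mathrm{bit} \ge f \cdot \mathrm{bit}_{\max}$ survive, with default
$f = 1$ — exact ties only, the strictest reading. The per-query attribute
values entering aggregation come from the single best hit (ties broken by
subject taxon id, so results are permutation-invariant). E-values of zero,
which BLAST reports on underflow, are clamped to $10^{-300}$ before taking
log10. Queries whose subject taxa cannot be resolved against the taxonomy
are dropped and counted (strict mode raises instead); merged taxon ids are
remapped only when a `merged.dmp` is supplied, because silently dropping
renamed taxa is worse than failing loudly.

### Radix compression and depth summarization

Mapping classifications onto a full taxonomy produces long unary chains
(a species that is its class's only representative is redundantly nested
under every intermediate rank). `collapse_linear()` replaces every maximal
chain of single-child, zero-assignment nodes by its deepest — most specific —
node, recording the absorbed ancestors so search still finds them and the
uncompressed view can be reconstructed. `prune_depth()` truncates the tree at
a chosen depth, folding deeper magnitudes and attribute aggregates into the
retained ancestor. Both conserve the root total exactly for integer
magnitudes (floating-point inputs are conserved to rounding).

Depth counts from the root at depth 1, so "summarized at depth 6" keeps six
node generations including the root; the convention is declared here because
different tools count differently.

One interaction is worth noting: siblings are sorted by decreasing subtree
total with a case-insensitive lexicographic tie-break, and collapsing
*renames* a chain to its deepest node. When two sibling totals tie, sorting
before or after collapsing can therefore disagree — the tie-break keys
changed. The display pipeline always sorts after collapsing, and the test
suite asserts the corresponding invariant (pre-sorting never changes the
final order) rather than literal commutation.

### Angular layout

With total magnitude $M$ at the root, node $v$ gets sweep
$360 \cdot M(v)/M$ degrees, measured clockwise from 12 o'clock (start angle
configurable, default 0 — an arbitrary orientation made explicit). Children
pack contiguously from the parent's start angle in sorted order; the
trailing uncovered interval equals $360 \cdot m(v)/M$ and represents reads
assigned directly to the internal node. That *unassigned remainder* is drawn
as exposed parent ring rather than a synthetic child, so a parent with
direct assignments is visibly wider than the sum of its children. Nodes with
zero magnitude keep their place in the model but receive zero sweep, so
switching datasets never changes tree structure, only geometry.

Radial bands are compressed outward: band width at depth $d$ is proportional
to $c^{\max(0, d - d_0)}$, normalized to sum to 1, with compression
$c = 0.7$ and full-width depth $d_0 = 3$ by default. Deep ranks — usually
the interesting ones — stay in direct relation to the root while
intermediate rings shrink. The defaults are a readability judgment: $c=0.7$
keeps a depth-8 ring at about a quarter of a full band, still clickable and
labelable, and $d_0=3$ protects domain/phylum/class labels.

### Labels

Leaf-band labels run along radii; internal labels run along tangents at
their band's mid-radius. Text width is estimated as $0.6 \times$ font size
per character — a deterministic, renderer-independent heuristic chosen over
real font metrics so layout is reproducible byte-for-byte everywhere. A
tangential label must fit its sector's arc length, a radial label the span
to the canvas edge, and both need one text height of angular clearance;
oversize labels shrink step-wise to the longest prefix plus an ellipsis that
fits and are hidden when fewer than 4 characters fit. These constraints make
overlap impossible by construction; the tests verify zero overlaps with a
brute-force pairwise intersection check over randomized layouts. Siblings
with sweep below 1° can be merged into a single "N more…" group sector
(`group_small_sectors()`, threshold configurable).

### Polar zoom

Zooming is a re-layout, not a Cartesian scale-up: the focus node's sweep and
radial span grow until it occupies the full circle while everything else
compresses — a fisheye in polar coordinates. `zoom_layout()` exposes this as
a static transform: it computes the overview layout $S_0$ and the layout
$S_1$ re-rooted at the focus, then interpolates angle and radius linearly in
$t \in [0,1]$. At $t=0$ the result is bit-identical to $S_0$; at $t=1$ the
focus sweeps 360° and the layout equals a fresh chart rooted at the focus.
Nodes absent from $S_1$ interpolate their sweep to zero while keeping their
overview position — the spec of the easing curve is genuinely open, and
linear interpolation with held coordinates is the simplest choice satisfying
both boundary contracts. An animated viewer would sample $t$; this package
renders any single frame.

### Recursive HSL coloring

The default coloring ties hue to lineage and quantity. The root's immediate
children divide the hue circle into *equal* contiguous ranges in sorted
order; every deeper node subdivides its own range among its children
*weighted by subtree magnitude*. Each node takes the minimum of its range as
its hue, so the largest child of every generation inherits its parent's hue
exactly — dominant lineages read as one consistent color from center to rim.
Lightness increases linearly from 0.45 at the root to 0.80 at the deepest
visible ring to separate generations; saturation is constant at 0.70.

Two deliberate choices at the edges: whether the *root* level splits equally
or by magnitude is ambiguous; the equal split is used so small top-level
groups stay chromatically distinguishable, and the asymmetry (equal at the
root, weighted below) is intentional. Zero-magnitude children get zero-width
ranges — except when an entire sibling family is zero, where the range is
split equally so sibling ranges always partition the parent's range (the
invariant the tests verify against an independent iterative recomputation).

For secondary quantities (classifier confidence, average log e-value,
percent identity) a gradient colors each node by its subtree-pooled
aggregate, linearly interpolated per RGB channel between two end colors with
clamping at the domain ends. Confidence uses low = red, high = green; log
e-value reverses the ends (the most negative exponent is the most
significant hit, so it is colored green).

## File formats

* **BLAST tabular** — the standard 12-column tab-separated dialect; `#`
  comments ignored; errors report line numbers.
* **Generic lineage text** — magnitude, then one column per lineage level,
  root-first.
* **RDP-style** — query id then (name, rank, confidence) triplets;
  confidences must be in [0, 1].
* **PhymmBL-style** — a header of `<rank>`, `<rank>_conf` column pairs;
  a read's lineage truncates at its first unnamed rank. Per-rank confidences
  aggregate at every named node of the lineage, weighted by the read's
  magnitude.
* **ACE** — only `CO <name> <bases> <nreads>` headers are read, mapping each
  contig to its read count; a disagreeing `AS` total is a warning, not an
  error.
* **NCBI taxonomy dumps** — `nodes.dmp`/`names.dmp` (fields separated by
  `"\t|\t"`); scientific names are required for every id, the parent map must
  be acyclic with a single self-parent root.
* **Chart XML** — a self-defined, versioned schema (documented at the top of
  `R/chart-xml.R`): nested `<node>` elements carry name/rank/taxon id,
  per-dataset magnitudes, collapsed lineages and attribute aggregates.
  Numbers serialize as `%.17g`, so write∘read is the identity on the full
  model (property-tested on randomized charts). Text attributes are opaque
  payloads and may carry HTML or hyperlinks verbatim.

## Synthetic data

Every input the package reads can be generated offline, so the whole
pipeline is testable without downloads:

* `make_toy_taxonomy()` grows a random acyclic taxonomy (uniform attachment
  capped at a branching factor, ranks cycling through the standard ladder)
  and writes dump files the loader verifies on the way back in.
* `make_synthetic_hits()` writes BLAST tabular files with *known answers*: a
  tie-free query's best hit points at its true leaf; a tie query hits two
  sibling leaves with exactly equal bit scores so the correct assignment is
  their parent. Decoys score strictly lower. E-values are log-uniform on
  [1e-50, 1e-3] and identities uniform on [70, 100] — ranges typical of
  reported metagenomic BLAST screens. A ground-truth sidecar accompanies
  every file.
* `make_skewed_profile()` writes a lineage file that reproduces requested
  top-level fractions exactly (e.g. 0.8/0.1 gives 288° and 36° wedges),
  with the remainder assigned to the root.

What the generators deliberately do *not* emulate: sequencing error,
database incompleteness, chimeric alignments, or realistic community
structure. Passing tests therefore demonstrate that the bookkeeping —
LCA logic, conservation, layout, color, serialization — is exact, not that
classifications of real reads are accurate; accuracy belongs to the
upstream classifier, which this package only visualizes.

## Numerical choices and degenerate inputs

* Conservation assertions use exact equality for integer magnitudes and
  1e-9 (relative, or degrees) for reals.
* An all-zero chart cannot be laid out (`compute_angles()` errors rather
  than emitting NaN geometry).
* Sorting ties break lexicographically, case-insensitively — deterministic
  output across runs and platforms.
* A full-circle sector is drawn as two half-arcs, since a single 360° SVG
  arc degenerates.
* SVG coordinates are formatted to fixed precision (`%.4f`), making renders
  byte-identical for identical inputs.
* Gradient domains may be fixed (confidence: [0, 1]) or resolved from the
  data; a degenerate domain maps everything to the low color with a warning.

Problem sizes in the test suite (up to 500-node random trees, a 200-node toy
taxonomy, 1000 random hit sets, 100 round-trip charts) were chosen as the
smallest sizes at which every code path — ties, zero-magnitude families,
unary chains, multi-dataset vectors — is exercised many times per run.

## Limitations

* The package renders static documents (SVG and a self-contained HTML
  wrapper embedding the chart XML); it is not an interactive viewer. Any
  zoom frame can be rendered, but animation and mouse-driven exploration
  are out of scope.
* Depth summarization is numeric only; "summarize at rank X" is not
  implemented (ranks are carried through and displayed, not used for
  pruning).
* Label geometry uses a width heuristic, not font metrics; labels are
  conservative (never overlapping, sometimes shorter than strictly
  necessary).
* Taxonomy lookups are linear-scan (`match`) — fine for the bundled toy
  taxonomies and for subsets, but indexing the full NCBI dump would benefit
  from an environment-based hash, which the `taxonomy_db` structure leaves
  room for.
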