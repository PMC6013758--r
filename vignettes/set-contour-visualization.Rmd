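---
title: "Set-contour visualization of small annotated networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Set-contour visualization of small annotated networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contourgraph)
```

## The problem

A common end point of network biology pipelines is a *small* annotated
graph: a subnetwork module of a few dozen genes extracted from a large
interaction network, whose nodes are annotated with the enriched gene sets
(GO terms, pathways) they belong to. The same shape of data appears outside
biology — for instance a small social network with overlapping community
assignments. The visualization task is to show the graph structure and the
set structure *together*: a node-link layout in which each selected set is
drawn as one translucent rounded region that encompasses and connects its
members, overlapping freely with the regions of other sets.

`contourgraph` implements that rendering pipeline as composable R
functions plus a scriptable command layer, so figures can be regenerated
deterministically from plain-text inputs.

## Layout model

**Target distances.** The layout aims to reproduce graph-theoretic
distances: `graph_distances()` computes all-pairs shortest paths over
unit-weight edges. Node pairs in different components receive a surrogate
distance of 1.5× the finite diameter — large enough to keep components
visually separate, small enough to keep them on the same canvas. All
distances are finite by construction.

**Stress.** Given targets $d_{uv}$ and positions $p$, the objective is

$$S(p) = \sum_{u<v} w_{uv}\,\bigl(\lVert p_u-p_v\rVert - d_{uv}\bigr)^2,
  \qquad w_{uv} = d_{uv}^{\,q},\ q=-2 .$$

The exponent $q=-2$ (tunable via `layout_params(weight_exponent=)`)
normalizes each pair's contribution by its squared target distance, so
local structure is reproduced faithfully while long-range error is
tolerated — the standard choice for distance-based graph layout.

**Majorization.** `compute_layout()` minimizes $S$ by localized (per-node,
Gauss–Seidel) majorization: each node in turn moves to the minimizer of the
standard majorizing quadratic given all other positions. Each such move can
only lower the stress, which gives the suite's monotonicity guarantee
(asserted on the recorded `stress_trace` of every test layout). Iteration
stops when the relative stress change drops below `tol` ($10^{-6}$) or
after `max_iter` (300) rounds. The initial placement is uniform random in a
$\sqrt{n}$-side square under the user's seed; identical inputs and seed give
bit-identical layouts.

**Set attraction.** For every *selected* group, a spanning graph is built:
the minimum spanning tree of the complete graph on the group's members,
weighted by the base graph distances (`spanning_graph()`, Kruskal with a
lexicographic tie-break so the tree is unique and deterministic; a Steiner
variant routing through non-members was considered and rejected to keep
member sets self-contained). The tree's links are injected as extra
weighted links — a link of base distance $d$ enters with weight
$\alpha\,d$, $\alpha = 0.7$ — and distances are recomputed over the
augmented graph. Because $\alpha < 1$ strictly shortens member–member
paths, selecting a group can only pull its members closer in the target
metric; the test suite checks the realized effect across seeded runs and
requires it in at least 4 of 5.

**Scale and glyphs.** Hop distances are mapped to drawing units by
`edge_length` (100 units per hop), chosen so that two adjacent short-label
glyphs — a glyph is a rectangle of width $7\cdot\mathrm{nchar}+10$ and
height 18, a monospace approximation — fit between neighboring nodes
without immediate overlap.

**Overlap removal.** After stress minimization, `remove_overlaps()`
displaces glyphs pairwise: any two rectangles closer than the sum of their
half-extents plus a `padding` of 2 units (per axis) are pushed apart along
the line through their centers, each moving half the required distance;
coincident centers separate along x. Sweeps over all pairs repeat until no
overlap remains or `max_sweeps` (200) is reached, in which case the layout
is returned with its `converged` flag unset and a warning — in practice the
desk-scale graphs in scope converge in a handful of sweeps, verified by an
exhaustive rectangle-pair check on every test layout.

## Contour geometry

The contour of a selected group is the outline of the union of

* a disc of radius $r + c_i$ at each member $i$, where $r$ is the contour
  radius (default 14 units) and $c_i$ the member glyph's circumradius, and
* a band of half-width $r$ with rounded ends along each spanning link.

`contour_shape()` extracts that outline as the zero level set of the
union's exact signed distance field, sampled on a regular grid of step
$r/10$ and traced with `grDevices::contourLines()`. This representation
unions overlapping primitives for free, produces the rounded joins the
style calls for, and yields far more than the minimum 16 segments per full
circle; on closed-form cases the enclosed area is within a fraction of a
percent of $\pi(r+c)^2$ (single member) and $2rL + \pi r^2$ (two members at
distance $L$), both asserted at a 1% tolerance. A spanning *tree* yields
one closed boundary component; the code nevertheless keeps every traced
ring (even-odd rule), so incidental holes render correctly. Degenerate
geometry (no traceable outline) is an error.

Member centers are strictly inside their contour by construction (the field
is positive there); the suite re-checks this with an independent
point-in-polygon oracle on every rendered scene. Non-member *exclusion* is
best effort only: the layout pulls members together, and only nodes farther
than $r$ plus their circumradius from every member disc and link band are
asserted to lie outside. Overlapping contours are alpha-blended (fill
opacity 0.25) with no contour-contour avoidance.

**Scene order and color.** `build_scene()` stacks contours largest member
count first, so small sets paint above large ones and stay visible; then
edges, node glyphs with labels, and group labels. Colors come from a fixed
12-hue qualitative palette indexed by *selection order*, making color
assignment reproducible across runs. Each group's label (with its
enrichment score at 2 significant digits when `showScore` is on) is placed
at the boundary point farthest from the graph centroid, which keeps labels
on the outside of the drawing.

## Command layer

The command layer mirrors the automation vocabulary of set-visualization
tools: `network import`, `network select`, `table import`,
`examine generate groups` / `select groups` / `remove groups` /
`update settings` / `export` / `interact`. Decisions worth recording:

* Both `selectedGroup` and `selectedGroups` are accepted for group
  selection, since published workflows use either spelling.
* `table import` carries no node-vs-group flag; an imported table is routed
  to group annotation when its keys match existing group ids at least as
  well as node ids, else to the node table. Group labels come from a
  `Label`-like column, scores from the settings' score column.
* `update settings` treats `selectedGroupColumns` as a display filter; a
  named column that generated no groups raises a warning rather than an
  error (workflows occasionally name a superset of columns).
* Commands are atomic — any error returns the untouched pre-command
  session — and `interact` emits the scene to a debug SVG, since
  interactive windows are out of scope (as is any HTTP/REST transport; the
  script runner and CLI replace them).
* Script files use one command per line
  (`namespace command key=value ...`) or a JSON array; relative input paths
  resolve against the script's own directory, so bundled workflows replay
  from anywhere. The session's layout cache is invalidated by any mutation
  and reused across repeated exports.

## Synthetic fixtures

`generate_annotated_graph()` emulates the package's target inputs: a
connected sparse graph (random spanning tree plus extra edges, by
probability or exact count), groups planted as connected patches
(round-robin breadth-first claiming from random seeds), a requested
fraction of nodes upgraded to multi-group membership by joining an
adjacent second group (which preserves per-group connectivity), a planted
connected `Module = "small"` patch emulating an upstream module-extraction
result, and typed annotation columns in the `s/f/sl` dialect — either a
minimal table or a 12-column `s,s,f,f,f,s,s,s,sl,sl,sl,sl` layout shaped
like an enriched-module annotation export.

The two bundled fixtures under `inst/extdata/` are seed-pinned outputs of
this generator, *synthetic stand-ins* with the same shape as the reference
workflow data: a 40-node network whose planted module selects 17 nodes
spanning 18 induced edges with pathway/function groups, and a 34-node,
78-edge graph with six overlapping communities. What the generator does
*not* emulate: realistic degree distributions, actual enrichment
statistics, or biologically meaningful set structure — so green tests
demonstrate the geometric and procedural guarantees on realistic *shapes*,
not statistical properties of real interaction networks.

Test and acceptance runs use desk-scale problems — 12–40 nodes, up to 50
seeded replicates per property — matching the tool's intended scope of
small, relatively sparse networks.

## Parameters at a glance

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 0.7 | — | spanning-link attraction factor (< 1 pulls members together) |
| `edge_length` | 100 | layout units/hop | drawing scale relative to glyph sizes |
| `weight_exponent` | −2 | — | stress weight exponent $w = d^q$ |
| `max_iter` / `tol` | 300 / 1e−6 | — | majorization stopping rule |
| `padding` | 2 | layout units | minimum gap between glyph rectangles |
| `max_sweeps` | 200 | — | overlap-removal cap |
| `radius` | 14 | layout units | contour radius around glyphs and links |
| grid step | `radius/10` | layout units | contour sampling resolution |

## Known limitations

* Intended for small, sparse graphs; the all-pairs distance matrix and the
  per-pair overlap sweeps scale quadratically, and the visual idiom itself
  stops working beyond a few dozen nodes or sets.
* One network per session; multigraphs, edge attributes and nested groups
  are out of scope.
* Contours do not avoid one another (translucent overlap is the intended
  reading), group-label placement does not avoid collisions, and
  non-member exclusion from a contour is not guaranteed.
* The overlap-removal heuristic minimizes displacement only locally; it is
  deterministic but not optimal.
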