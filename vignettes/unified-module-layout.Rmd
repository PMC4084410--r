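---
title: "Unified SOM layout of annotated network modules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unified SOM layout of annotated network modules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Integrative network analysis produces *annotated modules*: small subnetworks
(dozens of genes and interactions) together with a system of enriched
annotation sets — pathways, processes, functions — that overlap freely, vary
in cardinality from one gene to the whole module, and typically outnumber
the interactions. Conveying such a module requires laying out the network
*and* the set system together: laying out the graph first and painting set
hulls on top emphasizes topology at the expense of the sets, and vice
versa.

somset treats both kinds of relations as the same mathematical object. A
module is a hypergraph whose binary edges are the interactions and whose
n-ary edges are the active annotation sets. Every node $t$ receives a
membership vector $t = (t_1, \dots, t_M)$ over the $M$ = (interactions +
active sets) components, with $t_i = w_i$ if the node belongs to component
$i$ and $0$ otherwise. Interactions always carry weight 1; a set's
*dominance weight* $w_i$ (default 1) scales its component, so raising it
makes the set matter more in every distance computation. Component order is
fixed — interactions in input order, then active sets in selection order —
because everything downstream must be reproducible from the inputs alone.

## Reservation-based SOM

The layout is a self-organizing map on an $N \times N$ grid of
$M$-dimensional neurons, with one twist: within each training epoch every
item must claim a *unique* neuron ("reservation"), because each gene needs
its own tile in the figure. Each epoch:

1. reservations are cleared and items are visited in a freshly shuffled
   order (the shuffle consumes the run's seeded RNG);
2. each item reserves the unreserved neuron minimizing the metric cosine
   distance $d(q,p) = \arccos\!\big(q \cdot p / (|q||p|)\big)/\pi$;
3. all neurons within Chebyshev radius $r_i$ of the reserved cell — whether
   reserved or not — are pulled toward the item by the convex rule
   $q \leftarrow q + \alpha_i (t - q)$.

Both schedules anneal linearly: $\alpha_i = c\,(1 - i/I)$ and
$r_i = \lfloor (1 - i/I)\, N \rfloor$, over $I = \lceil 10^6/|T| \rceil$
epochs by default. The long, gradual schedule is not a luxury: the
coalescing of a dominance-weighted set's members is driven by thousands of
near-tied reservation contests, and our test suite shows the effect
reliably only from a few tens of thousands of epochs upward (unit tests
that only need structural properties — injectivity, determinism — use
$I = 2000$).

Degenerate vectors get the conventions $d(0,0)=0$ and $d(0,p\neq0)=1$.
Since all membership components are non-negative, minimizing $d$ equals
maximizing $(q \cdot t)^2/|q|^2$, which is how the compiled trainer
actually scans (no `acos`, no `sqrt`, division-free comparisons).

### Grid size

The natural reading of "N = 2|T| neurons" conflicts with $N$ being the side
of an $N \times N$ grid; we side with the spacious layouts the method is
known for and use side $N = \min(2|T|, 64)$ by default (the cap keeps
training cost bounded; `grid_policy = "cells"` selects the alternative
reading of roughly $2|T|$ cells in total).

### Initialization

Component $i$ of every neuron starts uniform on $[0, w_i]$, drawn component
by component. A component with *empty support* (an active set with no
members) starts at exactly 0 and consumes no random draws. This is not
cosmetic: noise in a dead component inflates $|q|$ and perturbs every
cosine distance, whereas a silent component provably changes nothing — so
appending an empty set to a module leaves the layout bit-for-bit identical
under the same seed, a property the test suite asserts.

### Tie-breaking and layout preservation

Trained fields contain mathematically exact plateaus: a neuron updated
purely toward one item is exactly parallel to it, so whole regions tie at
distance 0. Ties are broken toward the smallest row-major cell index, with
one addition: an item whose *standing position* (the reservation carried in
from a previous layout) ties the scan's best — within a relative hysteresis
margin of $10^{-12}$, since plateau similarities agree only to the last few
ulps — keeps its cell. The margin is far above rounding noise and far below
any meaningful similarity difference.

A *warm start* re-trains from the previous neuron field so that toggling a
set changes the layout as little as possible. Warm runs use strength
$c = 0.01$ and resume the annealing roughly where a cold run would stand
once its strength has decayed that far: the neighborhood radius restarts at
$\max(1, \lfloor N \cdot 0.01/0.5 \rfloor)$ rather than at $N$. Restarting
the radius at $N$ would have every item sweep (almost) the whole grid every
epoch; the per-epoch sweeps compose into a contraction that provably
flattens the field — and with it the layout being preserved — even at
$\alpha = 0.01$. Across a dimension change, surviving components keep their
trained values, removed ones are dropped, and new components start at 0
(a zero component rescales all cosines uniformly, so every item's
best-match ranking is initially unchanged, and the new set's field then
grows exactly around its members). With these choices, re-running an
unchanged module from its own final grid reproduces the layout exactly in
our tests, and adding a small set relocates few or no nodes.

```{r}
library(somset)
m <- example_module()
fit <- rsom_train(encode(m), seed = 1)          # cold start
m2 <- set_active(m, c(m$active))                # ... user toggles sets ...
fit2 <- rsom_train(encode(m2), grid = fit$grid, seed = 2)  # warm start
```

## Contours

For active set $S_i$, the $i$-th components of all neurons form a scalar
field — a fuzzy membership landscape. The contour body starts as the union
of grid tiles whose field value reaches $\tau \cdot w_i$ ($\tau = 1/2$ by
default; the threshold scales with the dominance weight, otherwise a
weighted set would trivially exceed a fixed ½ everywhere). Two hard edits
turn this into a guarantee rather than a hope: reserved cells of member
nodes are force-included and reserved cells of non-members force-excluded,
so *a placed node's tile is in the body exactly when the node is in the
set*.

The tile outline is then refined:

* **tighten** — one pass of corner cutting: every convex right-angle corner
  is replaced by the chord between the midpoints of its incident edges
  (at most half a tile from the corner), provided the cut-off triangle
  intersects no cell holding a placed item. Area never increases and no
  item's cell center changes side.
* **smooth** — dilation by $r$, erosion by $2r$, dilation by $r$ (a
  morphological closing followed by an opening with a disc of radius $r$),
  realized as round-joined polygon offsets. Opening a unit tile yields the
  closed-form area $1 - (4-\pi)r^2$, which the tests check to $10^{-3}$,
  as they do the Steiner formula for convex dilation.
* **nest and ribbon** — sets are ranked by descending body area (ties by
  input order; for truly nested sets the subset can never out-rank its
  superset) and the rank-$k$ body is eroded by $k\,\delta$, keeping nested
  outlines visibly separated. Each body is finally eroded by the ribbon
  width $e$ and the difference is the opaque ribbon that gets painted;
  drawing order is largest first.

All lengths live in tile units: $r = 0.15$, $\delta = 0.05$, $e = 0.12$,
arc tolerance $10^{-3}$ (area). The invariant $r + k_{\max}\delta + e <
1/2$ guarantees a member's cell center survives every erosion; when many
active sets would violate it, $\delta$ is shrunk automatically (with a
warning) instead of erroring, since the number of active sets is user data.
Under these bounds the containment guarantee also covers non-members: a
fully excluded cell keeps its center at distance $\ge 1/2 - r > r$ from the
body, so the closing step cannot recapture it.

## Rendering

The figure is a static SVG with two panes: a set overview (sets grouped by
category, sorted by ascending enrichment p-value, each with a circle scaled
by $-\log_{10} p$ and its scientific exponent as text) and the network
pane. Painting order is: opaque ribbons (largest set first), link halos,
quadratic link curves, dashed contour outlines (so occluded sections remain
inferable), then node labels on white boxes whose border color encodes the
differential-expression score (green under, red over). Ribbon colors cycle
through a qualitative Color-Brewer-derived palette; text and outlines are
dark gray (#404040) rather than black. Coordinates are written at a fixed
three decimals and nothing machine- or time-dependent enters the document,
so identical inputs give byte-identical files.

## Synthetic modules

`generate_module()` emulates the data characteristics the method targets:
a small, sparse, connected interaction network (random spanning tree plus
extra random edges; defaults 17 nodes, 20 edges); many annotation sets
(default 25, outnumbering the interactions); cardinalities spanning one
node to the whole module; and frequent overlap — sets draw their members
from a shared pool whose size shrinks as `overlap` grows, so the expected
pairwise Jaccard index rises monotonically with it (checked over seeds in
the tests). Enrichment p-values are log-uniform on $[10^{-8}, 10^{-2}]$
and expression scores standard normal.

What it does *not* emulate: real degree distributions (no hubs), ontology
structure among sets (no parent–child nesting beyond what overlap produces
by chance), correlation between a set's size and its significance, and any
biological signal linking expression scores to topology. Passing tests on
these modules therefore certify the layout/geometry machinery, not
biological interpretability of any particular dataset.

Problem sizes used by the test suite are the package's own choice: property
sweeps use modules of 4–40 nodes centered on the dozens-of-genes regime the
method targets, with reduced schedules ($I = 2000$) where only structural
properties are asserted, $I = 40000$ for the dominance effect, and the full
$I = \lceil 10^6/17 \rceil$ for the end-to-end run at the published module
scale.

## Known limitations

* The layout optimizes distance structure, not aesthetics: unnecessary
  link or contour crossings can occur, and no global optimization of
  contour complexity is attempted.
* Scalability is bounded by design: beyond roughly a hundred nodes or a
  few dozen simultaneously active sets, tile-based contours stop being
  legible, and training cost grows with the grid.
* Contours of a weighted set use the scaled threshold $\tau w_i$; a set
  whose weight is 0 has an empty field and contributes only its members'
  force-included tiles.
* The warm-start schedule preserves layouts at the cost of adaptation: a
  newly added large, dominant set may need a cold re-layout to express its
  structure fully.
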