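# somset

Unified self-organizing-map layout of set-annotated network modules.

Integrative network analysis ends with an *annotated module*: a small
subnetwork of genes and interactions plus a system of enriched annotation
sets (pathways, GO terms) that overlap freely and usually outnumber the
interactions. somset lays such a module out so that network topology and
set structure shape the picture *together*, and renders it as an
Euler-diagram-over-node-link figure: opaque set ribbons, curved links with
halos, expression-colored labels, and a significance overview pane.

## The method in brief

Every node $t$ gets a membership vector $t = (t_1,\dots,t_M)$ over the
$M$ = interactions + active sets components, $t_i = w_i$ if the node
belongs to component $i$ (interactions have weight 1, sets a tunable
dominance weight). A reservation-based self-organizing map (RSOM) embeds
the nodes into an $N\times N$ grid ($N = \min(2|T|, 64)$): per epoch,
items in seeded-random order each claim the *unreserved* neuron minimizing
the metric cosine distance $d(q,p)=\arccos(q\cdot p/(|q||p|))/\pi$, then
train their Chebyshev neighborhood by $q \leftarrow q + \alpha_i(t-q)$,
with $\alpha_i = c(1-i/I)$, $r_i = \lfloor(1-i/I)N\rfloor$, and
$I = \lceil 10^6/|T|\rceil$. The uniqueness of reservations makes similar
genes "trickle outwards" into adjacent cells instead of stacking.

Each active set's contour is carved from the trained neuron field: tiles
whose $i$-th component reaches $\tau w_i$ form the body (member tiles
force-included, non-member tiles force-excluded, so containment in the
drawn contour is *equivalent* to set membership), corners are tightened
across item-free tiles, the shape is smoothed morphologically (dilate $r$,
erode $2r$, dilate $r$), and overlapping sets are nested by area rank with
per-rank erosion; the painted ribbon is the body minus its erosion by the
ribbon width. Warm starts re-train from the previous neuron field at
$c=0.01$ so toggling a set preserves the mental map.

## Worked example

The packaged six-gene module (Calm1, Calm2, Calm3, Kras, Nr3c2, Plcb4;
seven interactions; the Glioma, Long-term potentiation and GnRH signaling
pathway sets, all active — also shipped as flat files under
`inst/extdata/`):

```r
library(somset)
mod <- example_module(p_values = c(glioma = 5.6e-6, ltp = 1.0e-6, gnrh = 2.3e-4))
mod
#> annotated module: 6 nodes, 7 interactions, 3 sets (3 active)

mat <- encode(mod)
mat["Nr3c2", ]
#>  Calm1--Kras Calm1--Plcb4  Calm2--Kras Calm2--Plcb4  Calm3--Kras Calm3--Plcb4
#>            0            0            0            0            0            0
#>  Kras--Nr3c2       glioma          ltp         gnrh
#>            1            0            0            0
cosine_distance(mat["Nr3c2", ], mat["Plcb4", ])
#> [1] 0.5
```

Nr3c2 participates in one interaction and no pathway; its vector is
orthogonal to Plcb4's, so their distance is exactly ½ — maximally
dissimilar among non-opposing profiles. The full pipeline:

```r
out <- run_module(mod, run_config(seed = 42), out_svg = "module.svg")
#> training: 6 items, M = 10, grid 12x12, I = 166667, c = 0.5 (cold start)
#> training took 4.04 s
out$layout
#> module layout on a 12x12 grid
#>      id x y
#> 1 Calm1 8 0
#> 2 Calm2 4 0
#> 3 Calm3 2 0
#> 4  Kras 2 5
#> 5 Nr3c2 0 3
#> 6 Plcb4 0 0
```

Each gene occupies its own grid cell; the three calmodulins sit in one
row (they have identical interaction patterns and pathway memberships up
to edge identity), Kras bridges them to Nr3c2, and the contours are drawn
largest set first so the small Glioma contour is never hidden. `module.svg`
contains the two-pane figure; `run_module()` can also emit a layout JSON
that `render_from_json()` turns back into the byte-identical SVG.

## Command line

```sh
Rscript inst/cli/somset.R fixture  --out-prefix fix
Rscript inst/cli/somset.R simulate --n-nodes 17 --n-edges 20 --n-sets 25 --seed 1 --out-prefix sim
Rscript inst/cli/somset.R layout   --nodes fix_nodes.tsv --edges fix_edges.sif \
        --sets fix_sets.gmt --set-meta fix_set_meta.tsv --seed 3 --out fix.json --svg fix.svg
Rscript inst/cli/somset.R render   --json fix.json --svg fig.svg
```

Inputs are standard flat formats: TSV node tables, SIF or two-column TSV
interaction lists, GMT (or long-format TSV) set memberships, and a TSV of
set metadata (category, p-value).

## Documentation

`vignettes/unified-module-layout.Rmd` describes the model, every tunable
parameter with its default and units, the numerical design choices
(tie-breaking, warm-start schedule, geometric tolerances), what the
synthetic-module generator does and does not emulate, and known
limitations.
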