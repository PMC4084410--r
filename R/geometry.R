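# Polygon sets ("polysets") are lists of rings, each list(x, y), with
# nonzero-winding semantics: outer rings counter-clockwise, holes clockwise.
# All boolean and offset operations go through polyclip (Clipper); this file
# owns the contour pipeline built on top of them.

ps_empty <- function() list()

ps_is_empty <- function(ps) length(ps) == 0L

ring_area <- function(r) {
  x <- r$x; y <- r$y
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Area of a polygon set
#'
#' Signed ring areas are summed, so holes subtract from their outer ring.
#'
#' @param ps Polygon set (list of rings with `x`, `y`).
#' @return Total enclosed area.
#' @export
ps_area <- function(ps) {
  if (ps_is_empty(ps)) return(0)
  sum(vapply(ps, ring_area, 0))
}

ps_op <- function(A, B, op) {
  if (op == "union") {
    if (ps_is_empty(A)) return(B)
    if (ps_is_empty(B)) return(A)
  } else if (op == "intersection") {
    if (ps_is_empty(A) || ps_is_empty(B)) return(ps_empty())
  } else if (op == "minus") {
    if (ps_is_empty(A)) return(ps_empty())
    if (ps_is_empty(B)) return(A)
  }
  polyclip::polyclip(A, B, op = op, fillA = "nonzero", fillB = "nonzero")
}

#' @rdname ps_area
#' @param A,B Polygon sets.
#' @export
ps_union <- function(A, B) ps_op(A, B, "union")

#' @rdname ps_area
#' @export
ps_intersect <- function(A, B) ps_op(A, B, "intersection")

#' @rdname ps_area
#' @export
ps_difference <- function(A, B) ps_op(A, B, "minus")

#' Morphological dilation and erosion of a polygon set
#'
#' Minkowski sum (`delta > 0`) or subtraction (`delta < 0`) with a disc of
#' radius `|delta|`, realized as a round-joined polygon offset. Circular
#' arcs are approximated by polygons to within `arctol` (a distance).
#'
#' @param ps Polygon set.
#' @param delta Offset radius; negative erodes.
#' @param arctol Maximum distance between the true arc and its polygonal
#'   approximation.
#' @return The offset polygon set (possibly empty after erosion).
#' @export
ps_offset <- function(ps, delta, arctol = abs(delta) / 1500) {
  if (ps_is_empty(ps) || delta == 0) return(ps)
  out <- polyclip::polyoffset(ps, delta, jointype = "round", arctol = arctol)
  if (is.null(out)) ps_empty() else out
}

#' Point-in-polyset test
#'
#' @param ps Polygon set whose rings come from Clipper output (mutually
#'   non-crossing), so even-odd counting over rings is exact; points on a
#'   ring boundary count as inside.
#' @param x,y Point coordinate vectors.
#' @return Logical vector.
#' @export
ps_contains <- function(ps, x, y) {
  if (ps_is_empty(ps)) return(rep(FALSE, length(x)))
  P <- list(x = x, y = y)
  counts <- rep(0L, length(x))
  boundary <- rep(FALSE, length(x))
  for (r in ps) {
    res <- polyclip::pointinpolygon(P, r)
    counts <- counts + as.integer(res == 1)
    boundary <- boundary | res == -1
  }
  (counts %% 2L == 1L) | boundary
}

#' Geometry parameters for contour construction
#'
#' All lengths are in canvas units; the grid tile is `tile` units across.
#' The bound `r + depth_max * delta + e < tile / 2` guarantees that a member
#' node's cell center can never be eroded out of its set's ribbon, which is
#' what makes containment of an item in a contour equivalent to set
#' membership.
#'
#' @param tile Canvas units per grid cell.
#' @param tau Threshold fraction of the set weight at which a tile joins the
#'   contour body.
#' @param r Smoothing (dilation/erosion) radius.
#' @param delta Per-nesting-level extra erosion, separating outlines of
#'   nested contours.
#' @param e Ribbon width (erosion cut out of the body).
#' @param arc_tol Acceptable area error when approximating circular arcs by
#'   polygons; also the comparison tolerance used in the package's tests.
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(tile = 1, tau = 0.5, r = 0.15 * tile,
                            delta = 0.05 * tile, e = 0.12 * tile,
                            arc_tol = 1e-3 * tile^2) {
  stopifnot(tile > 0, tau > 0, tau <= 1, r > 0, delta > 0, e > 0,
            arc_tol > 0)
  if (r + e >= 0.5 * tile) {
    stop("r + e must stay below half a tile to preserve the membership ",
         "containment guarantee", call. = FALSE)
  }
  structure(list(tile = tile, tau = tau, r = r, delta = delta, e = e,
                 arc_tol = arc_tol),
            class = "geometry_params")
}

#' Extract the scalar field of one membership component
#'
#' The i-th components of all neurons form a fuzzy membership landscape for
#' component i over the grid; the contour of an active set is carved out of
#' this field.
#'
#' @param grid A trained `neuron_grid`.
#' @param component_index 1-based component (column) index.
#' @return N x N numeric matrix `F` with `F[x + 1, y + 1]` the value at cell
#'   (x, y); carries the component weight as attribute `weight`.
#' @export
scalar_field <- function(grid, component_index) {
  stopifnot(inherits(grid, "neuron_grid"))
  i <- as.integer(component_index)
  if (i < 1L || i > grid$M) {
    stop("component index ", i, " out of range [1, ", grid$M, "]",
         call. = FALSE)
  }
  F <- matrix(grid$values[, i], nrow = grid$side)
  attr(F, "weight") <- grid$weights[i]
  F
}

#' Threshold a scalar field into a tile body
#'
#' A cell joins the body when its field value reaches `tau * w` (the
#' threshold scales with the set's dominance weight). Reserved cells of
#' member nodes are then force-included and reserved cells of non-member
#' nodes force-excluded, turning the training-dependent landscape into a
#' hard guarantee: a placed node's tile is in the body exactly when the node
#' is in the set.
#'
#' @param field Matrix from [scalar_field()].
#' @param layout A `module_layout`.
#' @param set_members Character vector of member node ids.
#' @param params [geometry_params()].
#' @return Data frame of 0-based cell coordinates `x`, `y`.
#' @export
tile_body <- function(field, layout, set_members, params = geometry_params()) {
  N <- nrow(field)
  w <- attr(field, "weight")
  if (is.null(w)) w <- 1
  if (w > 0) {
    hit <- which(field >= params$tau * w, arr.ind = TRUE)
    cells <- data.frame(x = hit[, 1L] - 1L, y = hit[, 2L] - 1L)
  } else {
    cells <- data.frame(x = integer(), y = integer())
  }
  placed_in <- layout$id %in% set_members
  cells <- rbind(cells, data.frame(x = layout$x[placed_in],
                                   y = layout$y[placed_in]))
  key <- cells$x + N * cells$y
  cells <- cells[!duplicated(key), , drop = FALSE]
  out_key <- layout$x[!placed_in] + N * layout$y[!placed_in]
  cells <- cells[!(cells$x + N * cells$y) %in% out_key, , drop = FALSE]
  rownames(cells) <- NULL
  cells
}

#' Merge grid cells into polygons
#'
#' Each cell (x, y) becomes the axis-aligned square
#' \[x tile, (x+1) tile\] x \[y tile, (y+1) tile\]; the union is returned as
#' simple polygons with holes. Its area is exactly the cell count times the
#' tile area.
#'
#' @param cells Data frame of 0-based cell coordinates `x`, `y`.
#' @param params [geometry_params()].
#' @return Polygon set.
#' @export
tiles_to_polygon <- function(cells, params = geometry_params()) {
  if (NROW(cells) == 0L) return(ps_empty())
  tile <- params$tile
  # merge each row of cells into horizontal runs, then union the rectangles
  rects <- list()
  for (yy in sort(unique(cells$y))) {
    xs <- sort(cells$x[cells$y == yy])
    run_start <- xs[c(TRUE, diff(xs) != 1L)]
    run_end <- xs[c(diff(xs) != 1L, TRUE)]
    for (k in seq_along(run_start)) {
      x0 <- run_start[k] * tile; x1 <- (run_end[k] + 1) * tile
      y0 <- yy * tile; y1 <- (yy + 1) * tile
      rects[[length(rects) + 1L]] <- list(x = c(x0, x1, x1, x0),
                                          y = c(y0, y0, y1, y1))
    }
  }
  out <- rects[1L]
  if (length(rects) > 1L) {
    out <- polyclip::polyclip(rects, rects[[1L]], op = "union",
                              fillA = "positive", fillB = "positive")
    # dissolve rings that touch along an edge into one simple boundary
    out <- polyclip::polysimplify(out, filltype = "nonzero")
  }
  out
}

# Cells (0-based x,y) of the tiles occupied by placed items, as squares.
item_cell_squares <- function(layout, params) {
  tile <- params$tile
  lapply(seq_len(NROW(layout)), function(i) {
    x0 <- layout$x[i] * tile; y0 <- layout$y[i] * tile
    list(x = c(x0, x0 + tile, x0 + tile, x0),
         y = c(y0, y0, y0 + tile, y0 + tile))
  })
}

#' Cut staircase corners that shortcut across item-free space
#'
#' One pass of corner cutting over a tile-union polygon: every convex
#' right-angle corner is replaced by the chord between the midpoints of its
#' two incident edges (at most half a tile from the corner), provided the
#' cut-off triangle does not intersect any cell that holds a placed item.
#' Item cell centers therefore keep their in/out status, and the area never
#' increases.
#'
#' @param polygon Polygon set produced by [tiles_to_polygon()].
#' @param item_cells Data frame of 0-based cell coordinates `x`, `y` of all
#'   placed items (members and non-members alike).
#' @param params [geometry_params()].
#' @return The tightened polygon set.
#' @export
tighten <- function(polygon, item_cells, params = geometry_params()) {
  if (ps_is_empty(polygon)) return(polygon)
  tile <- params$tile
  half <- tile / 2
  squares <- item_cell_squares(item_cells, params)

  blocked <- function(tri) {
    for (sq in squares) {
      hit <- polyclip::polyclip(list(tri), sq, op = "intersection",
                                fillA = "nonzero", fillB = "nonzero")
      if (length(hit) && abs(ps_area(hit)) > 1e-9 * tile^2) return(TRUE)
    }
    FALSE
  }

  out <- lapply(polygon, function(ring) {
    n <- length(ring$x)
    if (n < 4) return(ring)
    orient <- sign(ring_area(ring))
    nx <- numeric(0); ny <- numeric(0)
    for (i in seq_len(n)) {
      ip <- if (i == 1L) n else i - 1L
      im <- if (i == n) 1L else i + 1L
      px <- ring$x[ip]; py <- ring$y[ip]
      vx <- ring$x[i];  vy <- ring$y[i]
      qx <- ring$x[im]; qy <- ring$y[im]
      cross <- (vx - px) * (qy - vy) - (vy - py) * (qx - vx)
      convex <- (cross * orient) > 0
      cut <- FALSE
      if (convex) {
        l1 <- min(half, sqrt((px - vx)^2 + (py - vy)^2) / 2)
        l2 <- min(half, sqrt((qx - vx)^2 + (qy - vy)^2) / 2)
        u1 <- c(px - vx, py - vy); u1 <- u1 / sqrt(sum(u1^2))
        u2 <- c(qx - vx, qy - vy); u2 <- u2 / sqrt(sum(u2^2))
        ax <- vx + u1[1L] * l1; ay <- vy + u1[2L] * l1
        bx <- vx + u2[1L] * l2; by <- vy + u2[2L] * l2
        tri <- list(x = c(ax, vx, bx), y = c(ay, vy, by))
        if (!blocked(tri)) {
          nx <- c(nx, ax, bx); ny <- c(ny, ay, by)
          cut <- TRUE
        }
      }
      if (!cut) {
        nx <- c(nx, vx); ny <- c(ny, vy)
      }
    }
    list(x = nx, y = ny)
  })
  out
}

#' Morphological smoothing of a contour body
#'
#' A dilation by `r`, erosion by `2r` and dilation by `r` — i.e. a
#' morphological closing followed by an opening, both with a disc of radius
#' `r` — rounds sharp corners with radius-`r` arcs while keeping the shape
#' within `r` of the original boundary.
#'
#' @param polygon Polygon set.
#' @param params [geometry_params()].
#' @return The smoothed polygon set (empty in, empty out).
#' @export
smooth_contour <- function(polygon, params = geometry_params()) {
  if (ps_is_empty(polygon)) return(polygon)
  r <- params$r
  arctol <- params$r / 1500
  ps_offset(ps_offset(ps_offset(polygon, r, arctol), -2 * r, arctol),
            r, arctol)
}

#' Nest contour bodies and carve their ribbons
#'
#' Active sets are ranked by descending body area (ties by input order) and
#' the rank-k body (k = 0 for the largest) is eroded by k * delta, so nested
#' or overlapping contours keep visibly distinct outlines. Each final body
#' is then eroded by the ribbon width `e` and the difference body \\ eroded
#' is the opaque ribbon that gets painted. Drawing order (z) follows the
#' rank: largest first, smallest last, so small sets are never hidden.
#'
#' @param bodies Named list of smoothed polygon sets, one per active set, in
#'   selection order.
#' @param params [geometry_params()].
#' @param layout Optional `module_layout` used to assert the containment
#'   guarantee.
#' @param members Optional named list of member-id vectors, parallel to
#'   `bodies`.
#' @return List of `set_contour` objects: `set_id`, `body`, `eroded`,
#'   `ribbon`, `z` (1 = drawn first) and `base_area` (the pre-erosion body
#'   area that determined the rank).
#' @export
nest_and_ribbon <- function(bodies, params = geometry_params(),
                            layout = NULL, members = NULL) {
  n <- length(bodies)
  if (n == 0L) return(list())
  ids <- names(bodies)
  if (is.null(ids)) ids <- paste0("set", seq_len(n))
  delta <- params$delta
  depth_max <- n - 1L
  budget <- 0.5 * params$tile - params$r - params$e
  if (depth_max > 0 && params$r + depth_max * delta + params$e >=
      0.5 * params$tile) {
    delta <- 0.9 * budget / depth_max
    warning("nesting step delta shrunk to ", signif(delta, 3),
            " to keep item centers inside all eroded bodies", call. = FALSE)
  }
  areas <- vapply(bodies, ps_area, 0)
  rank <- order(-areas)  # stable: ties keep input order
  contours <- vector("list", n)
  for (z in seq_len(n)) {
    j <- rank[z]
    body <- ps_offset(bodies[[j]], -(z - 1L) * delta)
    eroded <- ps_offset(body, -params$e)
    ribbon <- ps_difference(body, eroded)
    if (!is.null(layout) && !is.null(members)) {
      mem <- layout$id %in% members[[ids[j]]]
      if (any(mem)) {
        cx <- (layout$x[mem] + 0.5) * params$tile
        cy <- (layout$y[mem] + 0.5) * params$tile
        if (!all(ps_contains(body, cx, cy))) {
          stop("containment guarantee violated for set '", ids[j],
               "': a member center left the body after nesting erosion",
               call. = FALSE)
        }
      }
    }
    contours[[z]] <- structure(
      list(set_id = ids[j], body = body, eroded = eroded, ribbon = ribbon,
           z = z, base_area = areas[[j]]),
      class = "set_contour"
    )
  }
  contours
}

#' Contours for all active sets of a trained layout
#'
#' Composes the full contour pipeline per active set: slice the neuron
#' field, threshold it into a tile body (with the hard membership
#' guarantee), merge tiles into polygons, cut staircase corners across
#' item-free space, smooth morphologically, then nest and carve ribbons
#' across sets.
#'
#' @param grid Trained `neuron_grid` from [rsom_train()].
#' @param layout The matching `module_layout`.
#' @param module The `annotated_module` that was laid out.
#' @param params [geometry_params()].
#' @return List of `set_contour` objects in drawing order.
#' @export
set_contours <- function(grid, layout, module, params = geometry_params()) {
  stopifnot(inherits(module, "annotated_module"))
  n_e <- nrow(module$interactions)
  active <- module$active
  if (length(active) == 0L) return(list())
  item_cells <- data.frame(x = layout$x, y = layout$y)
  bodies <- vector("list", length(active))
  names(bodies) <- active
  members <- vector("list", length(active))
  names(members) <- active
  for (j in seq_along(active)) {
    s <- module$sets[[active[j]]]
    field <- scalar_field(grid, n_e + j)
    cells <- tile_body(field, layout, s$members, params)
    poly <- tiles_to_polygon(cells, params)
    poly <- tighten(poly, item_cells, params)
    poly <- smooth_contour(poly, params)
    bodies[[j]] <- poly
    members[[j]] <- s$members
  }
  nest_and_ribbon(bodies, params, layout = layout, members = members)
}
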