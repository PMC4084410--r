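make_layout <- function(ids, x, y, side, tile = 1) {
  l <- data.frame(id = ids, x = x, y = y, stringsAsFactors = FALSE)
  attr(l, "side") <- as.integer(side)
  attr(l, "tile") <- tile
  class(l) <- c("module_layout", "data.frame")
  l
}

test_that("scalar fields are exact slices of the neuron grid", {
  set.seed(3)
  g <- init_grid(6, c(1, 2, 1))
  f <- scalar_field(g, 2)
  expect_equal(attr(f, "weight"), 2)
  # brute-force per-cell lookup
  for (x in 0:5) {
    for (y in 0:5) {
      expect_identical(f[x + 1, y + 1], g$values[x + y * 6 + 1, 2])
    }
  }
  expect_error(scalar_field(g, 4), "out of range")
  expect_error(scalar_field(g, 0), "out of range")

  # untrained all-zero component gives an all-zero field
  g0 <- init_grid(4, c(1), support = FALSE)
  expect_true(all(scalar_field(g0, 1) == 0))
})

test_that("after a full-overwrite epoch the member's cell carries the set weight", {
  mat <- matrix(c(1, 1), nrow = 1, dimnames = list("n1", c("e1", "s1")))
  attr(mat, "weights") <- c(1, 1)
  set.seed(8)
  g <- init_grid(4, c(1, 1))
  g1 <- train_epoch(g, mat, alpha = 1, radius = 0)
  k <- g1$reservations[[1]]
  f <- scalar_field(g1, 2)
  expect_equal(f[k %% 4 + 1, k %/% 4 + 1], 1)
})

test_that("tile bodies force-include members and force-exclude non-members", {
  p <- geometry_params()
  # all-zero field, no members -> empty body
  f0 <- matrix(0, 5, 5); attr(f0, "weight") <- 1
  lay <- make_layout(c("a", "b"), c(1, 3), c(1, 3), 5)
  expect_equal(nrow(tile_body(f0, lay, character(), p)), 0L)

  # saturated field with no placed non-members -> all cells
  f1 <- matrix(1, 5, 5); attr(f1, "weight") <- 1
  expect_equal(nrow(tile_body(f1, lay, c("a", "b"), p)), 25L)

  # a member whose cell is below threshold is still included
  f2 <- matrix(0, 5, 5); attr(f2, "weight") <- 1
  body <- tile_body(f2, lay, "a", p)
  expect_equal(nrow(body), 1L)
  expect_equal(c(body$x, body$y), c(1, 1))

  # a non-member whose cell is above threshold is excluded
  body2 <- tile_body(f1, lay, "a", p)
  expect_false(any(body2$x == 3 & body2$y == 3))
  expect_equal(nrow(body2), 24L)

  # threshold scales with the set weight
  fw <- matrix(1.9, 5, 5); attr(fw, "weight") <- 4  # 1.9 < tau * 4 = 2
  expect_equal(nrow(tile_body(fw, make_layout("a", 0, 0, 5), "a", p)), 1L)
  attr(fw, "weight") <- 1  # now every cell passes, none is a placed outsider
  expect_equal(nrow(tile_body(fw, make_layout("a", 0, 0, 5), "a", p)), 25L)
})

test_that("tile unions have exact area and an independently computed perimeter", {
  p <- geometry_params()
  one <- tiles_to_polygon(data.frame(x = 2, y = 3), p)
  expect_equal(ps_area(one), 1)
  block <- tiles_to_polygon(data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1)), p)
  expect_equal(ps_area(block), 4)
  expect_equal(length(block), 1L)

  set.seed(14)
  for (rep in 1:5) {
    cells <- unique(data.frame(x = sample(0:7, 30, TRUE),
                               y = sample(0:7, 30, TRUE)))
    poly <- tiles_to_polygon(cells, p)
    expect_equal(ps_area(poly), nrow(cells))
    expect_equal(ps_perimeter(poly), tile_perimeter_oracle(cells))
  }

  # a ring of tiles yields a polygon with a hole
  ring <- expand.grid(x = 0:2, y = 0:2)
  ring <- ring[!(ring$x == 1 & ring$y == 1), ]
  poly <- tiles_to_polygon(ring, p)
  expect_equal(ps_area(poly), 8)
  expect_false(ps_contains(poly, 1.5, 1.5))
  expect_true(ps_contains(poly, 0.5, 0.5))
})

test_that("tightening cuts free corners only and never grows the area", {
  p <- geometry_params()
  no_items <- data.frame(x = integer(), y = integer())

  rect <- tiles_to_polygon(expand.grid(x = 0:3, y = 0:1), p)
  cut <- tighten(rect, no_items, p)
  expect_lt(ps_area(cut), ps_area(rect))
  expect_equal(length(cut[[1]]$x), 8L)  # 4 corners -> octagon

  # L-shape: the concave elbow survives, convex corners are cut unless an
  # item sits in the corner tile
  L <- rbind(expand.grid(x = 0:2, y = 0), expand.grid(x = 0, y = 1:2))
  lp <- tiles_to_polygon(L, p)
  cut_free <- tighten(lp, no_items, p)
  expect_lt(ps_area(cut_free), ps_area(lp))
  # item in the far corner tile (2,0) blocks that cut
  cut_blocked <- tighten(lp, data.frame(x = 2, y = 0), p)
  expect_gt(ps_area(cut_blocked), ps_area(cut_free))
  # the item's cell center keeps its in-status
  expect_true(ps_contains(cut_blocked, 2.5, 0.5))

  expect_identical(tighten(list(), no_items, p), list())

  # item centers never change side across a tightening pass
  set.seed(21)
  for (rep in 1:5) {
    cells <- unique(data.frame(x = sample(0:5, 14, TRUE),
                               y = sample(0:5, 14, TRUE)))
    items <- unique(data.frame(x = sample(0:5, 4), y = sample(0:5, 4)))
    poly <- tiles_to_polygon(cells, p)
    tp <- tighten(poly, items, p)
    expect_lte(ps_area(tp), ps_area(poly) + 1e-9)
    inside_before <- ps_contains(poly, items$x + 0.5, items$y + 0.5)
    inside_after <- ps_contains(tp, items$x + 0.5, items$y + 0.5)
    expect_identical(inside_after, inside_before)
  }
})

test_that("morphological smoothing matches closed-form areas", {
  p <- geometry_params()
  expect_identical(smooth_contour(list(), p), list())

  # opening/closing a unit tile with r: area = 1 - (4 - pi) r^2
  sq <- list(list(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
  expect_equal(ps_area(smooth_contour(sq, p)), 1 - (4 - pi) * p$r^2,
               tolerance = p$arc_tol)

  # dilation of a convex polygon obeys the Steiner formula
  tri <- list(list(x = c(0, 2, 0), y = c(0, 0, 2)))
  per <- 2 + 2 + sqrt(8)
  expect_equal(ps_area(ps_offset(tri, p$r)), 2 + per * p$r + pi * p$r^2,
               tolerance = p$arc_tol)

  # area sanity: dilation never shrinks, erosion never grows
  set.seed(31)
  for (rep in 1:20) {
    cells <- unique(data.frame(x = sample(0:5, 10, TRUE),
                               y = sample(0:5, 10, TRUE)))
    poly <- tiles_to_polygon(cells, p)
    a <- ps_area(poly)
    expect_gte(ps_area(ps_offset(poly, p$r)) + 1e-9, a)
    expect_lte(ps_area(ps_offset(poly, -p$r)), a + 1e-9)
    # closing-then-opening stays between erosion and dilation
    sm <- ps_area(smooth_contour(poly, p))
    expect_lte(sm, ps_area(ps_offset(poly, p$r)) + 1e-9)
    expect_gte(sm + 1e-9, ps_area(ps_offset(poly, -p$r)))
  }
})

test_that("offsets agree with an independent buffer route", {
  # dilation via polyoffset vs. explicit Minkowski sum with a polygonal
  # disc (polyminkowski), on random tile unions
  set.seed(41)
  th <- seq(0, 2 * pi, length.out = 720)[-1]
  disc <- list(x = 0.15 * cos(th), y = 0.15 * sin(th))
  for (rep in 1:20) {
    cells <- unique(data.frame(x = sample(0:4, 8, TRUE),
                               y = sample(0:4, 8, TRUE)))
    poly <- tiles_to_polygon(cells, geometry_params())
    a1 <- ps_area(ps_offset(poly, 0.15))
    # per-ring boundary sweeps (annuli) unioned with the original = dilation
    sweeps <- lapply(poly, function(r) {
      if (somset:::ring_area(r) < 0) r <- list(x = rev(r$x), y = rev(r$y))
      polyclip::polyminkowski(list(r), disc)
    })
    mink <- Reduce(function(A, B) {
      polyclip::polyclip(A, B, "union", fillA = "nonzero", fillB = "nonzero")
    }, sweeps, accumulate = FALSE)
    mink <- polyclip::polyclip(mink, poly, "union",
                               fillA = "nonzero", fillB = "nonzero")
    a2 <- sum(vapply(mink, function(r) {
      n <- length(r$x); j <- c(n, seq_len(n - 1))
      sum(r$x[j] * r$y - r$x * r$y[j]) / 2
    }, 0))
    expect_equal(a1, a2, tolerance = 2e-3)
  }
})

test_that("nesting ranks by area and ribbons partition their bodies", {
  p <- geometry_params()
  sq <- function(s, ox = 0, oy = 0) {
    list(list(x = c(0, s, s, 0) + ox, y = c(0, 0, s, s) + oy))
  }
  # single square body: ribbon area 4 e (s - e), exactly
  ct <- nest_and_ribbon(list(only = sq(4)), p)
  expect_equal(ps_area(ct[[1]]$ribbon), 4 * p$e * (4 - p$e),
               tolerance = p$arc_tol)
  # partition: ribbon and eroded body are disjoint and rebuild the body
  expect_equal(ps_area(ct[[1]]$ribbon) + ps_area(ct[[1]]$eroded),
               ps_area(ct[[1]]$body), tolerance = p$arc_tol)
  expect_equal(ps_area(ps_intersect(ct[[1]]$ribbon, ct[[1]]$eroded)), 0,
               tolerance = p$arc_tol)

  # nested squares: superset drawn first, subset's outline strictly inside
  cts <- nest_and_ribbon(list(inner = sq(2, 1, 1), outer = sq(6)), p)
  expect_equal(cts[[1]]$set_id, "outer")
  expect_equal(cts[[2]]$set_id, "inner")
  expect_equal(vapply(cts, `[[`, 0, "z"), c(1, 2))
  expect_true(all(vapply(seq_along(cts[[2]]$body[[1]]$x), function(i) {
    ps_contains(cts[[1]]$body, cts[[2]]$body[[1]]$x[i],
                cts[[2]]$body[[1]]$y[i])
  }, TRUE)))
  # deeper nesting level means more erosion
  expect_lt(ps_area(cts[[2]]$body), 4)
  expect_equal(ps_area(cts[[1]]$body), 36, tolerance = p$arc_tol)

  # area ties break by input order
  tie <- nest_and_ribbon(list(a = sq(3), b = sq(3, 10, 0)), p)
  expect_equal(tie[[1]]$set_id, "a")

  expect_identical(nest_and_ribbon(list(), p), list())
})

test_that("contour containment matches set membership on trained modules", {
  p <- geometry_params()
  for (seed in 1:4) {
    m <- generate_module(12, 15, 8, seed = 600 + seed, n_active = 3)
    r <- rsom_train(encode(m), iterations = 1000, seed = 700 + seed)
    cts <- set_contours(r$grid, r$layout, m, p)
    expect_equal(length(cts), 3L)
    for (ct in cts) {
      members <- m$sets[[ct$set_id]]$members
      inside <- ps_contains(ct$body, (r$layout$x + 0.5) * p$tile,
                            (r$layout$y + 0.5) * p$tile)
      expect_identical(inside, r$layout$id %in% members)
    }
    # z-order is the descending order of the pre-erosion body areas
    expect_identical(order(-vapply(cts, `[[`, 0, "base_area")),
                     seq_along(cts))
  }
})

test_that("too many nesting levels shrink delta rather than break containment", {
  p <- geometry_params()
  sq <- function(s) list(list(x = c(0, s, s, 0), y = c(0, 0, s, s)))
  bodies <- stats::setNames(lapply(seq(20, 2, by = -2), sq),
                            paste0("s", 1:10))
  expect_warning(cts <- nest_and_ribbon(bodies, p), "delta")
  expect_equal(length(cts), 10L)
  expect_true(all(vapply(cts, function(ct) ps_area(ct$eroded) > 0, TRUE)))
})
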