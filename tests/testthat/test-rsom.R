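test_that("cosine distance satisfies its metric contract", {
  m <- example_module()
  mat <- encode(m)
  # self-distance of a nonzero vector is 0
  expect_equal(cosine_distance(mat["Plcb4", ], mat["Plcb4", ]), 0)
  # the two printed worked-example vectors are orthogonal: distance 1/2
  expect_equal(cosine_distance(mat["Nr3c2", ], mat["Plcb4", ]), 0.5)
  # antiparallel
  expect_equal(cosine_distance(c(1, 0), c(-1, 0)), 1)
  # degenerate zero-vector conventions
  expect_equal(cosine_distance(numeric(3), numeric(3)), 0)
  expect_equal(cosine_distance(numeric(3), c(1, 2, 3)), 1)
  expect_error(cosine_distance(1:3, 1:4), "length")

  set.seed(11)
  for (k in 1:1000) {
    M <- sample(2:12, 1)
    q <- rnorm(M); p <- rnorm(M)
    d1 <- cosine_distance(q, p)
    expect_gte(d1, 0); expect_lte(d1, 1)
    expect_identical(d1, cosine_distance(p, q))
    expect_lt(abs(d1 - cos_oracle(q, p)), 1e-12)
  }
})

test_that("annealing schedule has the stated endpoints and monotonicity", {
  s <- training_schedule(1000, c = 0.5, N = 24)
  expect_equal(s$alpha(0), 0.5)
  expect_equal(s$alpha(1000), 0)
  expect_equal(s$radius(0), 24L)
  expect_equal(s$radius(1000), 0L)
  expect_true(all(diff(s$alphas) < 0))
  expect_true(all(diff(s$radii) <= 0))
  expect_equal(default_iterations(17), ceiling(1e6 / 17))
})

test_that("grid sizing follows the side policy with a cap", {
  expect_equal(grid_side(6), 12L)
  expect_equal(grid_side(40), 64L)
  expect_equal(grid_side(40, cap = 128), 80L)
  expect_gte(grid_side(10, "cells")^2, 20)
  # always room for all items
  expect_gte(grid_side(5000, cap = 8)^2, 5000)
})

test_that("grid initialization is reproducible, ranged, and uniform in moments", {
  w <- c(1, 2, 0.5)
  set.seed(5); g1 <- init_grid(16, w)
  set.seed(5); g2 <- init_grid(16, w)
  expect_identical(g1$values, g2$values)
  for (i in 1:3) {
    expect_true(all(g1$values[, i] >= 0 & g1$values[, i] <= w[i]))
  }
  # component-wise mean of a 64x64 grid within 3 standard errors of w/2
  set.seed(6); g3 <- init_grid(64, w)
  for (i in 1:3) {
    se <- w[i] / sqrt(12 * 64^2)
    expect_lt(abs(mean(g3$values[, i]) - w[i] / 2), 3 * se)
  }
  # a component with no support stays silent and consumes no draws
  set.seed(7); ga <- init_grid(8, c(1, 1), support = c(TRUE, TRUE))
  set.seed(7); gb <- init_grid(8, c(1, 1), support = c(TRUE, FALSE))
  expect_identical(ga$values[, 1], gb$values[, 1])
  expect_true(all(gb$values[, 2] == 0))
})

test_that("a training epoch reserves injectively and trains convexly", {
  m <- rand_module(2, n_nodes = 9, n_sets = 4, n_active = 2)
  mat <- encode(m)
  set.seed(9)
  g <- init_grid(8, attr(mat, "weights"))

  # alpha = 0: values untouched, reservations still complete and injective
  g0 <- train_epoch(g, mat, alpha = 0, radius = 3)
  expect_identical(g0$values, g$values)
  expect_equal(length(g0$reservations), nrow(mat))
  expect_false(anyDuplicated(g0$reservations) > 0)

  # full-strength zero-radius epoch overwrites the winning neuron exactly
  single <- mat[1, , drop = FALSE]
  g1 <- train_epoch(g, single, alpha = 1, radius = 0)
  k <- g1$reservations[[1]]
  expect_equal(unname(g1$values[k + 1, ]), unname(single[1, ]))

  # identical items still land on distinct cells (trickle outwards)
  twin <- rbind(a = mat[1, ], b = mat[1, ])
  g2 <- train_epoch(g, twin, alpha = 0.5, radius = 2)
  expect_equal(length(unique(g2$reservations)), 2L)

  # convexity: components never leave [0, w_i] across epochs
  gg <- g
  for (ep in 1:25) {
    gg <- train_epoch(gg, mat, alpha = 0.5 * (1 - ep / 25), radius = 3)
    for (i in seq_len(ncol(mat))) {
      expect_true(all(gg$values[, i] >= 0 - 1e-12 &
                      gg$values[, i] <= attr(mat, "weights")[i] + 1e-12))
    }
  }

  # more items than cells is rejected at entry
  tiny <- init_grid(2, attr(mat, "weights"))
  big <- mat[rep(1, 5), ]
  rownames(big) <- paste0("r", 1:5)
  expect_error(train_epoch(tiny, big, 0.1, 1), "more items")
})

test_that("training is deterministic given module and seed", {
  m <- rand_module(4, n_nodes = 10, n_sets = 5, n_active = 2)
  mat <- encode(m)
  r1 <- rsom_train(mat, iterations = 800, seed = 123)
  r2 <- rsom_train(mat, iterations = 800, seed = 123)
  expect_identical(r1$layout, r2$layout)
  expect_identical(r1$grid$values, r2$grid$values)
})

test_that("layouts are injective across random modules", {
  # moderate sweep here; the acceptance suite runs the full 50-module sweep
  for (seed in 1:6) {
    n <- sample(4:20, 1)
    m <- rand_module(seed + 40, n_nodes = n, n_sets = 5, n_active = 2)
    r <- rsom_train(encode(m), iterations = 500, seed = seed)
    expect_equal(nrow(unique(r$layout[, c("x", "y")])), n)
    expect_true(all(r$layout$x >= 0 & r$layout$x < attr(r$layout, "side")))
    expect_true(all(r$layout$y >= 0 & r$layout$y < attr(r$layout, "side")))
  }
})

test_that("an appended zero-member active set leaves the layout identical", {
  m <- rand_module(5, n_nodes = 11, n_sets = 5, n_active = 2)
  m2 <- m
  m2$sets$void <- annotation_set("void", members = character())
  m2 <- build_module(m2$nodes, m2$interactions, m2$sets,
                     active = c(m$active, "void"))
  r1 <- rsom_train(encode(m), iterations = 1200, seed = 77)
  r2 <- rsom_train(encode(m2), iterations = 1200, seed = 77)
  expect_identical(r1$layout$x, r2$layout$x)
  expect_identical(r1$layout$y, r2$layout$y)
})

test_that("warm starts preserve the previous layout on an unchanged module", {
  m <- rand_module(6, n_nodes = 12, n_sets = 6, n_active = 3)
  mat <- encode(m)
  r1 <- rsom_train(mat, iterations = 2000, seed = 42)
  r2 <- rsom_train(mat, iterations = 2000, grid = r1$grid, seed = 43)
  moved <- mean(r2$layout$x != r1$layout$x | r2$layout$y != r1$layout$y)
  # a small fraction may relocate; report and bound it
  expect_lte(moved, 0.25)
  # and the warm result is still a complete injective layout
  expect_equal(nrow(unique(r2$layout[, c("x", "y")])), nrow(mat))
})

test_that("warm starts reconcile components across a dimension change", {
  m <- rand_module(7, n_nodes = 10, n_sets = 6, n_active = 2)
  r1 <- rsom_train(encode(m), iterations = 1500, seed = 21)

  extra_id <- setdiff(names(m$sets), m$active)[1]
  m2 <- set_active(m, c(m$active, extra_id))
  r2 <- rsom_train(encode(m2), iterations = 1500, grid = r1$grid, seed = 22)
  expect_equal(length(r2$grid$weights), ncol(encode(m2)))
  expect_equal(nrow(unique(r2$layout[, c("x", "y")])), 10L)
  # most nodes stay put when one set is toggled on
  moved <- mean(r2$layout$x != r1$layout$x | r2$layout$y != r1$layout$y)
  expect_lte(moved, 0.6)

  # removing a set also reconciles
  m3 <- set_active(m, m$active[1])
  r3 <- rsom_train(encode(m3), iterations = 1500, grid = r1$grid, seed = 23)
  expect_equal(r3$grid$M, ncol(encode(m3)))
})

test_that("raising a set's dominance weight pulls its members together", {
  # the coalescing effect needs the long, gradual annealing the method
  # prescribes; short schedules freeze members before they can converge
  deltas <- vapply(1:6, function(s) {
    base <- generate_module(10, 13, 0, seed = 700 + s)
    planted <- annotation_set("planted",
                              members = base$nodes$id[c(2, 4, 6, 8)])
    mod <- build_module(base$nodes, base$interactions, list(planted),
                        active = "planted")
    mean_pd <- function(w) {
      r <- rsom_train(encode(set_weight(mod, "planted", w)),
                      iterations = 40000, seed = s)
      ii <- match(c("g02", "g04", "g06", "g08"), r$layout$id)
      mean(stats::dist(cbind(r$layout$x[ii], r$layout$y[ii])))
    }
    mean_pd(1) - mean_pd(5)
  }, 0)
  expect_gt(mean(deltas), 0)
})

test_that("weight zero removes a set's influence on the layout", {
  m <- rand_module(8, n_nodes = 10, n_sets = 3, n_active = 1)
  sid <- m$active[1]
  # drop the component entirely vs. keep it at weight 0: identical layouts
  r_off <- rsom_train(encode(set_weight(m, sid, 0)), iterations = 1000,
                      seed = 31)
  m_none <- set_active(m, character())
  r_none <- rsom_train(encode(m_none), iterations = 1000, seed = 31)
  expect_identical(r_off$layout$x, r_none$layout$x)
  expect_identical(r_off$layout$y, r_none$layout$y)
})
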