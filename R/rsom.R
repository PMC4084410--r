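#' Metric cosine distance
#'
#' The metric form of cosine similarity, d(q, p) = arccos(q.p / (|q||p|)) / pi,
#' mapping parallel vectors to 0, orthogonal ones to 1/2 and antiparallel
#' ones to 1. It outperforms Euclidean norms for the high-dimensional,
#' sparse membership vectors trained here. The dot-product cosine is clamped
#' to [-1, 1] before arccos. Degenerate zero vectors follow the conventions
#' d(0, 0) = 0 and d(0, p != 0) = 1.
#'
#' @param q,p Numeric vectors of equal length.
#' @return A number in \[0, 1\].
#' @export
cosine_distance <- function(q, p) {
  if (length(q) != length(p)) stop("vectors differ in length", call. = FALSE)
  nq <- sum(q * q)
  np <- sum(p * p)
  if (nq == 0 && np == 0) return(0)
  if (nq == 0 || np == 0) return(1)
  acos(min(1, max(-1, sum(q * p) / sqrt(nq * np)))) / pi
}

#' Linear annealing schedule for SOM training
#'
#' Training strength and neighborhood radius decrease linearly:
#' alpha(i) = c (1 - i/I) and radius(i) = floor((1 - i/I) N), so early
#' epochs train nearly the whole grid strongly and late epochs make small
#' local refinements. Training runs epochs i = 0, ..., I-1.
#'
#' @param I Number of epochs; the default for a module with `n_items` nodes
#'   is `ceiling(1e6 / n_items)`.
#' @param c Initial training strength in (0, 1); 0.5 for cold starts, 0.01
#'   for warm starts that should preserve the previous layout.
#' @param N Grid side; radius(0) = `radius_start` spans the whole grid for
#'   cold starts.
#' @param radius_start Radius at epoch 0; defaults to `N`. Warm starts pass
#'   a small value here: restarting the neighborhood at the full grid side
#'   would sweep every neuron with every item each epoch, which provably
#'   flattens the trained field (and with it the previous layout) even at
#'   tiny strengths.
#' @return An object of class `som_schedule` with functions `alpha(i)` and
#'   `radius(i)` plus the per-epoch vectors used by the trainer.
#' @export
training_schedule <- function(I, c = 0.5, N, radius_start = N) {
  stopifnot(I >= 1, c > 0, c < 1, N >= 1, radius_start >= 0,
            radius_start <= N)
  I <- as.integer(I)
  alpha <- function(i) c * (1 - i / I)
  radius <- function(i) as.integer(floor((1 - i / I) * radius_start))
  i <- seq_len(I) - 1L
  structure(
    list(I = I, c = c, N = as.integer(N), alpha = alpha, radius = radius,
         alphas = alpha(i), radii = radius(i)),
    class = "som_schedule"
  )
}

#' Default number of training epochs
#'
#' @param n_items Number of module nodes.
#' @return `ceiling(1e6 / n_items)`, the schedule length giving gradual and
#'   accurate training.
#' @export
default_iterations <- function(n_items) {
  as.integer(ceiling(1e6 / max(1L, n_items)))
}

#' Grid side for a module of a given size
#'
#' @param n_items Number of module nodes.
#' @param policy `"side"` (default): side N = 2 n_items, giving spacious
#'   layouts; `"cells"`: total cell count about 2 n_items, i.e. side
#'   `ceiling(sqrt(2 n_items))`.
#' @param cap Upper bound on the side (default 64) to keep training cost
#'   bounded for larger modules.
#' @return Integer grid side, at least 2 and at least large enough to hold
#'   all items.
#' @export
grid_side <- function(n_items, policy = c("side", "cells"), cap = 64L) {
  policy <- match.arg(policy)
  side <- switch(policy,
    side = 2L * as.integer(n_items),
    cells = as.integer(ceiling(sqrt(2 * n_items)))
  )
  side <- max(2L, min(as.integer(cap), side))
  while (side * side < n_items) side <- side + 1L
  side
}

#' Initialize a neuron grid
#'
#' Component i of every neuron is drawn uniformly on \[0, w_i\]. Draws are
#' consumed component by component, and a component with empty support (no
#' member node, so every training item is 0 there) is set to 0 and consumes
#' no draws: noise in a dead component would only bias the cosine distances,
#' and skipping its draws keeps the initial state of all other components
#' identical when such a component is added or removed.
#'
#' @param N Grid side.
#' @param weights Per-component weights w (length M).
#' @param support Logical vector, length M: does component i have at least
#'   one member? Defaults to all `TRUE`.
#' @return A `neuron_grid`: list with `side`, `M`, `weights`, `values`
#'   (N^2 x M matrix, row k is the neuron of cell k-1 in row-major x + y N
#'   order) and an empty `reservations` vector.
#' @export
init_grid <- function(N, weights, support = rep(TRUE, length(weights))) {
  N <- as.integer(N)
  M <- length(weights)
  stopifnot(N >= 1, length(support) == M)
  values <- matrix(0, nrow = N * N, ncol = M)
  for (i in seq_len(M)) {
    if (support[i]) values[, i] <- stats::runif(N * N, 0, weights[i])
  }
  structure(
    list(side = N, M = M, weights = as.numeric(weights), values = values,
         reservations = integer()),
    class = "neuron_grid"
  )
}

#' @export
print.neuron_grid <- function(x, ...) {
  cat("neuron grid: ", x$side, "x", x$side, " cells, M = ", x$M,
      ", ", length(x$reservations), " reserved\n", sep = "")
  invisible(x)
}

#' Convert row-major cell indices to grid coordinates
#'
#' @param cell 0-based row-major cell index (x + y N).
#' @param N Grid side.
#' @return Data frame with integer columns `x` and `y`.
#' @keywords internal
cell_xy <- function(cell, N) {
  data.frame(x = cell %% N, y = cell %/% N)
}

# Standing positions carried into training: -1 where an item has none.
prev_cells <- function(grid, matrix) {
  prev <- rep(-1L, nrow(matrix))
  if (length(grid$reservations)) {
    m <- match(rownames(matrix), names(grid$reservations))
    prev[!is.na(m)] <- as.integer(grid$reservations[m[!is.na(m)]])
  }
  prev
}

check_matrix <- function(matrix) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix))) {
    rownames(matrix) <- paste0("item", seq_len(nrow(matrix)))
  }
  matrix
}

#' Run one epoch of reservation-based training
#'
#' Reservations are cleared, the items are visited in a freshly shuffled
#' order (consuming the session RNG), and each item reserves the unreserved
#' neuron at minimal cosine distance (ties broken toward the smaller
#' row-major cell index). All neurons within the Chebyshev radius of the
#' reserved cell — reserved or not — are pulled toward the item by
#' q <- q + alpha (t - q). Because a neuron can be claimed only once per
#' epoch, identical items trickle outwards to adjacent free cells instead of
#' collapsing onto one.
#'
#' @param grid A `neuron_grid`.
#' @param matrix Membership matrix from [encode()] (rows = items).
#' @param alpha Training strength in \[0, 1\].
#' @param radius Non-negative integer Chebyshev neighborhood radius.
#' @return The updated `neuron_grid`, with `reservations` a named 0-based
#'   row-major cell index per item — a complete injective map.
#' @export
train_epoch <- function(grid, matrix, alpha, radius) {
  matrix <- check_matrix(matrix)
  stopifnot(inherits(grid, "neuron_grid"), ncol(matrix) == grid$M,
            alpha >= 0, alpha <= 1, radius >= 0)
  if (nrow(matrix) > grid$side^2) {
    stop("more items (", nrow(matrix), ") than grid cells (", grid$side^2,
         ")", call. = FALSE)
  }
  cn <- colnames(grid$values)
  out <- rsom_train_cpp(t(grid$values), t(matrix),
                        as.numeric(alpha), as.integer(radius),
                        grid$side, prev_cells(grid, matrix))
  grid$values <- t(out$neurons)
  colnames(grid$values) <- cn
  grid$reservations <- stats::setNames(out$reservations, rownames(matrix))
  grid
}

#' Train a reservation-based SOM layout
#'
#' Runs `iterations` epochs of [train_epoch()] under the linear annealing
#' schedule, either from a fresh random grid (cold start) or from a supplied
#' grid (warm start, default strength 0.01) so that re-laying-out a slightly
#' changed module preserves the user's mental map. The final epoch's
#' reservations are the layout.
#'
#' When a warm-start grid is given, its components are reconciled with the
#' matrix by component id: surviving components keep their trained neuron
#' values, removed components are dropped, and new components start at zero
#' so they grow only where their members are placed. The warm annealing
#' resumes late in the schedule (alpha at `strength`, radius at
#' `floor(N * strength / 0.5)`, at least 1) rather than restarting the
#' radius at N, which would erase the configuration being preserved.
#'
#' @param matrix Membership matrix from [encode()].
#' @param side Grid side N; default [grid_side()] of the item count.
#' @param iterations Number of epochs I; default [default_iterations()].
#' @param strength Initial training strength c; defaults to 0.5 for cold
#'   starts and 0.01 for warm starts.
#' @param grid Optional `neuron_grid` to warm-start from.
#' @param seed Integer seed; the whole run (initialization and every epoch
#'   shuffle) is reproducible from it.
#' @return List with `layout` (a `module_layout`: data frame of `id`, `x`,
#'   `y` integer cells plus `side` and `tile` attributes) and `grid` (the
#'   trained `neuron_grid`).
#' @export
rsom_train <- function(matrix, side = NULL, iterations = NULL,
                       strength = NULL, grid = NULL, seed = 1L) {
  matrix <- check_matrix(matrix)
  n_items <- nrow(matrix)
  weights <- attr(matrix, "weights")
  if (is.null(weights)) weights <- rep(1, ncol(matrix))
  warm <- !is.null(grid)
  if (is.null(strength)) strength <- if (warm) 0.01 else 0.5
  if (is.null(iterations)) iterations <- default_iterations(n_items)

  set.seed(as.integer(seed))
  if (warm) {
    grid <- reconcile_grid(grid, matrix, weights)
    if (is.null(side)) side <- grid$side
    if (side != grid$side) stop("side does not match warm-start grid",
                                call. = FALSE)
  } else {
    if (is.null(side)) side <- grid_side(n_items)
    support <- colSums(matrix != 0) > 0
    grid <- init_grid(side, weights, support)
  }
  if (n_items > side^2) {
    stop("more items (", n_items, ") than grid cells (", side^2, ")",
         call. = FALSE)
  }

  # A warm start resumes the annealing roughly where a cold run stands once
  # its strength has decayed to `strength`: both alpha and the neighborhood
  # radius restart at the corresponding late-schedule values. Restarting the
  # radius at N instead would have every item sweep the whole grid every
  # epoch, erasing the very configuration the warm start is meant to keep.
  radius_start <- if (warm) {
    max(1L, as.integer(floor(side * strength / 0.5)))
  } else side
  sched <- training_schedule(iterations, strength, side, radius_start)
  out <- rsom_train_cpp(t(grid$values), t(matrix), sched$alphas, sched$radii,
                        grid$side, prev_cells(grid, matrix))
  grid$values <- t(out$neurons)
  colnames(grid$values) <- colnames(matrix)
  grid$reservations <- stats::setNames(out$reservations, rownames(matrix))

  xy <- cell_xy(grid$reservations, side)
  layout <- data.frame(id = rownames(matrix), x = xy$x, y = xy$y,
                       stringsAsFactors = FALSE)
  attr(layout, "side") <- as.integer(side)
  attr(layout, "tile") <- 1
  class(layout) <- c("module_layout", "data.frame")
  list(layout = layout, grid = grid)
}

# Carry trained neuron values across a change of membership components.
# Matching is by component id (colnames); removed components are dropped and
# new components start at 0 everywhere. Starting them at noise instead would
# either survive as speckle in the new set's scalar field (small warm
# radius) or require grid-wide sweeps that destroy the old layout (large
# radius); starting at 0 keeps the best-match ranking of every item exactly
# as before (a zero component scales all cosines by the same factor) and
# lets the new set's field grow only around its members' cells.
reconcile_grid <- function(grid, matrix, weights) {
  stopifnot(inherits(grid, "neuron_grid"))
  old_ids <- colnames(grid$values)
  new_ids <- colnames(matrix)
  if (is.null(old_ids) || is.null(new_ids)) {
    if (grid$M == ncol(matrix)) {  # positional match when ids are absent
      grid$weights <- as.numeric(weights)
      return(grid)
    }
    stop("cannot reconcile grids without component ids", call. = FALSE)
  }
  N2 <- grid$side^2
  values <- matrix(0, nrow = N2, ncol = ncol(matrix),
                   dimnames = list(NULL, new_ids))
  for (j in seq_along(new_ids)) {
    k <- match(new_ids[j], old_ids)
    if (!is.na(k)) values[, j] <- grid$values[, k]
  }
  grid$values <- values
  grid$M <- ncol(matrix)
  grid$weights <- as.numeric(weights)
  # reservations stay: they are the items' standing positions, which seed
  # the sticky tie-breaking of the next training run
  grid
}

#' @export
print.module_layout <- function(x, ...) {
  cat("module layout on a ", attr(x, "side"), "x", attr(x, "side"),
      " grid\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
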