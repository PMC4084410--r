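# Shared fixtures and independent oracles for the test suite.

# Brute-force membership oracle for the encoding: a double loop over nodes
# and components, no matrix algebra shared with encode().
brute_encode <- function(module) {
  ids <- module$nodes$id
  ia <- module$interactions
  n_e <- nrow(ia)
  comps <- c(
    lapply(seq_len(n_e), function(i) {
      list(members = c(ia$a[i], ia$b[i]), w = 1)
    }),
    lapply(module$active, function(sid) {
      s <- module$sets[[sid]]
      list(members = s$members, w = s$weight)
    })
  )
  out <- matrix(0, nrow = length(ids), ncol = length(comps))
  rownames(out) <- ids
  for (v in seq_along(ids)) {
    for (i in seq_along(comps)) {
      for (mem in comps[[i]]$members) {
        if (mem == ids[v]) out[v, i] <- comps[[i]]$w
      }
    }
  }
  out
}

# Independent evaluation of the metric cosine distance through atan2 of the
# rejection norm -- a different formula and different conditioning than the
# acos route used by the package.
cos_oracle <- function(q, p) {
  nq <- sum(q^2); np <- sum(p^2)
  if (nq == 0 && np == 0) return(0)
  if (nq == 0 || np == 0) return(1)
  dot <- sum(q * p)
  rej2 <- max(0, nq * np - dot^2)
  atan2(sqrt(rej2), dot) / pi
}

# A small random annotated module with a controllable shape.
rand_module <- function(seed, n_nodes = 10, n_sets = 6, n_active = 2,
                        overlap = 0.5) {
  n_edges <- min(n_nodes + 3, n_nodes * (n_nodes - 1) / 2)
  generate_module(n_nodes, n_edges, n_sets, seed = seed, overlap = overlap,
                  n_active = n_active)
}

mean_pairwise_jaccard <- function(module) {
  sets <- lapply(module$sets, `[[`, "members")
  n <- length(sets)
  if (n < 2) return(NA_real_)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      u <- length(union(sets[[i]], sets[[j]]))
      vals <- c(vals, if (u == 0) 0 else
        length(intersect(sets[[i]], sets[[j]])) / u)
    }
  }
  mean(vals)
}

# Perimeter of a polygon set (sum over rings of edge lengths).
ps_perimeter <- function(ps) {
  sum(vapply(ps, function(r) {
    n <- length(r$x)
    j <- c(n, seq_len(n - 1L))
    sum(sqrt((r$x - r$x[j])^2 + (r$y - r$y[j])^2))
  }, 0))
}

# Independent perimeter of a union of unit tiles: 4 per cell minus 2 per
# orthogonally adjacent pair.
tile_perimeter_oracle <- function(cells, tile = 1) {
  n <- nrow(cells)
  adj <- 0L
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (abs(cells$x[i] - cells$x[j]) + abs(cells$y[i] - cells$y[j]) == 1L)
          adj <- adj + 1L
      }
    }
  }
  (4 * n - 2 * adj) * tile
}
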