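#' Generate a synthetic annotated module
#'
#' Emulates the data characteristics of modules produced by integrative
#' network analysis: a small, sparse, connected interaction network (a
#' random spanning tree plus extra random edges); many annotation sets,
#' by default outnumbering the interactions; set cardinalities spanning a
#' single node up to the whole module; and frequent set overlap, tunable
#' via `overlap` (sets are drawn from a shared node pool whose size shrinks
#' as `overlap` grows, so the expected pairwise Jaccard index rises with
#' it). Enrichment p-values are log-uniform on \[1e-8, 1e-2\] and node
#' scores standard normal; everything is reproducible from `seed`.
#'
#' @param n_nodes Number of nodes (default 17).
#' @param n_edges Number of interactions (default 20); must admit a
#'   connected simple graph, i.e. lie in \[n_nodes - 1, n_nodes(n_nodes-1)/2\]
#'   (0 for a single node).
#' @param n_sets Number of annotation sets (default 25).
#' @param seed Integer seed.
#' @param overlap Overlap level in \[0, 1\].
#' @param n_active Number of sets (most significant first) marked active;
#'   default `min(3, n_sets)`.
#' @param out_prefix Optional path prefix; when given the module is also
#'   written via [write_module()].
#' @return An `annotated_module`.
#' @export
generate_module <- function(n_nodes = 17, n_edges = 20, n_sets = 25,
                            seed = 1L, overlap = 0.5,
                            n_active = min(3L, n_sets), out_prefix = NULL) {
  stopifnot(n_nodes >= 1, n_sets >= 0, overlap >= 0, overlap <= 1,
            n_active >= 0, n_active <= n_sets)
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_nodes == 1L) {
    if (n_edges != 0) stop("a single-node module admits no edges",
                           call. = FALSE)
  } else if (n_edges < n_nodes - 1 || n_edges > max_edges) {
    stop("n_edges must lie in [", n_nodes - 1, ", ", max_edges,
         "] for a connected simple graph on ", n_nodes, " nodes",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  ids <- sprintf("g%02d", seq_len(n_nodes))
  nodes <- data.frame(id = ids, label = ids,
                      score = stats::rnorm(n_nodes),
                      url = NA_character_, stringsAsFactors = FALSE)

  # D1: connected and sparse — random spanning tree, then extra edges
  a <- character(); b <- character()
  if (n_nodes > 1L) {
    for (i in 2:n_nodes) {
      j <- if (i == 2L) 1L else sample.int(i - 1L, 1L)
      a <- c(a, ids[j]); b <- c(b, ids[i])
    }
    key <- function(u, v) ifelse(u < v, paste(u, v), paste(v, u))
    have <- key(a, b)
    while (length(a) < n_edges) {
      uv <- sample.int(n_nodes, 2L)
      k <- key(ids[uv[1L]], ids[uv[2L]])
      if (!k %in% have) {
        a <- c(a, ids[uv[1L]]); b <- c(b, ids[uv[2L]])
        have <- c(have, k)
      }
    }
  }
  interactions <- data.frame(a = a, b = b, stringsAsFactors = FALSE)

  # D3 + D4: cardinalities from 1 to n_nodes, members from a shared pool
  sets <- list()
  if (n_sets > 0L) {
    pool_size <- min(n_nodes,
                     max(2L, as.integer(ceiling(n_nodes * (1 - 0.85 * overlap)))))
    pool <- sample(ids, pool_size)
    rest <- setdiff(ids, pool)
    sizes <- pmin(n_nodes, pmax(1L, as.integer(round(
      stats::qbeta(stats::runif(n_sets), 1.2, 2.5) * n_nodes))))
    if (n_sets >= 2L) {  # make sure the range is actually spanned
      sizes[1L] <- 1L
      sizes[2L] <- n_nodes
    }
    p_values <- 10^stats::runif(n_sets, -8, -2)
    cats <- c("pathway", "process", "function")
    for (k in seq_len(n_sets)) {
      sz <- sizes[k]
      members <- if (sz <= pool_size) {
        sample(pool, sz)
      } else {
        c(pool, sample(rest, sz - pool_size))
      }
      sets[[k]] <- annotation_set(
        sprintf("s%02d", k), members = members,
        label = sprintf("annotation %02d", k),
        category = cats[(k - 1L) %% 3L + 1L],
        p_value = p_values[k]
      )
    }
  }
  active <- if (n_active > 0L) {
    ord <- order(vapply(sets, `[[`, 0, "p_value"))
    vapply(sets[ord[seq_len(n_active)]], `[[`, "", "id")
  } else character()

  module <- build_module(nodes, interactions, sets, active = active)
  if (!is.null(out_prefix)) write_module(module, out_prefix)
  module
}
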