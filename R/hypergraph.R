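#' Construct an annotation set
#'
#' An annotation set is an n-ary edge of the module hypergraph: a named,
#' categorized subset of the module's nodes carrying an overrepresentation
#' p-value and a dominance weight.
#'
#' @param id Unique set identifier.
#' @param members Character vector of member node ids.
#' @param label Display label; defaults to `id`.
#' @param category Grouping used in the set overview (e.g. "pathway",
#'   "process", "function"). Default `"uncategorized"`.
#' @param p_value Enrichment p-value in (0, 1]. Default 1.
#' @param weight Non-negative dominance weight; 1 leaves the set on equal
#'   terms with interactions, larger values pull its members together in the
#'   layout, 0 removes its influence.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(id, members, label = id,
                           category = "uncategorized",
                           p_value = 1, weight = 1) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  members <- unique(as.character(members))
  if (!is.numeric(p_value) || length(p_value) != 1L || is.na(p_value) ||
      p_value <= 0 || p_value > 1) {
    stop("p_value of set '", id, "' must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
      weight < 0) {
    stop("weight of set '", id, "' must be a non-negative number",
         call. = FALSE)
  }
  structure(
    list(id = id, label = as.character(label), category = as.character(category),
         p_value = as.numeric(p_value), members = members,
         weight = as.numeric(weight)),
    class = "annotation_set"
  )
}

#' Build a validated annotated module
#'
#' An annotated module is a hypergraph: nodes (genes) connected by binary
#' edges (interactions) and by n-ary edges (annotation sets). Interactions
#' are undirected; duplicates are collapsed and self-pairs rejected. Every
#' id referenced by an interaction or a set must be present in the node
#' table — modules are curated inputs and unknown ids are an error.
#'
#' @param nodes Data frame with columns `id`, `label`, `score` and optionally
#'   `url`. `score` is a signed differential-expression statistic (negative =
#'   under-expressed); it may be `NA`.
#' @param interactions Data frame (or 2-column matrix) with columns `a`, `b`
#'   holding node ids of undirected interactions.
#' @param sets List of [annotation_set()] objects.
#' @param active Character vector of set ids selected for layout, in display
#'   order. Defaults to all sets in input order.
#' @return An object of class `annotated_module`.
#' @export
build_module <- function(nodes, interactions = NULL, sets = list(),
                         active = vapply(sets, `[[`, "", "id")) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (nrow(nodes) < 1L) stop("module must contain at least one node",
                             call. = FALSE)
  if (!all(c("id", "label") %in% names(nodes))) {
    if (!"id" %in% names(nodes)) stop("node table needs an 'id' column",
                                      call. = FALSE)
    nodes$label <- nodes$id
  }
  if (!"score" %in% names(nodes)) nodes$score <- NA_real_
  if (!"url" %in% names(nodes)) nodes$url <- NA_character_
  nodes$id <- as.character(nodes$id)
  nodes$label <- as.character(nodes$label)
  nodes$score <- as.numeric(nodes$score)
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(nodes$score) & !is.finite(nodes$score))) {
    stop("node scores must be finite (or NA)", call. = FALSE)
  }
  ids <- nodes$id

  if (is.null(interactions) || NROW(interactions) == 0L) {
    interactions <- data.frame(a = character(), b = character(),
                               stringsAsFactors = FALSE)
  } else {
    interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
    names(interactions)[1:2] <- c("a", "b")
    interactions$a <- as.character(interactions$a)
    interactions$b <- as.character(interactions$b)
    unknown <- setdiff(c(interactions$a, interactions$b), ids)
    if (length(unknown)) {
      stop("interaction endpoint(s) not in node table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(interactions$a == interactions$b)) {
      stop("self-interactions are not allowed (node ",
           interactions$a[interactions$a == interactions$b][1L], ")",
           call. = FALSE)
    }
    # canonical unordered form, first occurrence kept => stable component order
    key <- ifelse(interactions$a < interactions$b,
                  paste(interactions$a, interactions$b, sep = "\r"),
                  paste(interactions$b, interactions$a, sep = "\r"))
    interactions <- interactions[!duplicated(key), c("a", "b"), drop = FALSE]
    rownames(interactions) <- NULL
  }

  if (!is.list(sets)) stop("sets must be a list of annotation_set objects",
                           call. = FALSE)
  set_ids <- vapply(sets, function(s) {
    if (!inherits(s, "annotation_set"))
      stop("sets must be annotation_set objects", call. = FALSE)
    s$id
  }, "")
  if (anyDuplicated(set_ids)) {
    stop("duplicate set id(s): ",
         paste(unique(set_ids[duplicated(set_ids)]), collapse = ", "),
         call. = FALSE)
  }
  names(sets) <- set_ids
  for (s in sets) {
    unknown <- setdiff(s$members, ids)
    if (length(unknown)) {
      stop("set '", s$id, "' references unknown node id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  active <- as.character(active)
  if (anyDuplicated(active)) active <- unique(active)
  missing_active <- setdiff(active, set_ids)
  if (length(missing_active)) {
    stop("active selection names unknown set id(s): ",
         paste(missing_active, collapse = ", "), call. = FALSE)
  }

  structure(
    list(nodes = nodes, interactions = interactions, sets = sets,
         active = active),
    class = "annotated_module"
  )
}

#' @export
print.annotated_module <- function(x, ...) {
  cat("annotated module: ", nrow(x$nodes), " nodes, ",
      nrow(x$interactions), " interactions, ",
      length(x$sets), " sets (", length(x$active), " active)\n", sep = "")
  invisible(x)
}

#' Component ids of the membership space
#'
#' Components are ordered interactions-first (input order), then active sets
#' (selection order); this order is what fixes reproducibility of the
#' encoding and of everything trained from it.
#'
#' @param module An `annotated_module`.
#' @return Character vector of component ids: `"a--b"` for interactions,
#'   set ids for active sets.
#' @keywords internal
component_ids <- function(module) {
  ia <- module$interactions
  c(if (nrow(ia)) paste(ia$a, ia$b, sep = "--") else character(),
    module$active)
}

#' Encode a module as weighted membership vectors
#'
#' Every node t receives a vector t = (t_1, ..., t_M) over the M = |E| + |A|
#' components (interactions in input order, then active sets in selection
#' order), with t_i = w_i if the node belongs to component i and 0 otherwise.
#' Interactions always carry weight 1; annotation sets carry their dominance
#' weight. These vectors are the training items of the layout SOM, putting
#' binary and n-ary edges on equal terms.
#'
#' @param module An `annotated_module`.
#' @return Numeric matrix, one row per node (rownames = node ids), one column
#'   per component (colnames = [component_ids()]), with attributes
#'   `weights` (per-component weight) and `component` (`"interaction"` /
#'   `"set"`).
#' @export
encode <- function(module) {
  stopifnot(inherits(module, "annotated_module"))
  ids <- module$nodes$id
  ia <- module$interactions
  n_e <- nrow(ia)
  n_s <- length(module$active)
  M <- n_e + n_s
  mat <- matrix(0, nrow = length(ids), ncol = M,
                dimnames = list(ids, component_ids(module)))
  w <- numeric(M)
  kind <- character(M)
  if (n_e) {
    for (i in seq_len(n_e)) {
      mat[c(ia$a[i], ia$b[i]), i] <- 1
    }
    w[seq_len(n_e)] <- 1
    kind[seq_len(n_e)] <- "interaction"
  }
  if (n_s) {
    for (j in seq_len(n_s)) {
      s <- module$sets[[module$active[j]]]
      if (length(s$members)) mat[s$members, n_e + j] <- s$weight
      w[n_e + j] <- s$weight
      kind[n_e + j] <- "set"
    }
  }
  attr(mat, "weights") <- w
  attr(mat, "component") <- kind
  mat
}

#' Set the dominance weight of an annotation set
#'
#' Dominance weights scale a set's component in the membership vectors, so a
#' heavier set plays a larger role in the cosine distance and its members are
#' drawn together in the layout. Weight 0 removes the set's influence
#' entirely, leaving the network topology (and other sets) to define the
#' layout.
#'
#' @param module An `annotated_module`.
#' @param set_id Id of the set to reweight.
#' @param weight New non-negative weight.
#' @return The updated module.
#' @export
set_weight <- function(module, set_id, weight) {
  stopifnot(inherits(module, "annotated_module"))
  if (!set_id %in% names(module$sets)) {
    stop("unknown set id: ", set_id, call. = FALSE)
  }
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
      weight < 0) {
    stop("weight must be a non-negative number", call. = FALSE)
  }
  module$sets[[set_id]]$weight <- as.numeric(weight)
  module
}

#' Select the active annotation sets
#'
#' Only active sets contribute components to the encoding; toggling a set
#' changes the dimension M of the membership space.
#'
#' @param module An `annotated_module`.
#' @param active Character vector of set ids, in display order.
#' @return The updated module.
#' @export
set_active <- function(module, active) {
  build_module(module$nodes, module$interactions, module$sets, active)
}

#' The six-gene worked example module
#'
#' A small KEGG-derived module of interacting proteins used throughout the
#' documentation: Calm1, Calm2, Calm3, Kras, Nr3c2 and Plcb4, seven
#' interactions, and three overlapping pathway sets (Glioma, Long-term
#' potentiation, GnRH signaling pathway), all active. Kras and Plcb4 have
#' further interactions outside this module; those are not part of it.
#'
#' @param p_values Named numeric vector of per-set p-values; defaults to 1
#'   for all three pathways (the worked example does not fix them).
#' @return An `annotated_module` with 6 nodes, 7 interactions and 3 active
#'   sets, hence a 10-dimensional membership space.
#' @export
example_module <- function(p_values = c(glioma = 1, ltp = 1, gnrh = 1)) {
  v <- c("Calm1", "Calm2", "Calm3", "Kras", "Nr3c2", "Plcb4")
  nodes <- data.frame(
    id = v, label = v,
    score = c(-0.9, -0.5, -0.7, 1.2, 0.4, -1.1),  # illustrative expression
    url = NA_character_, stringsAsFactors = FALSE
  )
  # S1..S7 with v1..v6 = Calm1, Calm2, Calm3, Kras, Nr3c2, Plcb4
  interactions <- data.frame(
    a = v[c(1, 1, 2, 2, 3, 3, 4)],
    b = v[c(4, 6, 4, 6, 4, 6, 5)],
    stringsAsFactors = FALSE
  )
  sets <- list(
    annotation_set("glioma", members = v[1:4], label = "Glioma",
                   category = "pathway", p_value = unname(p_values["glioma"])),
    annotation_set("ltp", members = v[c(1, 2, 3, 4, 6)],
                   label = "Long-term potentiation", category = "pathway",
                   p_value = unname(p_values["ltp"])),
    annotation_set("gnrh", members = v[c(1, 2, 3, 4, 6)],
                   label = "GnRH signaling pathway", category = "pathway",
                   p_value = unname(p_values["gnrh"]))
  )
  build_module(nodes, interactions, sets, active = c("glioma", "ltp", "gnrh"))
}
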