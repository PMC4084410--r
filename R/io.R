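stop_at <- function(path, line, msg) {
  stop(path, ":", line, ": ", msg, call. = FALSE)
}

#' Read a node table
#'
#' Tab-separated with a header; required columns `id` and `label`, optional
#' `score` (signed differential-expression statistic) and `url`.
#'
#' @param path File path.
#' @return Data frame with columns `id`, `label`, `score`, `url`.
#' @export
read_node_table <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                      comment.char = ""),
    error = function(e) stop(path, ": ", conditionMessage(e), call. = FALSE)
  )
  if (!"id" %in% names(df)) stop_at(path, 1L, "missing 'id' column in header")
  if (!"label" %in% names(df)) df$label <- df$id
  if (!"score" %in% names(df)) df$score <- NA_real_
  if (!"url" %in% names(df)) df$url <- NA_character_
  df$url <- as.character(df$url)
  df$url[is.na(df$url) | !nzchar(df$url)] <- NA_character_
  bad <- which(!nzchar(df$id))
  if (length(bad)) stop_at(path, bad[1L] + 1L, "empty node id")
  df$score <- suppressWarnings(as.numeric(df$score))
  df[, c("id", "label", "score", "url")]
}

#' Read an interaction list
#'
#' Accepts SIF (`A <relation> B [C ...]`, whitespace- or tab-separated, one
#' source per line with one or more targets) or a headerless 2-column TSV
#' of node-id pairs. Lines with a single field are an error.
#'
#' @param path File path.
#' @param format `"auto"` (default), `"sif"` or `"tsv"`.
#' @return Data frame with columns `a`, `b`.
#' @export
read_edges <- function(path, format = c("auto", "sif", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  a <- character(); b <- character()
  for (ln in keep) {
    fields <- strsplit(trimws(lines[ln]), "[ \t]+")[[1L]]
    nf <- length(fields)
    fmt <- if (format == "auto") {
      if (nf >= 3L) "sif" else "tsv"
    } else format
    if (fmt == "sif") {
      if (nf < 3L) stop_at(path, ln, "SIF line needs source, relation and at least one target")
      a <- c(a, rep(fields[1L], nf - 2L))
      b <- c(b, fields[3:nf])
    } else {
      if (nf != 2L) stop_at(path, ln, paste0("expected 2 fields, found ", nf))
      a <- c(a, fields[1L])
      b <- c(b, fields[2L])
    }
  }
  data.frame(a = a, b = b, stringsAsFactors = FALSE)
}

#' Read GMT set memberships
#'
#' The de facto gene-set format: one set per line, tab-separated as
#' `set id<TAB>description<TAB>member1<TAB>member2...`. A line with only id
#' and description is accepted as an empty set, with a warning.
#'
#' @param path File path.
#' @return Named list of character member vectors, with the descriptions in
#'   attribute `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sets <- list()
  descs <- character()
  for (ln in seq_along(lines)) {
    if (!nzchar(trimws(lines[ln]))) next
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L) stop_at(path, ln, "GMT line needs at least id and description")
    id <- fields[1L]
    if (id %in% names(sets)) stop_at(path, ln, paste0("duplicate set id '", id, "'"))
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) {
      warning(path, ":", ln, ": set '", id, "' has no members", call. = FALSE)
    }
    sets[[id]] <- members
    descs[id] <- fields[2L]
  }
  attr(sets, "description") <- descs
  sets
}

#' Read a long-format set membership table
#'
#' Alternative to GMT: a headered TSV with columns `set_id` and `node_id`.
#'
#' @param path File path.
#' @return Named list of member vectors (no descriptions).
#' @export
read_set_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (!all(c("set_id", "node_id") %in% names(df))) {
    stop_at(path, 1L, "need 'set_id' and 'node_id' columns")
  }
  out <- split(df$node_id, factor(df$set_id, levels = unique(df$set_id)))
  lapply(out, as.character)
}

#' Read set metadata
#'
#' Headered TSV with columns `id`, `category`, `p_value`, optionally
#' `label`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_set_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("id", "category", "p_value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_at(path, 1L, paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  df$p_value <- suppressWarnings(as.numeric(df$p_value))
  bad <- which(is.na(df$p_value) | df$p_value <= 0 | df$p_value > 1)
  if (length(bad)) stop_at(path, bad[1L] + 1L, "p_value must lie in (0, 1]")
  df
}

#' Assemble an annotated module from standard input files
#'
#' @param node_table Path to the TSV node table ([read_node_table()]).
#' @param edge_file Path to the SIF or 2-column TSV interaction list.
#' @param gmt_file Path to the GMT (or long-format TSV, detected by the
#'   `.tsv` extension) set memberships.
#' @param set_meta Optional path to the set metadata TSV; sets without
#'   metadata get p-value 1 and category `"uncategorized"`.
#' @param active Character vector of active set ids; default all sets.
#' @return A validated `annotated_module`.
#' @export
read_module <- function(node_table, edge_file, gmt_file, set_meta = NULL,
                        active = NULL) {
  nodes <- read_node_table(node_table)
  edges <- read_edges(edge_file)
  memb <- if (grepl("\\.tsv$", gmt_file, ignore.case = TRUE)) {
    read_set_table(gmt_file)
  } else {
    read_gmt(gmt_file)
  }
  descs <- attr(memb, "description")
  meta <- if (!is.null(set_meta)) read_set_meta(set_meta) else NULL
  sets <- lapply(names(memb), function(id) {
    label <- if (!is.null(descs) && !is.na(descs[id]) && nzchar(descs[id])) {
      descs[[id]]
    } else id
    category <- "uncategorized"
    p <- 1
    weight <- 1
    if (!is.null(meta) && id %in% meta$id) {
      row <- meta[match(id, meta$id), ]
      category <- row$category
      p <- row$p_value
      if ("label" %in% names(meta) && !is.na(row$label)) label <- row$label
      if ("weight" %in% names(meta) && !is.na(row$weight)) weight <- row$weight
    }
    annotation_set(id, members = memb[[id]], label = label,
                   category = category, p_value = p, weight = weight)
  })
  if (is.null(active)) {
    if (!is.null(meta) && "active_rank" %in% names(meta)) {
      sel <- meta[!is.na(meta$active_rank) & meta$active_rank > 0, ]
      active <- sel$id[order(sel$active_rank)]
    } else {
      active <- names(memb)
    }
  }
  build_module(nodes, edges, sets, active = active)
}

#' Write an annotated module as standard files
#'
#' Emits `<prefix>_nodes.tsv`, `<prefix>_edges.sif`, `<prefix>_sets.gmt`
#' and `<prefix>_set_meta.tsv`; [read_module()] on these reproduces the
#' module.
#'
#' @param module An `annotated_module`.
#' @param prefix Output path prefix.
#' @return Invisibly, the named vector of written paths.
#' @export
write_module <- function(module, prefix) {
  stopifnot(inherits(module, "annotated_module"))
  paths <- c(nodes = paste0(prefix, "_nodes.tsv"),
             edges = paste0(prefix, "_edges.sif"),
             sets = paste0(prefix, "_sets.gmt"),
             meta = paste0(prefix, "_set_meta.tsv"))
  utils::write.table(module$nodes, paths["nodes"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  sif <- vapply(seq_len(nrow(module$interactions)), function(i) {
    paste(module$interactions$a[i], "interacts", module$interactions$b[i],
          sep = "\t")
  }, "")
  writeLines(sif, paths["edges"])
  gmt <- vapply(module$sets, function(s) {
    paste(c(s$id, s$label, s$members), collapse = "\t")
  }, "")
  writeLines(unname(gmt), paths["sets"])
  meta <- data.frame(
    id = vapply(module$sets, `[[`, "", "id"),
    label = vapply(module$sets, `[[`, "", "label"),
    category = vapply(module$sets, `[[`, "", "category"),
    p_value = vapply(module$sets, `[[`, 0, "p_value"),
    weight = vapply(module$sets, `[[`, 0, "weight"),
    active_rank = match(vapply(module$sets, `[[`, "", "id"), module$active,
                        nomatch = 0L),
    stringsAsFactors = FALSE
  )
  utils::write.table(meta, paths["meta"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
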