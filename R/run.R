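#' Configuration of a layout run
#'
#' Collects every knob of the pipeline in one validated object: grid-size
#' policy, training schedule, warm/cold strengths, contour geometry, the
#' active-set selection and per-set dominance weights, and the run seed
#' that all randomness flows from.
#'
#' @param seed Integer seed; mandatory for layout runs.
#' @param iterations Epoch count I; `NULL` (default) uses
#'   [default_iterations()] of the node count.
#' @param grid_policy `"side"` (side N = 2 |T|) or `"cells"` (about 2 |T|
#'   cells in total).
#' @param grid_cap Upper bound on the grid side (default 64).
#' @param strength_cold,strength_warm Initial training strengths c for cold
#'   and warm starts (defaults 0.5 and 0.01).
#' @param tile,tau,r,delta,e,arc_tol Contour geometry, see
#'   [geometry_params()].
#' @param active Optional character vector overriding the module's active
#'   selection.
#' @param weights Optional named numeric vector of per-set dominance
#'   weights.
#' @param style A [default_style()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed, iterations = NULL,
                       grid_policy = c("side", "cells"), grid_cap = 64L,
                       strength_cold = 0.5, strength_warm = 0.01,
                       tile = 1, tau = 0.5, r = 0.15 * tile,
                       delta = 0.05 * tile, e = 0.12 * tile,
                       arc_tol = 1e-3 * tile^2,
                       active = NULL, weights = NULL,
                       style = default_style()) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("a seed is mandatory for layout runs", call. = FALSE)
  }
  grid_policy <- match.arg(grid_policy)
  stopifnot(is.null(iterations) || iterations >= 1,
            grid_cap >= 2,
            strength_cold > 0, strength_cold < 1,
            strength_warm > 0, strength_warm < 1)
  geometry <- geometry_params(tile = tile, tau = tau, r = r, delta = delta,
                              e = e, arc_tol = arc_tol)
  structure(
    list(seed = as.integer(seed),
         iterations = if (is.null(iterations)) NULL else as.integer(iterations),
         grid_policy = grid_policy, grid_cap = as.integer(grid_cap),
         strength_cold = strength_cold, strength_warm = strength_warm,
         geometry = geometry, active = active, weights = weights,
         style = style),
    class = "run_config"
  )
}

# Tiny FNV-1a over the serialized config: a stable fingerprint for the
# provenance block, not a cryptographic hash.
config_hash <- function(config) {
  keep <- config[c("seed", "iterations", "grid_policy", "grid_cap",
                   "strength_cold", "strength_warm", "geometry", "active",
                   "weights")]
  keep$geometry <- unclass(keep$geometry)
  bytes <- utf8ToInt(jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Lay out, contour and render an annotated module
#'
#' The full pipeline: apply the config's active selection and dominance
#' weights, encode the module, train the reservation-based SOM, derive the
#' set contours, and render the SVG. Optionally writes a layout JSON
#' (positions, grid side, per-set polygon coordinates, colors, z-order,
#' and a provenance block with the seed and a config fingerprint) and the
#' SVG document. Per-stage timings and the schedule are reported via
#' `message()`.
#'
#' @param module An `annotated_module`.
#' @param config A [run_config()].
#' @param out_json,out_svg Optional output paths.
#' @param grid Optional `neuron_grid` for a warm start (layout
#'   preservation); trained with `strength_warm`.
#' @param quiet Suppress progress messages.
#' @return List with `layout`, `grid`, `contours`, `colors`, `svg` (the
#'   document string) and `json` (the layout-JSON string).
#' @export
run_module <- function(module, config, out_json = NULL, out_svg = NULL,
                       grid = NULL, quiet = FALSE) {
  stopifnot(inherits(module, "annotated_module"),
            inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  if (!is.null(config$active)) module <- set_active(module, config$active)
  if (!is.null(config$weights)) {
    for (id in names(config$weights)) {
      if (!id %in% module$active) {
        warning("dominance weight for inactive set '", id, "' ignored",
                call. = FALSE)
        next
      }
      module <- set_weight(module, id, config$weights[[id]])
    }
  }

  mat <- encode(module)
  n_items <- nrow(mat)
  iterations <- if (is.null(config$iterations)) {
    default_iterations(n_items)
  } else config$iterations
  warm <- !is.null(grid)
  side <- if (warm) grid$side else {
    grid_side(n_items, config$grid_policy, config$grid_cap)
  }
  strength <- if (warm) config$strength_warm else config$strength_cold
  say(sprintf("training: %d items, M = %d, grid %dx%d, I = %d, c = %g (%s start)",
              n_items, ncol(mat), side, side, iterations, strength,
              if (warm) "warm" else "cold"))

  t0 <- proc.time()[["elapsed"]]
  trained <- rsom_train(mat, side = side, iterations = iterations,
                        strength = strength, grid = grid,
                        seed = config$seed)
  t1 <- proc.time()[["elapsed"]]
  say(sprintf("training took %.2f s", t1 - t0))

  contours <- set_contours(trained$grid, trained$layout, module,
                           config$geometry)
  t2 <- proc.time()[["elapsed"]]
  say(sprintf("contours took %.2f s", t2 - t1))

  colors <- assign_colors(module$active, config$style)
  svg <- render_svg(module, trained$layout, contours, config$style)
  t3 <- proc.time()[["elapsed"]]
  say(sprintf("rendering took %.2f s", t3 - t2))

  json <- layout_json(module, trained$layout, contours, colors, config)
  if (!is.null(out_json)) {
    con <- file(out_json, open = "wb")
    writeBin(charToRaw(json), con)
    close(con)
  }
  if (!is.null(out_svg)) {
    con <- file(out_svg, open = "wb")
    writeBin(charToRaw(svg), con)
    close(con)
  }
  list(layout = trained$layout, grid = trained$grid, contours = contours,
       colors = colors, svg = svg, json = json)
}

# full precision: the JSON must re-render to the byte-identical SVG
ps_to_coords <- function(ps) {
  lapply(ps, function(r) list(x = r$x, y = r$y))
}

coords_to_ps <- function(coords) {
  lapply(coords, function(r) list(x = as.numeric(r$x), y = as.numeric(r$y)))
}

# The layout JSON is the interchange surface between layout and render:
# it carries everything needed to re-render without retraining.
layout_json <- function(module, layout, contours, colors, config) {
  doc <- list(
    schema = "somset-layout/1",
    provenance = list(seed = config$seed, config_hash = config_hash(config),
                      package_version = as.character(
                        utils::packageVersion("somset"))),
    grid = list(side = attr(layout, "side"), tile = attr(layout, "tile")),
    nodes = module$nodes,
    interactions = module$interactions,
    sets = lapply(unname(module$sets), function(s) {
      s[c("id", "label", "category", "p_value", "members", "weight")]
    }),
    active = module$active,
    positions = data.frame(id = layout$id, x = layout$x, y = layout$y),
    contours = lapply(contours, function(ct) {
      list(set_id = ct$set_id, z = ct$z, color = colors[[ct$set_id]],
           body = ps_to_coords(ct$body), eroded = ps_to_coords(ct$eroded),
           ribbon = ps_to_coords(ct$ribbon))
    })
  )
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, na = "null",
                   pretty = TRUE)
}

#' Re-render an SVG from an emitted layout JSON
#'
#' Reads the interchange JSON written by [run_module()] and rebuilds the
#' figure without retraining, so layout and rendering can be run (and
#' tested) in isolation.
#'
#' @param json_path Path to the layout JSON.
#' @param svg_path Optional output path for the SVG.
#' @param style A [default_style()].
#' @return The SVG document string (invisibly when `svg_path` is given).
#' @export
render_from_json <- function(json_path, svg_path = NULL,
                             style = default_style()) {
  doc <- jsonlite::fromJSON(json_path, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  sets <- lapply(seq_len(nrow(doc$sets)), function(i) {
    row <- doc$sets[i, ]
    annotation_set(row$id, members = unlist(row$members), label = row$label,
                   category = row$category, p_value = row$p_value,
                   weight = row$weight)
  })
  module <- build_module(doc$nodes, doc$interactions, sets,
                         active = doc$active)
  layout <- doc$positions
  attr(layout, "side") <- as.integer(doc$grid$side)
  attr(layout, "tile") <- as.numeric(doc$grid$tile)
  class(layout) <- c("module_layout", "data.frame")
  raw <- jsonlite::fromJSON(json_path, simplifyVector = FALSE)
  contours <- lapply(raw$contours, function(ct) {
    structure(list(set_id = ct$set_id,
                   body = coords_to_ps(ct$body),
                   eroded = coords_to_ps(ct$eroded),
                   ribbon = coords_to_ps(ct$ribbon),
                   z = ct$z),
              class = "set_contour")
  })
  svg <- render_svg(module, layout, contours, style, file = svg_path)
  if (!is.null(svg_path)) invisible(svg) else svg
}
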