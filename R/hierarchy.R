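HIERARCHY_LAYERS <- c("biomarker", "match_type", "drug_class", "drug",
                      "cancer_type", "evidence_level", "response", "citation")

# one categorical value per treatment row for a named layer
layer_value <- function(treatments, layer) {
  switch(layer,
    biomarker = dplyr::coalesce(treatments$biomarker, "unknown"),
    match_type = as.character(treatments$match_type),
    drug_class = map_chr(treatments$drug_classes,
                         ~ paste(sort(unique(.x)), collapse = ";")),
    drug = map_chr(treatments$drugs, ~ paste(sort(.x), collapse = ";")),
    cancer_type = dplyr::coalesce(treatments$cancer_type_main, "Unmatched"),
    evidence_level = dplyr::coalesce(treatments$amp_tier, "unset"),
    response = treatments$response,
    citation = dplyr::coalesce(treatments$citation_id, "uncited")
  )
}

#' Aggregate matched treatments into a sunburst hierarchy
#'
#' Groups treatments along an ordered sequence of categorical layers (as
#' drawn in sunburst visualizations: inner to outer ring). The leaf layer
#' is always the citation ID; it is appended when not named. Every node
#' carries the number of underlying treatments, so the sum of leaf counts
#' equals the number of treatments for any layer order.
#'
#' @param treatments Matched-treatment tibble from
#'   [build_treatment_table()].
#' @param layer_order Character vector drawn from `biomarker`,
#'   `match_type`, `drug_class`, `drug`, `cancer_type`, `evidence_level`,
#'   `response`, `citation`.
#' @return An object of class `treatment_hierarchy`: a nested list of
#'   nodes `(label, layer, count, children)`; leaves carry `citation_ids`.
#' @export
build_hierarchy <- function(treatments,
                            layer_order = c("match_type", "drug",
                                            "evidence_level", "citation")) {
  unknown <- setdiff(layer_order, HIERARCHY_LAYERS)
  if (length(unknown) > 0) {
    otr_error(paste0("unknown layer(s): ", paste(unknown, collapse = ", "),
                     "; valid layers are: ",
                     paste(HIERARCHY_LAYERS, collapse = ", ")),
              "oncotherapyr_layer_error")
  }
  if (length(layer_order) == 0 || layer_order[length(layer_order)] != "citation") {
    layer_order <- c(setdiff(layer_order, "citation"), "citation")
  }
  vals <- map(layer_order, layer_value, treatments = treatments)
  names(vals) <- layer_order
  idx <- seq_len(nrow(treatments))

  nest <- function(rows, depth) {
    if (depth > length(layer_order)) return(NULL)
    layer <- layer_order[depth]
    v <- vals[[layer]][rows]
    map(sort(unique(v)), function(lbl) {
      sub <- rows[v == lbl]
      node <- list(label = lbl, layer = layer, count = length(sub))
      if (depth == length(layer_order)) {
        node$citation_ids <- sort(unique(
          dplyr::coalesce(treatments$citation_id[sub], "uncited")))
      } else {
        node$children <- nest(sub, depth + 1)
      }
      node
    })
  }
  structure(
    list(layers = layer_order, n_treatments = nrow(treatments),
         children = nest(idx, 1)),
    class = "treatment_hierarchy"
  )
}

#' @method print treatment_hierarchy
#' @export
print.treatment_hierarchy <- function(x, ...) {
  cat("<treatment_hierarchy> ", x$n_treatments, " treatments, layers: ",
      paste(x$layers, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Serialize a treatment hierarchy to nested JSON
#'
#' Produces a nested JSON document consumable by any sunburst renderer.
#'
#' @param hierarchy A [build_hierarchy()] result.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly the path when `path` is given).
#' @export
hierarchy_to_json <- function(hierarchy, path = NULL) {
  js <- jsonlite::toJSON(unclass(hierarchy), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

# flattened view used by tidy() and autoplot()
flatten_hierarchy <- function(hierarchy) {
  walk_node <- function(node, depth, parent) {
    here <- tibble(depth = depth, layer = node$layer, label = node$label,
                   count = node$count, parent = parent)
    kids <- map(node$children %||% list(), walk_node, depth = depth + 1,
                parent = node$label)
    bind_rows(here, kids)
  }
  bind_rows(map(hierarchy$children, walk_node, depth = 1, parent = NA_character_))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Flatten a treatment hierarchy into a tibble
#'
#' @param x A `treatment_hierarchy`.
#' @param ... Unused.
#' @return Tibble with one row per node: `depth`, `layer`, `label`,
#'   `count`, `parent`.
#' @export
tidy.treatment_hierarchy <- function(x, ...) flatten_hierarchy(x)

#' Sunburst-style plot of a treatment hierarchy
#'
#' Draws the nested rings (one ring per layer, segment arc proportional to
#' treatment count) with ggplot2's polar coordinates.
#'
#' @param object A `treatment_hierarchy`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.treatment_hierarchy <- function(object, ...) {
  nodes <- flatten_hierarchy(object)
  # assign angular extents by depth-first walk
  seg <- nodes |>
    group_by(.data$depth) |>
    mutate(xmax = cumsum(.data$count), xmin = .data$xmax - .data$count) |>
    ungroup()
  ggplot2::ggplot(seg) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$depth, ymax = .data$depth + 0.9,
                                    fill = .data$layer),
                       colour = "white", linewidth = 0.3) +
    ggplot2::coord_polar() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "layer",
                  title = paste(object$layers, collapse = " > "))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
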