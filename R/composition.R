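#' Morphological composition per stratum
#'
#' Counts and proportions of predicted morphological classes per
#' region x layer stratum (configurable grouping). Excluded cells
#' (certainty filter) are counted per stratum but removed from the
#' proportion denominators. Strata with zero non-excluded cells are
#' flagged empty.
#'
#' @param records Data frame with a prediction column and, unless every
#'   cell was predicted, an `excluded` logical column.
#' @param by Grouping columns (default `c("region", "layer")`).
#' @param prediction Column holding the class prediction (default
#'   `"predicted_nn"`, falling back to `"predicted_rule"` or `"label"`
#'   if absent).
#' @return A `soma_composition` tibble, one row per stratum x class:
#'   grouping columns, `cell_type`, `n`, `proportion`, plus per-stratum
#'   `n_excluded`, `n_total` and `empty`.
#' @export
build_composition <- function(records, by = c("region", "layer"),
                              prediction = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(prediction)) {
    prediction <- intersect(c("predicted_nn", "predicted_rule", "label"),
                            names(records))[1]
    if (is.na(prediction)) abort("no prediction column found")
  }
  stopifnot(all(by %in% names(records)), prediction %in% names(records))
  rec <- as_tibble(records)
  if (!"excluded" %in% names(rec)) rec$excluded <- FALSE
  if (any(!rec$excluded & is.na(rec[[prediction]]))) {
    abort("every non-excluded record needs a prediction")
  }
  strata <- rec |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_excluded = sum(.data$excluded),
      .groups = "drop"
    )
  counts <- rec |>
    dplyr::filter(!.data$excluded) |>
    dplyr::mutate(cell_type = as_cell_type(.data[[prediction]])) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by)), .data$cell_type,
                    .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop_last") |>
    dplyr::mutate(.total = sum(.data$n),
                  proportion = dplyr::if_else(.data$.total > 0,
                                              .data$n / .data$.total,
                                              NA_real_)) |>
    dplyr::ungroup() |>
    dplyr::select(-".total")
  out <- counts |>
    dplyr::inner_join(strata, by = by) |>
    dplyr::mutate(empty = .data$n_total - .data$n_excluded == 0)
  class(out) <- c("soma_composition", class(out))
  out
}

# Super-class membership for the ternary summary.
PYRAMIDAL_TYPES <- c("small_pyramidal", "medium_pyramidal",
                     "large_pyramidal", "gigantic_pyramidal")
FUSIFORM_TYPES <- c("small_fusiform", "large_fusiform")

#' Ternary coordinates of the granule/pyramidal/fusiform balance
#'
#' Collapses a composition to the three principal classes (pyramidal and
#' fusiform size subtypes summed), renormalizes the triple to sum to 1
#' (polymorphic cells drop out of the denominator) and adds the 2D
#' Cartesian coordinates of the standard ternary diagram
#' (granule, pyramidal and fusiform corners).
#'
#' @param composition A `soma_composition`.
#' @return Tibble with the grouping columns, `granule`, `pyramidal`,
#'   `fusiform` proportions and plot coordinates `tx`, `ty`.
#' @export
ternary_coords <- function(composition) {
  stopifnot(inherits(composition, "soma_composition") ||
              is.data.frame(composition))
  by <- setdiff(names(composition),
                c("cell_type", "n", "proportion", "n_excluded", "n_total", "empty"))
  out <- composition |>
    dplyr::mutate(super = dplyr::case_when(
      .data$cell_type == "granule" ~ "granule",
      .data$cell_type %in% PYRAMIDAL_TYPES ~ "pyramidal",
      .data$cell_type %in% FUSIFORM_TYPES ~ "fusiform",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$super)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by)), .data$super) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop_last") |>
    dplyr::mutate(p = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "super", values_from = "p",
                       values_fill = 0)
  for (cl in c("granule", "pyramidal", "fusiform")) {
    if (!cl %in% names(out)) out[[cl]] <- 0
  }
  # corners: granule (0,0), pyramidal (1,0), fusiform (1/2, sqrt(3)/2)
  out |>
    dplyr::mutate(tx = .data$pyramidal + 0.5 * .data$fusiform,
                  ty = sqrt(3) / 2 * .data$fusiform)
}

#' Radar (spider) coordinates over the seven observed classes
#'
#' Per-stratum proportion vector over the seven non-gigantic classes,
#' with the polar angle of each class axis, ready for a radar chart.
#'
#' @param composition A `soma_composition`.
#' @return Long tibble: grouping columns, `cell_type`, `proportion`,
#'   `angle`.
#' @export
radar_coords <- function(composition) {
  classes <- setdiff(CELL_TYPES, "gigantic_pyramidal")
  out <- composition |>
    dplyr::filter(.data$cell_type %in% classes) |>
    dplyr::mutate(
      cell_type = factor(as.character(.data$cell_type), levels = classes),
      angle = 2 * pi * (as.integer(.data$cell_type) - 1) / length(classes)
    )
  out
}

#' Ternary diagram of regional/laminar composition
#' @param composition A `soma_composition` built per region (and
#'   optionally layer).
#' @param colour Column mapped to point colour (default first grouping
#'   column).
#' @return A ggplot object.
#' @export
plot_ternary <- function(composition, colour = NULL) {
  tc <- ternary_coords(composition)
  by <- setdiff(names(tc), c("granule", "pyramidal", "fusiform", "tx", "ty"))
  colour <- colour %||% by[1]
  tri <- tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  lab <- tibble(x = c(-0.04, 1.04, 0.5), y = c(-0.04, -0.04, sqrt(3) / 2 + 0.05),
                text = c("granule", "pyramidal", "fusiform"))
  ggplot2::ggplot(tc, ggplot2::aes(.data$tx, .data$ty)) +
    ggplot2::geom_path(data = tri, ggplot2::aes(.data$x, .data$y),
                       inherit.aes = FALSE, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 2) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(.data$x, .data$y, label = .data$text),
                       inherit.aes = FALSE, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Radar diagram of per-stratum class proportions
#' @param composition A `soma_composition`.
#' @return A ggplot object (polar coordinates, one panel per stratum
#'   combination when grouped).
#' @export
plot_radar <- function(composition) {
  rc <- radar_coords(composition)
  by <- setdiff(names(rc),
                c("cell_type", "n", "proportion", "n_excluded", "n_total",
                  "empty", "angle"))
  p <- ggplot2::ggplot(rc, ggplot2::aes(.data$cell_type, .data$proportion,
                                        group = 1)) +
    ggplot2::geom_polygon(fill = "steelblue", alpha = 0.3, colour = "steelblue") +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 7))
  if (length(by) > 0) {
    p <- p + ggplot2::facet_wrap(by)
  }
  p
}

#' @export
autoplot.soma_composition <- function(object, ...) plot_radar(object)
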