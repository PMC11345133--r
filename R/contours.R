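#' Build a contour table from vertex polygons
#'
#' A contour table (`soma_contours`) is a tibble with one row per cell:
#' columns `id`, `subject`, `region`, `layer`, an optional ground-truth
#' `label`, and a `vertices` list-column of n x 2 matrices (coordinates
#' in micrometres, free-standing 2D Cartesian, no image origin implied).
#' On construction every polygon is checked (>= 3 distinct vertices,
#' simple, non-degenerate), duplicate consecutive vertices are removed
#' (1e-9 um tolerance) and winding is normalized to counterclockwise.
#'
#' @param vertices A list of n x 2 numeric matrices (or a single matrix).
#' @param id,subject Character vectors (recycled); ids default to `cell_<i>`.
#' @param region Cortical region; one of `"BA9"`, `"BA14r"`, `"BA24"`,
#'   anything else is kept as `"other"`.
#' @param layer Cortical layer `"I"`..`"VI"` or `"unknown"`.
#' @param label Optional ground-truth morphological class.
#' @param validate If `FALSE`, skip the O(n^2) self-intersection check
#'   (used internally for shapes that are simple by construction).
#' @return A `soma_contours` tibble.
#' @export
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' contour_table(list(sq), region = "BA9", layer = "III")
contour_table <- function(vertices, id = NULL, subject = "subj1",
                          region = "other", layer = "unknown",
                          label = NA_character_, validate = TRUE) {
  if (is.matrix(vertices)) vertices <- list(vertices)
  n <- length(vertices)
  if (is.null(id)) id <- paste0("cell_", seq_len(n))
  vertices <- purrr::map(vertices, normalize_polygon, validate = validate)
  out <- tibble(
    id = as.character(rep_len(id, n)),
    subject = as.character(rep_len(subject, n)),
    region = as_region(rep_len(region, n)),
    layer = as_layer(rep_len(layer, n)),
    label = as_cell_type(rep_len(label, n)),
    vertices = vertices
  )
  class(out) <- c("soma_contours", class(out))
  out
}

#' Compute the ten morphometric descriptors of soma contours
#'
#' For each contour computes Perimeter, Area, Feret Max, Feret Min,
#' Aspect Ratio (= Feret Max / Feret Min), Compactness
#' (= sqrt(4 Area / pi) / Feret Max, the diameter of the area-equivalent
#' circle relative to the longest caliper diameter), Convexity
#' (= hull perimeter / perimeter), Form Factor (= 4 pi Area / Perimeter^2),
#' Roundness (= Compactness^2 = 4 Area / (pi Feret Max^2)) and Solidity
#' (= Area / convex hull Area).
#'
#' All descriptors are invariant under rotation and translation; the four
#' ratio descriptors and Aspect Ratio are additionally scale-invariant.
#' Form Factor, Convexity, Solidity and Roundness lie in (0, 1] for any
#' simple polygon and equal 1 in the circle limit; Aspect Ratio >= 1.
#'
#' @param contours A `soma_contours` tibble (see [contour_table()]), or any
#'   data frame with a `vertices` list-column.
#' @return A `soma_features` tibble: the metadata columns of `contours`
#'   (minus `vertices`) plus the ten descriptor columns
#'   `perimeter_um`, `area_um2`, `feret_max_um`, `feret_min_um`,
#'   `aspect_ratio`, `compactness`, `convexity`, `form_factor`,
#'   `roundness`, `solidity`.
#' @export
#' @examples
#' sq <- contour_table(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' compute_features(sq)$form_factor # pi / 4
compute_features <- function(contours) {
  stopifnot(is.data.frame(contours), "vertices" %in% names(contours))
  feats <- purrr::map(contours$vertices, measure_polygon)
  out <- dplyr::bind_cols(
    dplyr::select(as_tibble(contours), -"vertices"),
    dplyr::bind_rows(feats)
  )
  class(out) <- c("soma_features", class(out))
  out
}

# Descriptor vector of one normalized vertex matrix, as a one-row tibble.
measure_polygon <- function(v) {
  area <- polygon_area_xy(v)
  per <- polygon_perimeter_xy(v)
  hull <- convex_hull_xy(v)
  cal <- caliper_extremes_xy(v)
  compactness <- sqrt(4 * area / pi) / cal$feret_max
  tibble(
    perimeter_um = per,
    area_um2 = area,
    feret_max_um = cal$feret_max,
    feret_min_um = cal$feret_min,
    aspect_ratio = cal$feret_max / cal$feret_min,
    compactness = compactness,
    convexity = hull$hull_perimeter / per,
    form_factor = 4 * pi * area / per^2,
    roundness = compactness^2,
    solidity = area / hull$hull_area
  )
}

#' Plot soma contours
#'
#' Draws each contour as a closed polygon, faceted by layer when layers
#' vary, filled by ground-truth label when present.
#'
#' @param contours A `soma_contours` tibble.
#' @param max_cells Cap on the number of contours drawn.
#' @return A ggplot object.
#' @export
plot_contours <- function(contours, max_cells = 200) {
  stopifnot(is.data.frame(contours), "vertices" %in% names(contours))
  if (nrow(contours) > max_cells) {
    contours <- contours[seq_len(max_cells), ]
  }
  df <- contours |>
    dplyr::mutate(.xy = purrr::map(.data$vertices, ~ tibble(x = .x[, 1], y = .x[, 2]))) |>
    dplyr::select(-"vertices") |>
    tidyr::unnest(".xy")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$id)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
  if (!all(is.na(df$label))) {
    p <- p + ggplot2::geom_polygon(ggplot2::aes(fill = .data$label),
                                   colour = "grey20", linewidth = 0.2, alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_polygon(fill = "grey80", colour = "grey20", linewidth = 0.2)
  }
  if (dplyr::n_distinct(df$layer) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$layer))
  }
  p
}
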