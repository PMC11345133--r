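# Synthetic soma generator. Each morphological class maps to a shape
# family — ellipse-like (granule), rounded triangle with apical taper
# (pyramidal sizes), tapered spindle (fusiform sizes), radially perturbed
# polygon with injected concavities (polymorphic). All families are
# star-shaped about the origin by construction, hence simple polygons.

#' Default shape parameters for a morphological class
#'
#' Returns the generator's parameter set for one of the eight classes:
#' the von Economo-style height/width ranges (µm) the class is described
#' by, the target aspect-ratio and area ranges the generated contour is
#' calibrated to (aligned with the default classification rule regions,
#' so that generated ground truth and rule-based predictions agree), the
#' irregularity level and the vertex count.
#'
#' When `target_area_range` is set (the default), the contour is rescaled
#' to a target area drawn from a truncated lognormal over that range and
#' elongation is drawn from `target_aspect_ratio_range`; the height/width
#' ranges then only describe shape proportions. Setting
#' `target_area_range = NULL` switches to literal height x width
#' geometry drawn from the µm ranges.
#'
#' @param cell_type One of `"granule"`, `"small_pyramidal"`,
#'   `"medium_pyramidal"`, `"large_pyramidal"`, `"gigantic_pyramidal"`,
#'   `"small_fusiform"`, `"large_fusiform"`, `"polymorphic"`.
#' @return A named list of class `soma_shape_params`.
#' @export
class_shape_params <- function(cell_type) {
  cell_type <- match.arg(cell_type, CELL_TYPES)
  base <- list(
    cell_type = cell_type,
    height_range = NULL, width_range = NULL,
    target_aspect_ratio_range = NULL,
    target_area_range = NULL, area_meanlog = NULL, area_sdlog = 0.25,
    irregularity = 0.08, n_vertices = 48, taper_range = c(0.20, 0.36)
  )
  p <- switch(cell_type,
    granule = list(
      height_range = c(4, 8), width_range = c(4, 10),
      target_aspect_ratio_range = c(1.02, 1.34),
      target_area_range = c(35, 200), area_meanlog = log(95), area_sdlog = 0.30,
      irregularity = 0.05
    ),
    small_pyramidal = list(
      height_range = c(10, 14), width_range = c(8, 12),
      target_aspect_ratio_range = c(1.40, 1.84),
      target_area_range = c(60, 200), area_meanlog = log(135), area_sdlog = 0.25
    ),
    medium_pyramidal = list(
      height_range = c(20, 30), width_range = c(12, 18),
      target_aspect_ratio_range = c(1.40, 1.84),
      target_area_range = c(210, 390), area_meanlog = log(285), area_sdlog = 0.18
    ),
    large_pyramidal = list(
      height_range = c(30, 45), width_range = c(15, 20),
      target_aspect_ratio_range = c(1.40, 1.84),
      target_area_range = c(400, 850), area_meanlog = log(510), area_sdlog = 0.20
    ),
    gigantic_pyramidal = list(
      height_range = c(50, 90), width_range = c(25, 45),
      target_aspect_ratio_range = c(1.40, 1.84),
      target_area_range = c(950, 1800), area_meanlog = log(1150), area_sdlog = 0.15
    ),
    small_fusiform = list(
      height_range = c(12, 18), width_range = c(8, 12),
      target_aspect_ratio_range = c(1.92, 2.90),
      target_area_range = c(50, 158), area_meanlog = log(100), area_sdlog = 0.25
    ),
    large_fusiform = list(
      height_range = c(25, 35), width_range = c(12, 18),
      target_aspect_ratio_range = c(1.92, 3.40),
      target_area_range = c(170, 460), area_meanlog = log(255), area_sdlog = 0.25
    ),
    polymorphic = list(
      height_range = NULL, width_range = NULL,
      target_aspect_ratio_range = c(1.05, 2.20),
      target_area_range = c(40, 500), area_meanlog = log(140), area_sdlog = 0.35,
      irregularity = 0.85, n_vertices = 64
    )
  )
  out <- utils::modifyList(base, p)
  structure(out, class = "soma_shape_params")
}

# --- shape families (unit scale; star-shaped about the origin) ---------

chaikin <- function(v, iterations = 4) {
  for (k in seq_len(iterations)) {
    n <- nrow(v)
    nxt <- c(2:n, 1)
    q <- 0.75 * v + 0.25 * v[nxt, , drop = FALSE]
    r <- 0.25 * v + 0.75 * v[nxt, , drop = FALSE]
    v <- cbind(as.vector(rbind(q[, 1], r[, 1])), as.vector(rbind(q[, 2], r[, 2])))
  }
  v
}

shape_ellipse <- function(elong, n_vertices, jitter_sd) {
  t <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  t <- t + runif(1, 0, 2 * pi / n_vertices)
  r <- 1 + rnorm(n_vertices, 0, jitter_sd)
  cbind(elong * cos(t) * r, sin(t) * r)
}

# Rounded triangle: apex up, corner-cut smoothing, slight base asymmetry.
shape_pyramidal <- function(elong, jitter_sd) {
  w2 <- 0.5 * runif(1, 0.85, 1.15)
  tri <- rbind(
    c(runif(1, -0.12, 0.12), elong),
    c(-0.5, 0),
    c(w2, 0)
  )
  v <- chaikin(tri, 4)
  ctr <- colMeans(v)
  v <- sweep(v, 2, ctr)
  v * (1 + rnorm(nrow(v), 0, jitter_sd))
}

# Spindle: ellipse tapered toward the poles, pointier than an ellipse
# but with area close to pi*a*b (factor 1 - taper/4).
shape_fusiform <- function(elong, taper, n_vertices, jitter_sd) {
  t <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  x <- elong * cos(t)
  y <- sin(t) * (1 - taper * cos(t)^2)
  r <- 1 + rnorm(n_vertices, 0, jitter_sd)
  cbind(x * r, y * r)
}

# Radially perturbed polygon with lobes (cosine harmonics) that create
# at least two concavities; `depth` scales lobe amplitude.
shape_polymorphic <- function(elong, n_vertices, depth) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- rep(1, n_vertices)
  ks <- sample(3:7, 3)
  for (k in ks) {
    r <- r + depth * runif(1, 0.5, 1) * cos(k * th + runif(1, 0, 2 * pi))
  }
  r <- r + rnorm(n_vertices, 0, 0.02)
  r <- pmax(r, 0.15)
  cbind(elong * r * cos(th), r * sin(th))
}

rotate_xy <- function(v, angle) {
  co <- cos(angle); si <- sin(angle)
  cbind(co * v[, 1] - si * v[, 2], si * v[, 1] + co * v[, 2])
}

# One candidate contour for a class; uses the current RNG stream.
gen_candidate <- function(params, attempt = 1) {
  ct <- params$cell_type
  arr <- params$target_aspect_ratio_range
  elong <- runif(1, arr[1], arr[2])
  jit <- 0.004 + 0.006 * min(params$irregularity, 0.5)
  v <- switch(
    ct,
    granule = shape_ellipse(elong, params$n_vertices, jit),
    polymorphic = shape_polymorphic(
      elong, params$n_vertices,
      depth = 0.16 * (1 + 0.20 * (attempt - 1))
    ),
    small_fusiform = ,
    large_fusiform = shape_fusiform(
      elong, runif(1, params$taper_range[1], params$taper_range[2]),
      params$n_vertices, jit
    ),
    # pyramidal sizes: measured Feret aspect ratio of a rounded triangle
    # of height h and unit width tracks h closely; draw h = target AR
    shape_pyramidal(elong, jit)
  )
  if (is.null(params$target_area_range)) {
    h <- runif(1, params$height_range[1], params$height_range[2])
    w <- runif(1, params$width_range[1], params$width_range[2])
    cur_h <- diff(range(v[, 1])) # elongation axis is x for ellipse/fusiform
    if (ct %in% c("small_pyramidal", "medium_pyramidal", "large_pyramidal",
                  "gigantic_pyramidal")) {
      cur_h <- diff(range(v[, 2]))
      v <- cbind(v[, 1] * w / diff(range(v[, 1])), v[, 2] * h / cur_h)
    } else {
      v <- cbind(v[, 1] * h / cur_h, v[, 2] * w / diff(range(v[, 2])))
    }
  } else {
    target_area <- rtrunc_lnorm(1, params$area_meanlog, params$area_sdlog,
                                params$target_area_range[1],
                                params$target_area_range[2])
    v <- v * sqrt(target_area / abs(signed_area(v)))
  }
  v <- rotate_xy(v, runif(1, 0, 2 * pi))
  normalize_polygon(v, validate = FALSE)
}

# Rule-region class a generated cell must land in to be accepted.
# The rule set has no gigantic class; gigantic somata fall in the
# large-pyramidal region.
conform_target <- function(cell_type) {
  if (cell_type == "gigantic_pyramidal") "large_pyramidal" else cell_type
}

#' Generate one labeled synthetic soma contour
#'
#' Draws a contour from the class's shape family (see
#' [class_shape_params()]), rescales it to a target area, applies a random
#' rotation and vertex jitter. With `conform = TRUE` (default) the
#' candidate is rejection-sampled until its measured descriptors fall in
#' the class's default rule region (for polymorphic: Form Factor < 0.79
#' and Solidity < 0.95, with lobe depth increased on each retry), so that
#' ground-truth labels are consistent with the threshold classifier; after
#' `max_attempts` failures an error is raised. Deterministic for a fixed
#' `seed`.
#'
#' @param cell_type Morphological class name.
#' @param params Parameter list, default [class_shape_params()] for the class.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param id,subject,region,layer Metadata stored on the record.
#' @param conform Reject candidates outside the class's rule region.
#' @param max_attempts Rejection-sampling cap.
#' @return A one-row `soma_contours` tibble with ground-truth `label`.
#' @export
#' @examples
#' generate_cell("granule", seed = 1)
generate_cell <- function(cell_type, params = NULL, seed = NULL,
                          id = "cell_1", subject = "synthetic",
                          region = "other", layer = "unknown",
                          conform = TRUE, max_attempts = 100) {
  cell_type <- match.arg(cell_type, CELL_TYPES)
  if (is.null(params)) params <- class_shape_params(cell_type)
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed,
      generate_cell(cell_type, params, seed = NULL, id = id,
                    subject = subject, region = region, layer = layer,
                    conform = conform, max_attempts = max_attempts)
    ))
  }
  if (!is.null(params$target_aspect_ratio_range) &&
      params$target_aspect_ratio_range[1] < 1) {
    abort("infeasible parameters: target aspect ratio below 1")
  }
  v <- gen_vertices(params, conform = conform && !is.null(params$target_area_range),
                    max_attempts = max_attempts)
  contour_table(list(v), id = id, subject = subject, region = region,
                layer = layer, label = cell_type, validate = FALSE)
}

gen_vertices <- function(params, conform = TRUE, max_attempts = 100) {
  target <- conform_target(params$cell_type)
  rules <- default_ruleset()
  for (attempt in seq_len(max_attempts)) {
    v <- gen_candidate(params, attempt)
    if (!conform) return(v)
    f <- measure_polygon(v)
    if (as.character(apply_ruleset(f, rules)) == target) return(v)
  }
  abort(paste0("could not generate a conforming ", params$cell_type,
               " contour in ", max_attempts, " attempts"))
}

#' Default laminar composition profile of a cortical region
#'
#' Encodes, per layer I-VI, the relative layer thickness and the
#' probability of each morphological class, reflecting the reported
#' laminar patterns of the three regions: layer I dominated by granule
#' cells (> 80%) with no medium/large pyramidal or large fusiform cells;
#' pyramidal-rich layers III, V and VI; a large-pyramidal-rich layer III
#' in BA9; relatively smaller cells and very few large pyramidal cells in
#' BA14r; and in BA24 an excess of elongated large fusiform cells in
#' layer V (von Economo neuron territory) plus more polymorphic cells
#' throughout. Gigantic pyramidal cells are absent from all default
#' profiles.
#'
#' @param region `"BA9"`, `"BA14r"` or `"BA24"`.
#' @return A `soma_profile` tibble with columns `layer`, `rel_thickness`
#'   and one probability column per morphological class (rows sum to 1).
#' @export
composition_profile <- function(region = c("BA9", "BA14r", "BA24")) {
  region <- match.arg(region)
  cols <- c("layer", "rel_thickness", CELL_TYPES)
  m <- switch(region,
    BA9 = rbind(
      # gran  s_py  m_py  l_py  gig  s_fu  l_fu  poly
      c(0.11, 0.84, 0.07, 0.00, 0.00, 0, 0.05, 0.00, 0.04),
      c(0.08, 0.62, 0.28, 0.02, 0.00, 0, 0.04, 0.00, 0.04),
      c(0.30, 0.37, 0.14, 0.26, 0.12, 0, 0.03, 0.03, 0.05),
      c(0.07, 0.63, 0.27, 0.02, 0.00, 0, 0.04, 0.00, 0.04),
      c(0.20, 0.36, 0.16, 0.24, 0.08, 0, 0.04, 0.06, 0.06),
      c(0.24, 0.30, 0.16, 0.24, 0.06, 0, 0.04, 0.10, 0.10)
    ),
    BA14r = rbind(
      c(0.12, 0.84, 0.07, 0.00, 0.00, 0, 0.05, 0.00, 0.04),
      c(0.09, 0.66, 0.25, 0.01, 0.00, 0, 0.04, 0.00, 0.04),
      c(0.29, 0.39, 0.28, 0.21, 0.03, 0, 0.03, 0.02, 0.04),
      c(0.04, 0.65, 0.26, 0.01, 0.00, 0, 0.04, 0.00, 0.04),
      c(0.21, 0.37, 0.22, 0.21, 0.03, 0, 0.04, 0.06, 0.07),
      c(0.25, 0.29, 0.22, 0.21, 0.02, 0, 0.04, 0.10, 0.12)
    ),
    BA24 = rbind(
      c(0.13, 0.84, 0.07, 0.00, 0.00, 0, 0.05, 0.00, 0.04),
      c(0.09, 0.60, 0.26, 0.01, 0.00, 0, 0.05, 0.00, 0.08),
      c(0.28, 0.38, 0.20, 0.20, 0.03, 0, 0.04, 0.04, 0.11),
      c(0.03, 0.60, 0.25, 0.01, 0.00, 0, 0.05, 0.00, 0.09),
      c(0.22, 0.33, 0.21, 0.22, 0.02, 0, 0.04, 0.10, 0.08),
      c(0.25, 0.28, 0.22, 0.21, 0.02, 0, 0.03, 0.09, 0.15)
    )
  )
  out <- as_tibble(as.data.frame(m))
  names(out) <- c("rel_thickness", CELL_TYPES)
  out <- dplyr::bind_cols(tibble(layer = factor(LAYERS[1:6], levels = LAYERS)), out)
  attr(out, "region") <- region
  class(out) <- c("soma_profile", class(out))
  validate_profile(out)
  out
}

validate_profile <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("layer", "rel_thickness", CELL_TYPES) %in% names(profile)))
  if (any(profile$rel_thickness <= 0)) abort("invalid profile: non-positive layer thickness")
  psum <- rowSums(as.matrix(profile[, CELL_TYPES]))
  if (any(abs(psum - 1) > 1e-9)) {
    abort("invalid profile: class probabilities must sum to 1 per layer")
  }
  invisible(profile)
}

#' Generate a synthetic cortical column
#'
#' Assigns `n_cells` to layers with probability proportional to relative
#' layer thickness, draws each cell's morphological class from its
#' layer's probability vector and generates a labeled contour per cell.
#'
#' @param profile A `soma_profile` (see [composition_profile()]).
#' @param n_cells Number of cells (>= 1).
#' @param seed Optional integer seed (whole column reproducible).
#' @param subject Subject id stored on the records.
#' @return A `soma_contours` tibble of `n_cells` rows.
#' @export
generate_column <- function(profile, n_cells, seed = NULL, subject = "synthetic") {
  validate_profile(profile)
  stopifnot(n_cells >= 1)
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed, generate_column(profile, n_cells, seed = NULL, subject = subject)
    ))
  }
  region <- attr(profile, "region") %||% "other"
  lay_idx <- sample.int(nrow(profile), n_cells, replace = TRUE,
                        prob = profile$rel_thickness)
  pm <- as.matrix(profile[, CELL_TYPES])
  cells <- purrr::map(seq_len(n_cells), function(i) {
    ct <- sample(CELL_TYPES, 1, prob = pm[lay_idx[i], ])
    generate_cell(ct, seed = NULL, id = sprintf("cell_%05d", i),
                  subject = subject, region = region,
                  layer = as.character(profile$layer[lay_idx[i]]))
  })
  out <- dplyr::bind_rows(cells)
  class(out) <- c("soma_contours", class(out))
  out
}
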