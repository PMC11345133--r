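# Feature-level simulator: draws the ten descriptors directly from
# per-class distributions, bypassing geometry. Used for classifier and
# statistics tests where contour geometry is irrelevant.

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(runif(n, plo, phi), meanlog, sdlog)
}

#' Default per-class feature distributions
#'
#' For each morphological class: a truncated lognormal for Area and
#' truncated normals for Aspect Ratio, Form Factor, Solidity and
#' Convexity, each centered inside the class's default rule region and
#' truncated at the region's boundaries so that simulated ground truth
#' is consistent with the threshold classifier. The remaining
#' descriptors are derived: Perimeter from Form Factor and Area,
#' Feret Max from Area and Aspect Ratio (with a small shape-inflation
#' factor), Feret Min = Feret Max / Aspect Ratio, Compactness and
#' Roundness from their definitions.
#'
#' @return A named list (one entry per class) of distribution parameter
#'   lists; pass (possibly modified) to [simulate_feature_table()].
#' @export
class_feature_params <- function() {
  # ar/ff/sol/conv: c(mean, sd, lo, hi); area: c(meanlog, sdlog, lo, hi)
  list(
    granule = list(ar = c(1.17, 0.09, 1.001, 1.3799),
                   area = c(log(95), 0.30, 35, 200),
                   ff = c(0.88, 0.04, 0.7905, 0.98),
                   sol = c(0.975, 0.012, 0.9505, 0.998),
                   conv = c(0.985, 0.008, 0.95, 1)),
    small_pyramidal = list(ar = c(1.60, 0.12, 1.3801, 1.8599),
                           area = c(log(135), 0.25, 60, 202.0),
                           ff = c(0.84, 0.04, 0.7905, 0.96),
                           sol = c(0.968, 0.010, 0.9505, 0.995),
                           conv = c(0.975, 0.010, 0.94, 1)),
    medium_pyramidal = list(ar = c(1.60, 0.12, 1.3801, 1.8599),
                            area = c(log(285), 0.18, 202.4, 394.3),
                            ff = c(0.83, 0.04, 0.7905, 0.95),
                            sol = c(0.968, 0.010, 0.9505, 0.995),
                            conv = c(0.975, 0.010, 0.94, 1)),
    large_pyramidal = list(ar = c(1.60, 0.12, 1.3801, 1.8599),
                           area = c(log(480), 0.22, 394.7, 920),
                           ff = c(0.82, 0.04, 0.7905, 0.94),
                           sol = c(0.966, 0.010, 0.9505, 0.995),
                           conv = c(0.972, 0.010, 0.94, 1)),
    gigantic_pyramidal = list(ar = c(1.60, 0.12, 1.3801, 1.8599),
                              area = c(log(1100), 0.15, 950, 1800),
                              ff = c(0.82, 0.04, 0.7905, 0.94),
                              sol = c(0.966, 0.010, 0.9505, 0.995),
                              conv = c(0.972, 0.010, 0.94, 1)),
    small_fusiform = list(ar = c(2.15, 0.22, 1.8601, 3.2),
                          area = c(log(105), 0.22, 50, 161.0),
                          ff = c(0.78, 0.05, 0.60, 0.92),
                          sol = c(0.965, 0.010, 0.9505, 0.995),
                          conv = c(0.975, 0.010, 0.94, 1)),
    large_fusiform = list(ar = c(2.30, 0.30, 1.8601, 3.8),
                          area = c(log(250), 0.25, 161.4, 650),
                          ff = c(0.78, 0.05, 0.60, 0.92),
                          sol = c(0.965, 0.010, 0.9505, 0.995),
                          conv = c(0.975, 0.010, 0.94, 1)),
    polymorphic = list(ar = c(1.50, 0.25, 1.05, 2.50),
                       area = c(log(140), 0.35, 40, 500),
                       ff = c(0.70, 0.05, 0.45, 0.7895),
                       sol = c(0.91, 0.02, 0.82, 0.9495),
                       conv = c(0.90, 0.03, 0.80, 0.97))
  )
}

#' Simulate a labeled morphometric feature table
#'
#' Draws `n` feature rows with equal class frequencies over `classes`
#' (remainder rows go to the first classes) from the per-class
#' distributions, so that every row satisfies the descriptor invariants
#' (Aspect Ratio >= 1, ratio descriptors in (0, 1], Roundness =
#' Compactness², Feret Max >= Feret Min). Deterministic for fixed `seed`.
#'
#' @param n Total number of rows (>= 1).
#' @param params Per-class distributions, default [class_feature_params()].
#' @param classes Classes to simulate; default all but gigantic pyramidal
#'   (mirroring a study sample containing none).
#' @param seed Optional integer seed.
#' @return A tibble with `id`, `label` and the ten descriptor columns.
#' @export
#' @examples
#' simulate_feature_table(70, seed = 1)
simulate_feature_table <- function(n, params = class_feature_params(),
                                   classes = setdiff(CELL_TYPES, "gigantic_pyramidal"),
                                   seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("n must be a positive integer")
  }
  classes <- match.arg(classes, CELL_TYPES, several.ok = TRUE)
  miss <- setdiff(classes, names(params))
  if (length(miss) > 0) {
    abort(paste0("no distribution parameters for class(es): ",
                 paste(miss, collapse = ", ")))
  }
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed, simulate_feature_table(n, params, classes, seed = NULL)
    ))
  }
  n <- as.integer(n)
  per <- rep(n %/% length(classes), length(classes))
  extra <- n %% length(classes)
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  rows <- purrr::map2(classes, per, function(cl, k) {
    if (k == 0) return(NULL)
    p <- params[[cl]]
    ar <- rtrunc_norm(k, p$ar[1], p$ar[2], p$ar[3], p$ar[4])
    area <- rtrunc_lnorm(k, p$area[1], p$area[2], p$area[3], p$area[4])
    ff <- rtrunc_norm(k, p$ff[1], p$ff[2], p$ff[3], p$ff[4])
    sol <- rtrunc_norm(k, p$sol[1], p$sol[2], p$sol[3], p$sol[4])
    conv <- rtrunc_norm(k, p$conv[1], p$conv[2], p$conv[3], p$conv[4])
    perim <- sqrt(4 * pi * area / ff)
    inflate <- runif(k, 1.0, 1.08) # real shapes exceed the ellipse bound
    fmax <- sqrt(4 * ar * area / pi) * inflate
    compact <- sqrt(4 * area / pi) / fmax
    tibble(
      label = cl,
      perimeter_um = perim, area_um2 = area,
      feret_max_um = fmax, feret_min_um = fmax / ar,
      aspect_ratio = ar, compactness = compact, convexity = conv,
      form_factor = ff, roundness = compact^2, solidity = sol
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[sample.int(nrow(out)), ]
  out <- dplyr::bind_cols(tibble(id = sprintf("sim_%05d", seq_len(nrow(out)))), out)
  out$label <- as_cell_type(out$label)
  class(out) <- c("soma_features", class(out))
  out
}
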